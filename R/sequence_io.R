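# Reading, validating and writing labeled RNA window sets.
#
# Sequences are held as plain character vectors (id + residues); a labeled
# set is an "rna_set" S3 object. Inputs may be DNA-alphabet FASTA: T is
# mapped to U on read, lowercase is uppercased, anything else is rejected
# with the record id and offending position.

#' Read RNA sequences from a FASTA file
#'
#' Records are read in file order. Lowercase residues are uppercased and
#' T is mapped to U, so DNA-alphabet files (common for published benchmark
#' sets) load transparently; any residue outside \{A, C, G, U, T\} raises a
#' validation error naming the record and position. Every sequence must
#' contain at least one dinucleotide (length >= 2).
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @param quiet Suppress the one-line note emitted when T residues were
#'   converted.
#' @return A data.frame with columns \code{id} and \code{seq}.
#' @export
read_fasta <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  recs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("malformed FASTA in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  if (length(recs) == 0) stop("no FASTA records in '", path, "'", call. = FALSE)
  ids <- sub("\\s.*$", "", names(recs))
  seqs <- toupper(as.character(recs))
  had_t <- any(grepl("T", seqs, fixed = TRUE))
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGU]", seqs[[i]])
    if (bad > 0) {
      stop("record '", ids[[i]], "' in '", path, "': invalid residue '",
           substr(seqs[[i]], bad, bad), "' at position ", bad, call. = FALSE)
    }
    if (nchar(seqs[[i]]) < 2) {
      stop("record '", ids[[i]], "' in '", path,
           "': sequence shorter than one dinucleotide", call. = FALSE)
    }
  }
  if (had_t && !quiet) message("note: T residues in '", path, "' read as U")
  data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param seqs A data.frame with columns \code{id} and \code{seq}, or an
#'   \code{rna_set}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "rna_set")) {
    seqs <- data.frame(id = seqs$id, seq = seqs$seq, stringsAsFactors = FALSE)
  }
  x <- Biostrings::BStringSet(seqs$seq)
  names(x) <- seqs$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Construct a labeled sequence set
#'
#' @param id Character vector of sequence identifiers.
#' @param seq Character vector of RNA sequences over \{A, C, G, U\}.
#' @param label Integer vector of binary labels (1 = pseudouridine site).
#' @return An \code{rna_set}: a list with fields \code{id}, \code{seq},
#'   \code{label} and \code{max_length} (length of the longest member).
#' @export
rna_set <- function(id, seq, label) {
  stopifnot(length(id) == length(seq), length(seq) == length(label))
  if (length(seq) == 0) stop("empty sequence set", call. = FALSE)
  if (!all(label %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  structure(
    list(id = as.character(id), seq = as.character(seq),
         label = as.integer(label), max_length = max(nchar(seq))),
    class = "rna_set")
}

#' @export
length.rna_set <- function(x) length(x$seq)

#' @export
print.rna_set <- function(x, ...) {
  cat("rna_set:", length(x), "sequences (",
      sum(x$label == 1L), "positive /", sum(x$label == 0L),
      "negative ), max length", x$max_length, "nt\n")
  invisible(x)
}

#' Load a labeled dataset from a positive and a negative FASTA file
#'
#' All records of \code{pos_path} are labeled 1, then all records of
#' \code{neg_path} are labeled 0, preserving file order. Labels come only
#' from which file a record sits in; headers are never parsed for labels.
#'
#' @param pos_path FASTA of pseudouridine-site windows.
#' @param neg_path FASTA of non-site windows.
#' @inheritParams read_fasta
#' @return An \code{\link{rna_set}}.
#' @export
load_dataset <- function(pos_path, neg_path, quiet = FALSE) {
  pos <- read_fasta(pos_path, quiet = quiet)
  neg <- read_fasta(neg_path, quiet = quiet)
  rna_set(id = c(pos$id, neg$id), seq = c(pos$seq, neg$seq),
          label = c(rep(1L, nrow(pos)), rep(0L, nrow(neg))))
}

#' Read a labeled dataset from a single TSV file
#'
#' Expects a header row with columns \code{id}, \code{sequence},
#' \code{label}. Sequence normalization (T to U, case) matches
#' \code{\link{read_fasta}}.
#'
#' @param path Path to the TSV file.
#' @return An \code{\link{rna_set}}.
#' @export
read_dataset_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "sequence", "label")
  if (!all(need %in% names(tab))) {
    stop("dataset TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  seqs <- gsub("T", "U", toupper(tab$sequence), fixed = TRUE)
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGU]", seqs[[i]])
    if (bad > 0) {
      stop("row ", i, " (id '", tab$id[[i]], "'): invalid residue at position ",
           bad, call. = FALSE)
    }
  }
  rna_set(id = tab$id, seq = seqs, label = tab$label)
}

#' Write a labeled dataset to TSV
#'
#' @param set An \code{\link{rna_set}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_dataset_tsv <- function(set, path) {
  utils::write.table(
    data.frame(id = set$id, sequence = set$seq, label = set$label),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check that every window has uridine at its center
#'
#' A reporting operation, not a filter: the set is never modified. Windows
#' of odd length N have a well-defined center at position (N + 1) / 2
#' (1-based); those whose center is not U are reported as violations.
#' Even-length windows have no center and are reported as unverifiable.
#'
#' @param set An \code{\link{rna_set}}.
#' @return A data.frame with columns \code{id} and \code{reason}
#'   ("center_not_U" or "even_length"); zero rows when the set is clean.
#' @export
check_center_uridine <- function(set) {
  n <- nchar(set$seq)
  even <- n %% 2L == 0L
  center <- (n + 1L) %/% 2L
  centred <- substr(set$seq, center, center)
  bad <- !even & centred != "U"
  data.frame(
    id = c(set$id[even], set$id[bad]),
    reason = c(rep("even_length", sum(even)), rep("center_not_U", sum(bad))),
    stringsAsFactors = FALSE)
}
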