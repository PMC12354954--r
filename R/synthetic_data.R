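# Synthetic benchmark generator.
#
# Emulates the compositional structure of published pseudouridine
# benchmark sets: balanced positive/negative windows of fixed odd length
# with uridine at the center in both classes (negatives are real uridine
# sites too), U-enriched flanks near the center in positives and
# A-enriched flanks in negatives. Enrichment is positional and
# independent across positions; no dinucleotide correlation or secondary
# structure is modeled.

#' Configuration for the synthetic dataset generator
#'
#' At signal strength \code{s}, the enriched nucleotide's probability at
#' an affected position is \code{0.25 + s * delta} (the remaining three
#' sharing the rest equally): U in the \code{enrich_window} positions on
#' each side of the center for positives, A across all flank positions
#' for negatives. \code{s = 0} makes the classes exchangeable;
#' \code{s = 1} applies the full \code{delta} mass shift.
#'
#' @param n_pos,n_neg Class sizes (defaults 100 each, mirroring a
#'   balanced 200-window benchmark).
#' @param window_length Odd window length >= 5 (default 21; 31 is the
#'   other benchmark size).
#' @param signal Signal strength s in [0, 1] (default 1).
#' @param seed Integer seed.
#' @param delta Mass shift toward the enriched nucleotide at s = 1
#'   (default 0.4, i.e. probability 0.65 at the affected positions).
#' @param enrich_window Number of positions flanking the center on each
#'   side that are U-enriched in positives (default 5).
#' @return A \code{"generator_config"} list.
#' @export
generator_config <- function(n_pos = 100L, n_neg = 100L,
                             window_length = 21L, signal = 1.0,
                             seed = 1L, delta = 0.4, enrich_window = 5L) {
  if (window_length %% 2L == 0L || window_length < 5L) {
    stop("window_length must be odd and >= 5", call. = FALSE)
  }
  if (signal < 0 || signal > 1) stop("signal must be in [0, 1]",
                                     call. = FALSE)
  if (delta < 0 || delta > 0.75) stop("delta must be in [0, 0.75]",
                                      call. = FALSE)
  if (n_pos < 1 || n_neg < 1) stop("need at least one sample per class",
                                   call. = FALSE)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 window_length = as.integer(window_length),
                 signal = signal, seed = as.integer(seed), delta = delta,
                 enrich_window = as.integer(enrich_window)),
            class = "generator_config")
}

# Per-position nucleotide probability matrix (4 x window_length, rows
# A/C/G/U) for one class.
position_probs <- function(cfg, positive) {
  L <- cfg$window_length
  center <- (L + 1L) %/% 2L
  shift <- cfg$signal * cfg$delta
  P <- matrix(0.25, 4L, L, dimnames = list(c("A", "C", "G", "U"), NULL))
  if (positive) {
    near <- setdiff(seq(center - cfg$enrich_window,
                        center + cfg$enrich_window), center)
    near <- near[near >= 1L & near <= L]
    P["U", near] <- 0.25 + shift
    P[c("A", "C", "G"), near] <- 0.25 - shift / 3
  } else {
    flanks <- setdiff(seq_len(L), center)
    P["A", flanks] <- 0.25 + shift
    P[c("C", "G", "U"), flanks] <- 0.25 - shift / 3
  }
  P[, center] <- c(0, 0, 0, 1)   # both classes: uridine at the center
  P
}

#' Generate a synthetic labeled window set
#'
#' Draws each flank residue independently from the per-position class
#' distribution (see \code{\link{generator_config}}); every window of
#' both classes carries U at the center. Byte-identical output for the
#' same configuration (including seed).
#'
#' @param cfg A \code{\link{generator_config}}.
#' @return An \code{\link{rna_set}} with positives first (ids
#'   \code{pos_1...}, then \code{neg_1...}).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  draw_class <- function(n, positive, prefix) {
    P <- position_probs(cfg, positive)
    seqs <- vapply(seq_len(n), function(i) {
      paste(apply(P, 2, function(p) sample(rownames(P), 1L, prob = p)),
            collapse = "")
    }, character(1))
    list(id = paste0(prefix, "_", seq_len(n)), seq = seqs)
  }
  pos <- draw_class(cfg$n_pos, TRUE, "pos")
  neg <- draw_class(cfg$n_neg, FALSE, "neg")
  rna_set(id = c(pos$id, neg$id), seq = c(pos$seq, neg$seq),
          label = c(rep(1L, cfg$n_pos), rep(0L, cfg$n_neg)))
}

#' Write a generated set as a FASTA pair plus manifest
#'
#' Writes \code{positives.fasta}, \code{negatives.fasta} and
#' \code{manifest.json} (the full generator configuration, for
#' provenance) into a directory.
#'
#' @param set An \code{\link{rna_set}}.
#' @param dir Output directory (created if absent).
#' @param cfg The \code{\link{generator_config}} that produced the set
#'   (recorded in the manifest; optional).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_dataset_fasta <- function(set, dir, cfg = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pos_path <- file.path(dir, "positives.fasta")
  neg_path <- file.path(dir, "negatives.fasta")
  man_path <- file.path(dir, "manifest.json")
  keep <- set$label == 1L
  write_fasta(data.frame(id = set$id[keep], seq = set$seq[keep]), pos_path)
  write_fasta(data.frame(id = set$id[!keep], seq = set$seq[!keep]),
              neg_path)
  jsonlite::write_json(
    list(generator = if (is.null(cfg)) NULL else unclass(cfg),
         n_pos = sum(keep), n_neg = sum(!keep),
         max_length = set$max_length),
    man_path, auto_unbox = TRUE, digits = NA)
  invisible(c(positives = pos_path, negatives = neg_path,
              manifest = man_path))
}
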