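# Dinucleotide-property encoding and DFT amplitude features.
#
# A length-N sequence gives a length-(N-1) numeric profile per property
# (overlapping dinucleotides, left to right). Profiles shorter than the
# longest in the set are right-padded with zeros; a discrete Fourier
# transform is applied and the amplitude (modulus) of every coefficient is
# kept, including the DC term and the redundant conjugate-symmetric half,
# so a set of windows of length N yields exactly 2(N-1) features.

#' Encode a sequence as a dinucleotide-property profile
#'
#' Replaces each of the N-1 overlapping dinucleotides with its tabulated
#' value for the requested property.
#'
#' @param seq A single RNA sequence (character scalar over A/C/G/U).
#' @param property "free_energy" or "hydrophilicity" (or any property in a
#'   user-supplied table).
#' @param table Property lookup, as from
#'   \code{\link{dinucleotide_properties}}.
#' @return Numeric vector of length \code{nchar(seq) - 1}.
#' @examples
#' encode_property("GGA", "free_energy")
#' @export
encode_property <- function(seq, property,
                            table = dinucleotide_properties()) {
  vals <- check_property_table(table, property)
  n <- nchar(seq)
  if (n < 2) stop("sequence must contain at least one dinucleotide",
                  call. = FALSE)
  di <- substring(seq, 1:(n - 1), 2:n)
  unknown <- !di %in% names(vals)
  if (any(unknown)) {
    stop("dinucleotide '", di[which(unknown)[1]], "' not in property table",
         call. = FALSE)
  }
  unname(vals[di])
}

#' Right-pad a numeric profile with zeros
#'
#' Used to bring every profile in a mixed-length set up to the length of
#' the longest one before the transform; padding is applied to the numeric
#' profile, never to the nucleotide string.
#'
#' @param profile Numeric profile (nonempty).
#' @param target_length Desired length, at least \code{length(profile)}.
#' @return The profile with zeros appended on the right.
#' @export
pad_profile <- function(profile, target_length) {
  if (length(profile) == 0) stop("empty profile", call. = FALSE)
  if (target_length < length(profile)) {
    stop("target_length (", target_length, ") shorter than profile (",
         length(profile), ")", call. = FALSE)
  }
  c(profile, rep(0, target_length - length(profile)))
}

#' Discrete Fourier transform of a profile
#'
#' Computes H(k) = sum_n h(n) exp(-i 2 pi k n / L) for k = 0 .. L-1, with
#' L the profile length, via the fast transform. H(0) is the profile sum
#' (the DC component).
#'
#' @param profile Numeric profile (nonempty).
#' @return Complex vector of length \code{length(profile)}.
#' @export
dft_profile <- function(profile) {
  if (length(profile) == 0) stop("empty profile", call. = FALSE)
  stats::fft(profile)
}

#' Amplitude spectrum of a transform
#'
#' @param spectrum Complex vector as from \code{\link{dft_profile}}.
#' @return Nonnegative numeric vector of moduli, same length.
#' @export
amplitude_spectrum <- function(spectrum) {
  if (length(spectrum) == 0) stop("empty spectrum", call. = FALSE)
  Mod(spectrum)
}

# One sequence -> one feature row of length 2 * (max_length - 1).
feature_row <- function(seq, max_length, table) {
  unlist(lapply(c("free_energy", "hydrophilicity"), function(p) {
    prof <- pad_profile(encode_property(seq, p, table), max_length - 1L)
    amplitude_spectrum(dft_profile(prof))
  }), use.names = FALSE)
}

#' Extract DFT amplitude features for a labeled set
#'
#' Per sequence and per property (free energy first, then hydrophilicity):
#' encode, zero-pad to the set's longest profile, transform, and take
#' amplitudes. The two amplitude blocks are concatenated, giving
#' \code{2 * (max_length - 1)} named columns
#' (\code{FreeEnergy_Amp_k}, \code{Hydrophilicity_Amp_k}, k from 1).
#'
#' @param set An \code{\link{rna_set}}.
#' @param table Property lookup, as from
#'   \code{\link{dinucleotide_properties}}.
#' @param standardize If TRUE, z-score each column (mean 0, sd 1; constant
#'   columns are left at 0). Off by default: the amplitudes are used raw.
#' @return Numeric matrix, one row per sequence (rownames = ids, row order
#'   = set order), with a \code{"labels"} attribute carrying the set's
#'   labels.
#' @export
extract_features <- function(set, table = dinucleotide_properties(),
                             standardize = FALSE) {
  stopifnot(inherits(set, "rna_set"))
  L <- set$max_length - 1L
  X <- t(vapply(set$seq, feature_row, numeric(2L * L),
                max_length = set$max_length, table = table))
  dimnames(X) <- list(set$id,
                      c(paste0("FreeEnergy_Amp_", seq_len(L)),
                        paste0("Hydrophilicity_Amp_", seq_len(L))))
  if (standardize) {
    mu <- colMeans(X)
    sd <- apply(X, 2, stats::sd)
    sd[sd == 0] <- 1
    X <- sweep(sweep(X, 2, mu), 2, sd, "/")
  }
  attr(X, "labels") <- set$label
  X
}

#' Write a feature matrix to TSV
#'
#' Layout: \code{id}, \code{label}, then the named feature columns.
#' Values are written at 17 significant digits so the round-trip through
#' \code{\link{read_features}} is bit-exact.
#'
#' @param X Feature matrix from \code{\link{extract_features}}.
#' @param path Output path.
#' @param labels Labels per row; defaults to the matrix's
#'   \code{"labels"} attribute.
#' @return \code{path}, invisibly.
#' @export
write_features <- function(X, path, labels = attr(X, "labels")) {
  if (is.null(labels)) stop("no labels supplied or attached", call. = FALSE)
  stopifnot(length(labels) == nrow(X))
  out <- data.frame(id = rownames(X), label = labels,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(X))) out[[colnames(X)[j]]] <- sprintf("%.17g", X[, j])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by \code{\link{write_features}}
#'
#' @param path Path to the TSV file.
#' @return Feature matrix with rownames, column names and a
#'   \code{"labels"} attribute, as \code{\link{extract_features}} returns.
#' @export
read_features <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!all(c("id", "label") %in% names(tab))) {
    stop("feature TSV must start with columns id, label", call. = FALSE)
  }
  X <- as.matrix(tab[, setdiff(names(tab), c("id", "label")), drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- tab$id
  attr(X, "labels") <- as.integer(tab$label)
  X
}
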