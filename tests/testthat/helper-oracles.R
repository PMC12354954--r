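# Independent oracles and small fixture builders.

# Naive O(L^2) discrete Fourier transform: the literal double-loop sum
# H(k) = sum_n h(n) exp(-i 2 pi k n / L). Deliberately independent of the
# fast path it checks.
naive_dft <- function(h) {
  L <- length(h)
  H <- complex(L)
  for (k in 0:(L - 1)) {
    acc <- 0 + 0i
    for (n in 0:(L - 1)) {
      acc <- acc + h[n + 1] * exp(-1i * (2 * pi / L) * k * n)
    }
    H[k + 1] <- acc
  }
  H
}

# Write a FASTA file from parallel id/sequence vectors; returns the path.
write_test_fasta <- function(ids, seqs, path = tempfile(fileext = ".fasta"),
                             width = NA) {
  lines <- unlist(mapply(function(i, s) {
    body <- if (is.na(width)) s else {
      starts <- seq(1, nchar(s), by = width)
      substring(s, starts, pmin(starts + width - 1, nchar(s)))
    }
    c(paste0(">", i), body)
  }, ids, seqs, SIMPLIFY = FALSE))
  writeLines(lines, path)
  path
}

# Random valid RNA window of odd length with U at the center.
random_window <- function(len) {
  s <- sample(c("A", "C", "G", "U"), len, replace = TRUE)
  s[(len + 1) %/% 2] <- "U"
  paste(s, collapse = "")
}

# Two well-separated Gaussian blobs (distance ~10 sd) for trainability
# checks: rows = samples, plus a 0/1 label vector.
gaussian_blobs <- function(n_per_class, dim, seed) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n_per_class * dim, 0, 1), n_per_class),
             matrix(stats::rnorm(n_per_class * dim, 10, 1), n_per_class))
  list(X = X, y = rep(c(0L, 1L), each = n_per_class))
}

# Small labeled set + features, shared by several training tests.
tiny_feature_set <- function(n = 30, len = 21, signal = 1, seed = 42) {
  set <- generate_dataset(generator_config(n, n, len, signal, seed = seed))
  X <- extract_features(set)
  list(set = set, X = X, y = attr(X, "labels"))
}
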