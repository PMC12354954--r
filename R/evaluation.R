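# Confusion-matrix metrics, rank-based AUC, and stratified k-fold CV.

#' Tally a binary confusion matrix
#'
#' @param y_true,y_pred Equal-length binary (0/1) vectors.
#' @return A \code{"confusion_counts"} list with TP, TN, FP, FN.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  stopifnot(all(y_true %in% c(0, 1)), all(y_pred %in% c(0, 1)))
  structure(list(
    TP = sum(y_true == 1 & y_pred == 1),
    TN = sum(y_true == 0 & y_pred == 0),
    FP = sum(y_true == 0 & y_pred == 1),
    FN = sum(y_true == 1 & y_pred == 0)), class = "confusion_counts")
}

#' Accuracy, sensitivity, specificity, and MCC from confusion counts
#'
#' ACC = (TP+TN)/n, Sn = TP/(TP+FN), Sp = TN/(TN+FP), and
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). Any metric
#' whose denominator is zero is reported as 0 and flagged degenerate (so
#' screening over many configurations survives pathological folds).
#'
#' @param counts A \code{"confusion_counts"} object, or a list with TP,
#'   TN, FP, FN.
#' @return List with ACC, Sn, Sp, MCC and a character vector
#'   \code{degenerate} naming any zero-denominator metrics.
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  n <- TP + TN + FP + FN
  if (n < 1) stop("empty confusion matrix", call. = FALSE)
  degenerate <- character(0)
  sn <- if (TP + FN == 0) { degenerate <- c(degenerate, "Sn"); 0 } else
    TP / (TP + FN)
  sp <- if (TN + FP == 0) { degenerate <- c(degenerate, "Sp"); 0 } else
    TN / (TN + FP)
  mden <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (mden == 0) { degenerate <- c(degenerate, "MCC"); 0 } else
    (TP * TN - FP * FN) / sqrt(mden)
  list(ACC = (TP + TN) / n, Sn = sn, Sp = sp, MCC = mcc,
       degenerate = degenerate)
}

#' Area under the ROC curve
#'
#' Mann-Whitney rank formulation: the probability that a random positive
#' scores above a random negative, with tied positive-negative pairs
#' contributing one half. Invariant under any strictly increasing
#' transform of the scores.
#'
#' @param y_true Binary (0/1) labels; both classes must be present.
#' @param scores Class-1 scores or probabilities.
#' @return AUC in [0, 1].
#' @export
auc_score <- function(y_true, scores) {
  stopifnot(length(y_true) == length(scores))
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC requires both classes", call. = FALSE)
  }
  r <- rank(scores)            # midranks handle ties
  (sum(r[y_true == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Stratified fold assignment
#'
#' Shuffles each class independently and deals its members round-robin
#' over the k folds, with the second class starting where the first left
#' off, so overall fold sizes differ by at most one and class proportions
#' are preserved as closely as integer counts allow. Assignment depends
#' only on (labels, k, seed), never on the features.
#'
#' @param labels Binary (0/1) labels.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in 1..k, one per sample.
#' @export
make_folds <- function(labels, k, seed) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (min(n1, n0) < k) {
    stop("each class needs at least k = ", k, " members for stratified ",
         k, "-fold CV", call. = FALSE)
  }
  set.seed(seed)
  fold <- integer(length(labels))
  idx1 <- sample(which(labels == 1))
  idx0 <- sample(which(labels == 0))
  fold[idx1] <- rep_len(seq_len(k), n1)
  # continue the deal so totals stay balanced across folds
  start <- (n1 %% k) + 1L
  fold[idx0] <- rep_len(c(seq(start, k), seq_len(start - 1L)), n0)
  fold
}

# Deterministic per-fold seed derived from the master seed; stays within
# 32-bit integer range.
fold_seed <- function(seed, fold) {
  as.integer((as.numeric(seed) * 131L + fold * 9973) %% 2147483647)
}

#' Stratified k-fold cross-validation of the network
#'
#' Each fold serves once as validation while a fresh model is trained on
#' the rest; ACC, Sn, Sp, MCC (hard labels at the 0.5 threshold) and AUC
#' are computed per validation fold and averaged. Fold assignment and all
#' training randomness derive from \code{seed}.
#'
#' @param X Feature matrix.
#' @param y Binary labels.
#' @param hp A \code{\link{hyperparams}} object.
#' @param k Number of folds (default 10).
#' @param epochs Training epochs per fold (default 30).
#' @param seed Master seed.
#' @param filters,mode Passed to \code{\link{build_model}}.
#' @param threshold Probability cutoff for hard labels (default 0.5).
#' @param pooled_auc If TRUE, also compute a single AUC over the pooled
#'   out-of-fold predictions (reported as \code{AUC_pooled}).
#' @return A \code{"cv_result"}: per-fold metric data.frame
#'   (\code{folds}), their means (\code{means}), the fold assignment, and
#'   the run parameters.
#' @export
cross_validate <- function(X, y, hp, k = 10L, epochs = 30L, seed = 1L,
                           filters = 16L, mode = "dense_projection",
                           threshold = 0.5, pooled_auc = FALSE) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y))
  spec <- build_model(hp, ncol(X), filters = filters, mode = mode,
                      quiet = TRUE)
  fold <- make_folds(y, k, seed)
  per <- vector("list", k)
  oof <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- fold != f
    model <- train_cnn(spec, X[tr, , drop = FALSE], y[tr], epochs = epochs,
                       seed = fold_seed(seed, f))
    p <- predict_proba(model, X[!tr, , drop = FALSE])
    oof[!tr] <- p
    yv <- y[!tr]
    met <- compute_metrics(confusion_counts(yv, as.integer(p > threshold)))
    auc <- if (length(unique(yv)) == 2) auc_score(yv, p) else NA_real_
    per[[f]] <- data.frame(fold = f, n = sum(!tr), ACC = met$ACC,
                           Sn = met$Sn, Sp = met$Sp, MCC = met$MCC,
                           AUC = auc)
  }
  folds <- do.call(rbind, per)
  means <- colMeans(folds[, c("ACC", "Sn", "Sp", "MCC", "AUC")],
                    na.rm = TRUE)
  res <- list(folds = folds, means = as.list(means),
              fold_assignment = fold, k = as.integer(k),
              epochs = as.integer(epochs), seed = as.integer(seed),
              hp = hp, filters = as.integer(filters), mode = mode,
              threshold = threshold)
  if (pooled_auc) res$means$AUC_pooled <- auc_score(y, oof)
  structure(res, class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%d epochs, seed %d)\n",
              x$k, x$epochs, x$seed))
  cat(sprintf("  ACC %.4f  Sn %.4f  Sp %.4f  MCC %.4f  AUC %.4f\n",
              x$means$ACC, x$means$Sn, x$means$Sp, x$means$MCC,
              x$means$AUC))
  invisible(x)
}

#' Write a cross-validation result to JSON and TSV
#'
#' @param res A \code{"cv_result"}.
#' @param json_path,tsv_path Output paths (either may be NULL to skip).
#' @return \code{res}, invisibly.
#' @export
write_cv_result <- function(res, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(res, "cv_result"))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(k = res$k, epochs = res$epochs, seed = res$seed,
           hyperparams = unclass(res$hp), filters = res$filters,
           mode = res$mode, means = res$means, folds = res$folds,
           fold_assignment = res$fold_assignment),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(res$folds, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(res)
}
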