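test_that("confusion_counts tallies exactly and partitions n", {
  c1 <- confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unclass(c1)[c("TP", "TN", "FP", "FN")],
               list(TP = 2L, TN = 2L, FP = 0L, FN = 0L),
               ignore_attr = TRUE)
  c2 <- confusion_counts(c(1, 0), c(0, 1))
  expect_equal(c(c2$TP, c2$TN, c2$FP, c2$FN), c(0, 0, 1, 1))
  set.seed(40)
  for (i in 1:20) {
    n <- sample(1:50, 1)
    ct <- confusion_counts(rbinom(n, 1, 0.5), rbinom(n, 1, 0.5))
    expect_equal(ct$TP + ct$TN + ct$FP + ct$FN, n)
  }
  expect_error(confusion_counts(c(1, 0), c(1)), "equal length")
})

test_that("compute_metrics reproduces the closed-form values", {
  perfect <- compute_metrics(list(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(perfect[c("ACC", "Sn", "Sp", "MCC")],
               list(ACC = 1, Sn = 1, Sp = 1, MCC = 1))
  m <- compute_metrics(list(TP = 40, FN = 10, TN = 30, FP = 20))
  expect_equal(m$ACC, 0.70)
  expect_equal(m$Sn, 0.80)
  expect_equal(m$Sp, 0.60)
  expect_equal(m$MCC, 1000 / sqrt(6e6))
  expect_length(m$degenerate, 0)
})

test_that("zero-denominator metrics are 0 and flagged degenerate", {
  m <- compute_metrics(list(TP = 0, FP = 0, TN = 30, FN = 10))
  expect_equal(m$Sn, 0)
  expect_equal(m$MCC, 0)
  expect_true(all(c("MCC") %in% m$degenerate))
  allneg <- compute_metrics(list(TP = 0, FP = 0, TN = 5, FN = 5))
  expect_equal(allneg$Sn, 0)
  expect_true("MCC" %in% allneg$degenerate)
})

test_that("metrics match a brute-force recount on random label vectors", {
  set.seed(41)
  for (i in 1:1000) {
    n <- sample(2:40, 1)
    yt <- rbinom(n, 1, 0.5)
    yp <- rbinom(n, 1, 0.5)
    m <- compute_metrics(confusion_counts(yt, yp))
    expect_equal(m$ACC, mean(yt == yp))
    if (sum(yt == 1) > 0) expect_equal(m$Sn, mean(yp[yt == 1] == 1))
    if (sum(yt == 0) > 0) expect_equal(m$Sp, mean(yp[yt == 0] == 0))
  }
})

test_that("swapping class labels exchanges Sn/Sp and negates MCC", {
  set.seed(42)
  for (i in 1:50) {
    yt <- rbinom(30, 1, 0.5)
    yp <- rbinom(30, 1, 0.5)
    a <- compute_metrics(confusion_counts(yt, yp))
    b <- compute_metrics(confusion_counts(1 - yt, 1 - yp))
    expect_equal(a$Sn, b$Sp)
    expect_equal(a$Sp, b$Sn)
    if (length(a$degenerate) == 0 && length(b$degenerate) == 0) {
      expect_equal(a$MCC, b$MCC)  # symmetric under joint swap
    }
    expect_equal(a$ACC, b$ACC)
    # flipping only the predictions negates MCC
    d <- compute_metrics(confusion_counts(yt, 1 - yp))
    if (length(a$degenerate) == 0 && length(d$degenerate) == 0) {
      expect_equal(d$MCC, -a$MCC)
    }
  }
})

test_that("auc_score handles separation, ties, and the 3/4 pair case", {
  expect_equal(auc_score(c(1, 1, 0, 0), c(0.9, 0.8, 0.1, 0.2)), 1.0)
  expect_equal(auc_score(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_equal(auc_score(c(1, 1, 0, 0), c(0.8, 0.4, 0.6, 0.2)), 0.75)
  expect_error(auc_score(c(1, 1), c(0.5, 0.6)), "both classes")
})

test_that("auc_score is invariant to increasing transforms and matches pROC", {
  skip_if_not_installed("pROC")
  set.seed(43)
  for (i in 1:25) {
    y <- c(rep(1, 10), rep(0, 10))[sample(20)]
    s <- round(stats::runif(20), 2)  # rounding forces some ties
    a <- auc_score(y, s)
    expect_equal(auc_score(y, exp(3 * s)), a)
    expect_equal(auc_score(y, rank(s, ties.method = "average")), a)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(a, ref, tolerance = 1e-12)
  }
})

test_that("make_folds stratifies, balances, and ignores features", {
  y <- rep(c(1L, 0L), each = 100)
  f <- make_folds(y, 10, seed = 5)
  expect_equal(sort(unique(f)), 1:10)
  expect_equal(as.numeric(table(f)), rep(20, 10))
  expect_equal(as.numeric(table(f[y == 1])), rep(10, 10))
  # sizes differ by at most one, also for awkward counts
  y2 <- c(rep(1L, 17), rep(0L, 23))
  f2 <- make_folds(y2, 4, seed = 5)
  expect_lte(diff(range(table(f2))), 1)
  # depends only on (labels, k, seed)
  expect_identical(f, make_folds(y, 10, seed = 5))
  expect_false(identical(f, make_folds(y, 10, seed = 6)))
  expect_error(make_folds(c(1, 0, 1), 3, 1), "at least k")
})

test_that("cross_validate partitions samples and aggregates by the mean", {
  fs <- tiny_feature_set(n = 20, seed = 14)
  hp <- hyperparams(7, 3, 2, 1, 8, "relu")
  res <- cross_validate(fs$X, fs$y, hp, k = 4, epochs = 3, seed = 2)
  expect_s3_class(res, "cv_result")
  expect_equal(nrow(res$folds), 4)
  expect_equal(sum(res$folds$n), length(fs$y))
  expect_equal(sort(unique(res$fold_assignment)), 1:4)
  expect_equal(res$means$ACC, mean(res$folds$ACC))
  expect_equal(res$means$AUC, mean(res$folds$AUC))
  for (mname in c("ACC", "Sn", "Sp", "AUC")) {
    expect_true(all(res$folds[[mname]] >= 0 & res$folds[[mname]] <= 1))
  }
  expect_true(all(res$folds$MCC >= -1 & res$folds$MCC <= 1))
  # reproducible from the seed
  res2 <- cross_validate(fs$X, fs$y, hp, k = 4, epochs = 3, seed = 2)
  expect_identical(res$folds, res2$folds)
  expect_error(cross_validate(fs$X, fs$y, hp, k = 1, epochs = 1, seed = 1),
               ">= 2")
})

test_that("cv_result serializes to JSON and per-fold TSV", {
  fs <- tiny_feature_set(n = 12, seed = 15)
  res <- cross_validate(fs$X, fs$y, hyperparams(6, 3, 3, 1, 4, "relu"),
                        k = 2, epochs = 2, seed = 3, pooled_auc = TRUE)
  jp <- tempfile(fileext = ".json"); tp <- tempfile(fileext = ".tsv")
  write_cv_result(res, jp, tp)
  j <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(j$means$ACC, res$means$ACC)
  expect_true(!is.null(j$means$AUC_pooled))
  tab <- utils::read.delim(tp)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("fold", "ACC", "Sn", "Sp", "MCC", "AUC") %in%
                    names(tab)))
})
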