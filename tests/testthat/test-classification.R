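make_clusters <- function(n = 50, sep = 10, p = 3, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * p), n), matrix(rnorm(n * p, mean = sep), n))
  list(x = x, y = rep(c("A", "B"), each = n))
}

test_that("KNN votes among the nearest neighbours under both metrics", {
  cl <- make_clusters()
  # a training point's own neighbourhood is single-class
  pred <- knn_classify(cl$x, cl$y, cl$x[c(1, 51), ], k = 10, metric = "cubic")
  expect_identical(pred, c("A", "B"))

  # well-separated clusters: perfect held-out accuracy
  te <- make_clusters(seed = 2)
  pred2 <- knn_classify(cl$x, cl$y, te$x, k = 10, metric = "cubic")
  expect_identical(pred2, te$y)
  pred3 <- knn_classify(cl$x, cl$y, te$x, k = 10, metric = "cosine")

  # cosine distance is scale-invariant in the test row
  one <- te$x[7, , drop = FALSE]
  expect_identical(knn_classify(cl$x, cl$y, one, metric = "cosine"),
                   knn_classify(cl$x, cl$y, 5 * one, metric = "cosine"))

  expect_error(knn_classify(cl$x[1:5, ], cl$y[1:5], cl$x[1, , drop = FALSE],
                            k = 10), "exceeds the training-set size")
})

test_that("cubic distance induces Euclidean ordering on 1-D features", {
  set.seed(4)
  trx <- matrix(rnorm(30), ncol = 1)
  try_ <- rep(c("lo", "hi"), 15)
  tex <- matrix(rnorm(10), ncol = 1)
  # on one feature |a-b|^3^(1/3) = |a-b|: predictions must match a plain
  # Euclidean KNN implemented independently
  oracle <- apply(tex, 1, function(v) {
    nn <- order(abs(trx[, 1] - v))[1:5]
    tab <- table(try_[nn])
    win <- names(tab)[tab == max(tab)]
    if (length(win) == 1) win else try_[nn][match(TRUE, try_[nn] %in% win)]
  })
  expect_identical(knn_classify(trx, try_, tex, k = 5, metric = "cubic"),
                   oracle)
})

test_that("SVM separates wide-margin clusters and rejects 1-class input", {
  cl <- make_clusters(sep = 10)
  te <- make_clusters(sep = 10, seed = 3)
  pred <- svm_classify(cl$x, cl$y, te$x)
  expect_identical(pred, te$y)
  expect_error(svm_classify(cl$x, rep("A", nrow(cl$x)), te$x),
               "single class")
  # three-class problems are handled (one-vs-one underneath)
  x3 <- rbind(cl$x, matrix(rnorm(50 * 3, mean = -10), 50))
  y3 <- c(cl$y, rep("C", 50))
  pred3 <- svm_classify(x3, y3, x3[c(1, 51, 101), ])
  expect_identical(pred3, c("A", "B", "C"))
  # nu-SVM variant
  predn <- svm_classify(cl$x, cl$y, te$x, type = "nu", nu = 0.5)
  expect_identical(predn, te$y)
})

test_that("permuted labels drop SVM accuracy to chance", {
  accs <- sapply(1:12, function(s) {
    set.seed(s)
    cl <- make_clusters(n = 26, sep = 10, seed = s)
    yperm <- sample(cl$y)
    cv <- stratified_repeated_cv(cl$x, yperm, classifier = "svm_rbf",
                                 k = 5, repeats = 2, seed = s)
    cv$mean
  })
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * max(se, 0.02))
})

test_that("repeated stratified CV honours its structural contract", {
  cl <- make_clusters(n = 13, sep = 12)
  cv <- stratified_repeated_cv(cl$x, cl$y, classifier = "knn_cubic",
                               k = 10, repeats = 20, seed = 5)
  expect_length(cv$fold_accuracies, 200)
  expect_true(all(cv$fold_accuracies >= 0 & cv$fold_accuracies <= 1,
                  na.rm = TRUE))
  # perfectly separable: every fold perfect
  expect_identical(cv$mean, 1)
  expect_identical(cv$sd, 0)
  # determinism under the same seed
  cv2 <- stratified_repeated_cv(cl$x, cl$y, classifier = "knn_cubic",
                                k = 10, repeats = 20, seed = 5)
  expect_identical(cv$fold_accuracies, cv2$fold_accuracies)

  expect_error(stratified_repeated_cv(cl$x, rep("A", 26)), "at least 2")
})

test_that("stratified partitions keep class counts within one sample", {
  y <- rep(c("NT", "ST"), each = 13)
  set.seed(9)
  for (r in 1:20) {
    folds <- propsignal:::.stratified_folds(y, 10)
    counts <- table(factor(folds, levels = 1:10), y)
    # 13 members over 10 folds: every fold holds 1 or 2 of each class
    expect_true(all(counts >= 1 & counts <= 2))
    expect_identical(sum(counts), 26L)
  }
})

test_that("standardization uses training-fold statistics only", {
  set.seed(6)
  x <- matrix(rnorm(26 * 2), 26)
  x[1, ] <- c(500, -500)               # extreme point
  y <- rep(c("A", "B"), 13)
  seen <- new.env()
  probe <- function(trx, try_, tex) {
    # training folds must be exactly z-scored regardless of the outlier's
    # position; if test rows leaked into the statistics this would fail
    # whenever the extreme point sits in the test fold
    expect_lt(max(abs(colMeans(trx))), 1e-10)
    expect_equal(unname(apply(trx, 2, sd)), c(1, 1), tolerance = 1e-10)
    seen$n <- (seen$n %||% 0) + 1
    rep(try_[1], nrow(tex))
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  invisible(stratified_repeated_cv(x, y, classifier = probe, k = 13,
                                   repeats = 1, seed = 2))
  expect_identical(seen$n, 13)
})

test_that("boxplot statistics follow the quartile and fence definitions", {
  s <- summarize_boxstats(as.numeric(1:100))
  expect_equal(unname(s$quartiles), c(25.75, 50.5, 75.25))
  expect_length(s$outliers, 0)

  s2 <- summarize_boxstats(c(0, 0, 0, 0, 10))
  expect_identical(s2$outliers, 10)

  s3 <- summarize_boxstats(c(rep(2, 8), 2.4))
  expect_identical(s3$iqr, 0)
  expect_identical(s3$outliers, 2.4)

  expect_error(summarize_boxstats(numeric(0)), "at least 4")
})

test_that("problem mappings drop and merge classes as defined", {
  probs <- taster_problems()
  lab <- c("NT", "MT", "ST")
  expect_identical(probs$nt_vs_st$map(lab), c("NT", NA, "ST"))
  expect_identical(probs$nt_vs_tasters$map(lab), c("NT", "Taster", "Taster"))
  expect_identical(probs$nt_vs_mt_vs_st$map(lab), lab)
  expect_identical(probs$diplotype$map(c("PAV/PAV", "bogus")),
                   c("PAV/PAV", NA))
})

test_that("run_problem drops excluded subjects and reports their count", {
  set.seed(10)
  n <- 13L
  mk <- function(lab, mu) {
    df <- as.data.frame(matrix(rnorm(n * 7, mean = mu), n))
    names(df) <- c("f1_area_dd", "f2_delta_amp", "f3_area_d", "f4_dd_mean",
                   "f5_delta_amp_2s", "f6_max_dd", "f7_t_half")
    df$taster_label <- lab
    df$diplotype <- c(NT = "AVI/AVI", MT = "PAV/AVI", ST = "PAV/PAV")[lab]
    df
  }
  tab <- rbind(mk("NT", 0), mk("MT", 5), mk("ST", 10))
  r <- run_problem(tab, "nt_vs_st", classifier = "knn_cubic", combo = "all",
                   seed = 3)
  expect_identical(r$n, 2L * n)
  expect_gte(r$mean, 0.95)

  # diplotype problem with PAV/PAV drawn from the PAV/AVI distribution:
  # heterozygotes and homozygote tasters are confusable, AVI/AVI is not
  tab2 <- rbind(mk("NT", 0), mk("MT", 8), mk("ST", 8))
  r2 <- suppressWarnings(run_problem(tab2, "diplotype",
                                     classifier = "knn_cubic",
                                     combo = "all", seed = 3))
  expect_gte(r2$per_class_accuracy[["AVI/AVI"]], 0.9)
  expect_lte(min(r2$per_class_accuracy[c("PAV/PAV", "PAV/AVI")]), 0.6)

  tab3 <- mk("NT", 0)
  expect_error(run_problem(tab3, "nt_vs_st"), "fewer than 2 classes")
})
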