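#' k-nearest-neighbour classification with cosine or cubic distance
#'
#' Majority vote among the `k` nearest training rows under the chosen
#' metric: cosine distance (`1 - cosine similarity`) or cubic distance
#' (Minkowski order 3). Vote ties are broken by the label of the single
#' nearest neighbour belonging to a tied class, which is deterministic and
#' distance-respecting.
#'
#' @param train_x Numeric training matrix (rows = observations).
#' @param train_y Training labels (factor or character).
#' @param test_x Numeric test matrix.
#' @param k Number of neighbours (default 10).
#' @param metric `"cubic"` or `"cosine"`.
#' @return Character vector of predicted labels, one per test row.
#' @export
knn_classify <- function(train_x, train_y, test_x, k = 10,
                         metric = c("cubic", "cosine")) {
  metric <- match.arg(metric)
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  train_y <- as.character(train_y)
  if (k > nrow(train_x)) {
    stop("k = ", k, " exceeds the training-set size ", nrow(train_x),
         call. = FALSE)
  }
  dist_to_train <- function(v) {
    if (metric == "cubic") {
      rowSums(abs(sweep(train_x, 2, v))^3)^(1 / 3)
    } else {
      nv <- sqrt(sum(v^2))
      nt <- sqrt(rowSums(train_x^2))
      sim <- as.numeric(train_x %*% v) / (nt * nv)
      sim[!is.finite(sim)] <- 0            # zero-norm rows: no direction
      1 - sim
    }
  }
  apply(test_x, 1, function(v) {
    d <- dist_to_train(v)
    ord <- order(d)
    nn <- ord[seq_len(k)]
    tab <- table(train_y[nn])
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) == 1L) return(winners)
    # tie: label of the closest neighbour among the tied classes
    train_y[nn][match(TRUE, train_y[nn] %in% winners)]
  })
}

#' RBF support-vector-machine classification
#'
#' Soft-margin SVM with a Gaussian radial-basis-function kernel; multiclass
#' problems are decomposed one-versus-one with majority vote (libsvm's
#' native scheme, via e1071). The default is a C-SVM with box constraint 1
#' and kernel scale 1 on standardized features; a nu-SVM variant
#' (`type = "nu"`, nu = 0.5) is available.
#'
#' @param train_x,train_y,test_x As in [knn_classify()].
#' @param cost Box constraint C (default 1).
#' @param gamma RBF kernel coefficient (default 1, i.e. unit kernel scale).
#' @param type `"C"` (default) or `"nu"`.
#' @param nu nu parameter for the nu-SVM variant (default 0.5).
#' @return Character vector of predicted labels.
#' @export
svm_classify <- function(train_x, train_y, test_x, cost = 1, gamma = 1,
                         type = c("C", "nu"), nu = 0.5) {
  type <- match.arg(type)
  train_y <- factor(as.character(train_y))
  if (nlevels(train_y) < 2) {
    stop("training set contains a single class", call. = FALSE)
  }
  m <- e1071::svm(x = as.matrix(train_x), y = train_y, scale = FALSE,
                  kernel = "radial", gamma = gamma,
                  type = if (type == "C") "C-classification" else
                    "nu-classification",
                  cost = cost, nu = nu)
  as.character(stats::predict(m, as.matrix(test_x)))
}

# stratified fold assignment: per class, shuffle then cycle fold ids, so
# per-fold class counts differ by at most one from exact proportionality
.stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(sample.int(k), length(idx))
  }
  folds
}

.make_classifier <- function(spec, opts = list()) {
  knn_k <- opts$knn_k %||% 10
  switch(spec,
    knn_cubic = function(trx, try, tex)
      knn_classify(trx, try, tex, k = knn_k, metric = "cubic"),
    knn_cosine = function(trx, try, tex)
      knn_classify(trx, try, tex, k = knn_k, metric = "cosine"),
    svm_rbf = function(trx, try, tex)
      svm_classify(trx, try, tex, cost = opts$svm_cost %||% 1,
                   gamma = opts$svm_gamma %||% 1,
                   type = opts$svm_type %||% "C", nu = opts$nu %||% 0.5),
    stop("unknown classifier '", spec,
         "'; valid: knn_cubic, knn_cosine, svm_rbf", call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Repeated stratified k-fold cross-validation
#'
#' The evaluation scheme of the classifier harness: `repeats` independent
#' stratified partitions into `k` folds (20 x 10 by default, giving 200
#' held-out accuracies). Features are standardized (z-score) using the
#' training fold's statistics only, so no information leaks from the test
#' fold. All partitions are drawn from a single seeded RNG stream, making
#' the whole report reproducible.
#'
#' @param X Numeric feature matrix (rows = subjects).
#' @param y Labels.
#' @param classifier `"knn_cubic"`, `"knn_cosine"` or `"svm_rbf"`, or a
#'   function `(train_x, train_y, test_x) -> labels`.
#' @param k Folds per repeat (default 10).
#' @param repeats Number of repeats (default 20).
#' @param seed RNG seed for the partitions.
#' @param standardize Z-score features per training fold (default TRUE).
#' @param opts List of classifier options (`knn_k`, `svm_cost`, `svm_gamma`,
#'   `svm_type`, `nu`).
#' @return An object of class `prop_cv`: `fold_accuracies` (length
#'   `repeats * k`), `mean`, `sd`, `quartiles`, `outliers`,
#'   `per_class_accuracy`, `confusion` (aggregated over all held-out
#'   predictions), `repeat_means`, `seed`.
#' @export
stratified_repeated_cv <- function(X, y, classifier = "knn_cubic", k = 10,
                                   repeats = 20, seed = 1,
                                   standardize = TRUE, opts = list()) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  small <- classes[table(y)[classes] < k]
  if (length(small)) {
    warning("class(es) ", paste(small, collapse = ", "), " have fewer than ",
            k, " members; some folds will lack them", call. = FALSE)
  }
  clf <- if (is.function(classifier)) classifier else
    .make_classifier(classifier, opts)
  acc <- numeric(0)
  conf <- matrix(0L, length(classes), length(classes),
                 dimnames = list(truth = classes, predicted = classes))
  .with_seed(seed, {
    for (r in seq_len(repeats)) {
      folds <- .stratified_folds(y, k)
      for (f in seq_len(k)) {
        te <- which(folds == f)
        tr <- which(folds != f)
        if (length(te) == 0) { acc <- c(acc, NA_real_); next }
        trx <- X[tr, , drop = FALSE]
        tex <- X[te, , drop = FALSE]
        if (standardize) {
          mu <- colMeans(trx)
          sg <- apply(trx, 2, stats::sd)
          sg[sg == 0 | !is.finite(sg)] <- 1
          trx <- sweep(sweep(trx, 2, mu), 2, sg, "/")
          tex <- sweep(sweep(tex, 2, mu), 2, sg, "/")
        }
        pred <- clf(trx, y[tr], tex)
        acc <- c(acc, mean(pred == y[te]))
        for (i in seq_along(te)) conf[y[te[i]], pred[i]] <-
            conf[y[te[i]], pred[i]] + 1L
      }
    }
  })
  box <- summarize_boxstats(acc)
  per_class <- diag(conf) / rowSums(conf)
  structure(list(fold_accuracies = acc,
                 mean = mean(acc, na.rm = TRUE),
                 sd = stats::sd(acc[!is.na(acc)]),
                 quartiles = box$quartiles, outliers = box$outliers,
                 per_class_accuracy = per_class,
                 confusion = conf,
                 repeat_means = colMeans(matrix(acc, nrow = k)),
                 k = k, repeats = repeats, seed = seed),
            class = "prop_cv")
}

#' @export
print.prop_cv <- function(x, ...) {
  cat(sprintf("Repeated stratified CV (%d x %d-fold): accuracy %.3f +/- %.3f\n",
              x$repeats, x$k, x$mean, x$sd))
  q <- x$quartiles
  cat(sprintf("  quartiles %.3f / %.3f / %.3f; %d outlier fold(s)\n",
              q[1], q[2], q[3], length(x$outliers)))
  invisible(x)
}

#' @export
summary.prop_cv <- function(object, ...) {
  print(object)
  cat("  per-class accuracy:\n")
  for (nm in names(object$per_class_accuracy)) {
    cat(sprintf("    %-10s %.3f\n", nm, object$per_class_accuracy[[nm]]))
  }
  invisible(object)
}

#' Box-and-whisker plot of the fold accuracies
#'
#' @param x A `prop_cv`.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.prop_cv <- function(x, ...) {
  graphics::boxplot(x$fold_accuracies, ylab = "fold accuracy",
                    range = 1.5, ...)
  invisible(x)
}

#' Quartiles and outliers, boxplot-style
#'
#' Quartiles by linear-interpolation percentiles ([stats::quantile] type 7).
#' Outliers are values above `q3 + 1.5 (q3 - q1)` or below
#' `q1 - 1.5 (q3 - q1)`; they are flagged but never removed from means or
#' standard deviations.
#'
#' @param values Numeric vector with at least 4 elements.
#' @return List: `quartiles` (named q1/median/q3), `iqr`, `fences`
#'   (lower/upper), `outliers`.
#' @export
summarize_boxstats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 4) {
    stop("need at least 4 values to summarize, got ", length(values),
         call. = FALSE)
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  list(quartiles = c(q1 = q[1], median = q[2], q3 = q[3]),
       iqr = iqr, fences = c(lower = lo, upper = hi),
       outliers = values[values < lo | values > hi])
}

#' The four classification problems
#'
#' Label mappings from subject metadata to the classes of each problem:
#' `nt_vs_st` (MT subjects dropped), `nt_vs_tasters` (MT and ST mapped to
#' `"Taster"`), `nt_vs_mt_vs_st` (three classes), and `diplotype`
#' (PAV/PAV vs PAV/AVI vs AVI/AVI).
#'
#' @return Named list of problem definitions; each has `name`, `label_from`
#'   (metadata column) and `map` (function label -> class or NA to drop).
#' @export
taster_problems <- function() {
  list(
    nt_vs_st = list(
      name = "nt_vs_st", label_from = "taster_label",
      map = function(l) ifelse(l %in% c("NT", "ST"), l, NA_character_)),
    nt_vs_tasters = list(
      name = "nt_vs_tasters", label_from = "taster_label",
      map = function(l) ifelse(l == "NT", "NT",
                               ifelse(l %in% c("MT", "ST"), "Taster",
                                      NA_character_))),
    nt_vs_mt_vs_st = list(
      name = "nt_vs_mt_vs_st", label_from = "taster_label",
      map = function(l) ifelse(l %in% c("NT", "MT", "ST"), l, NA_character_)),
    diplotype = list(
      name = "diplotype", label_from = "diplotype",
      map = function(l) ifelse(l %in% c("PAV/PAV", "PAV/AVI", "AVI/AVI"),
                               l, NA_character_))
  )
}

#' Run one classification problem on a cohort feature table
#'
#' Assembles the design matrix from the requested feature combination,
#' applies the problem's label mapping (dropping excluded subjects), and
#' evaluates the classifier by repeated stratified cross-validation.
#'
#' @param features Feature table (see [feature_table()]): columns `f1_area_dd`
#'   ... `f7_t_half` plus `taster_label` / `diplotype`.
#' @param problem Problem name (see [taster_problems()]) or a problem
#'   definition list.
#' @param classifier,combo,seed,k,repeats,opts,standardize Passed to
#'   [stratified_repeated_cv()] / [select_combo()].
#' @return A `prop_cv` report (with the problem name attached).
#' @export
run_problem <- function(features, problem = "nt_vs_st",
                        classifier = "knn_cubic", combo = "all", seed = 1,
                        k = 10, repeats = 20, standardize = TRUE,
                        opts = list()) {
  if (is.character(problem)) {
    probs <- taster_problems()
    if (!problem %in% names(probs)) {
      stop("unknown problem '", problem, "'; valid: ",
           paste(names(probs), collapse = ", "), call. = FALSE)
    }
    problem <- probs[[problem]]
  }
  labels <- problem$map(features[[problem$label_from]])
  keep <- !is.na(labels)
  if (!any(keep)) stop("no subjects left after label mapping", call. = FALSE)
  y <- labels[keep]
  if (length(unique(y)) < 2) {
    stop("problem '", problem$name, "' has fewer than 2 classes in this cohort",
         call. = FALSE)
  }
  fcols <- c("f1_area_dd", "f2_delta_amp", "f3_area_d", "f4_dd_mean",
             "f5_delta_amp_2s", "f6_max_dd", "f7_t_half")
  idx <- if (is.character(combo)) .normalize_combo(combo) else
    sort(as.integer(combo))
  X <- as.matrix(features[keep, fcols[idx], drop = FALSE])
  rep <- stratified_repeated_cv(X, y, classifier = classifier, k = k,
                                repeats = repeats, seed = seed,
                                standardize = standardize, opts = opts)
  rep$problem <- problem$name
  rep$n <- length(y)
  rep
}
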