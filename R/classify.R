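#' Two-sample t statistic from group summaries
#'
#' Student's pooled-variance two-sample t computed from means, standard
#' deviations and sizes (no raw data needed), with a Welch option.
#' `t = (m1 - m2) / (s_p * sqrt(1/n1 + 1/n2))` where
#' `s_p^2 = ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2)`.
#'
#' @param m1,sd1,n1 Mean, SD and size of group 1.
#' @param m2,sd2,n2 Mean, SD and size of group 2.
#' @param var_equal Pooled variance if `TRUE` (default), Welch otherwise.
#' @return List with `statistic`, `df`, `p.value`, `method`. If the pooled
#'   variance is zero with unequal means, `statistic` is signed infinity
#'   with attribute `flagged = TRUE`.
#' @export
pooled_t <- function(m1, sd1, n1, m2, sd2, n2, var_equal = TRUE) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    method <- "pooled two-sample t"
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    method <- "Welch two-sample t"
  }
  if (se == 0) {
    stat <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
    return(list(statistic = structure(stat, flagged = (m1 != m2)),
                df = df, p.value = if (m1 == m2) 1 else 0, method = method))
  }
  stat <- (m1 - m2) / se
  list(statistic = stat, df = df,
       p.value = 2 * stats::pt(-abs(stat), df), method = method)
}

#' Rank-based ROC curve and AUC
#'
#' AUC is the Mann-Whitney pair-counting statistic: the proportion of
#' (positive, negative) pairs where the positive scores higher, ties
#' counting one half. The ROC polyline is built by sweeping a threshold
#' down the pooled scores (tied scores move as one block); its trapezoid
#' area equals the pair-counting AUC identically.
#'
#' @param scores Numeric decision scores, larger = more positive.
#' @param labels Logical/binary/factor class labels.
#' @param positive Value of `labels` treated as positive; default the
#'   larger level (e.g. `TRUE`, `1`, or the last factor level).
#' @return List with `auc` and `roc_points` (matrix of FPR, TPR starting at
#'   (0,0) and ending at (1,1), monotone in both coordinates).
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  scores <- as.numeric(scores)
  f <- as.factor(labels)
  if (nlevels(f) != 2L)
    stop("labels must contain exactly two classes", call. = FALSE)
  if (is.null(positive)) positive <- levels(f)[2L]
  pos <- f == positive
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0L || nn == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)                     # midranks handle ties
  auc <- (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  grp <- cumsum(c(TRUE, diff(s) != 0)) # tied scores collapse to one step
  tp <- cumsum(tapply(p, grp, sum)[order(unique(grp))])
  fp <- cumsum(tapply(!p, grp, sum)[order(unique(grp))])
  roc <- cbind(FPR = c(0, unname(fp) / nn), TPR = c(0, unname(tp) / np))
  list(auc = auc, roc_points = roc)
}

# area under an ROC polyline by the trapezoid rule
trapezoid_auc <- function(roc_points) {
  x <- roc_points[, 1L]; y <- roc_points[, 2L]
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

# stratified fold assignment: within each class, shuffle then deal into k
# folds round-robin
.stratified_folds <- function(labels, k, seed) {
  restore <- .with_seed(seed)
  on.exit(restore(), add = TRUE)
  fold <- integer(length(labels))
  for (lv in levels(as.factor(labels))) {
    ix <- sample(which(labels == lv))
    fold[ix] <- rep_len(seq_len(k), length(ix))
  }
  fold
}

#' Stratified k-fold cross-validated linear SVM
#'
#' Splits subjects into `k` stratified folds (seeded), and for each fold
#' z-scores the features with the training fold's mean/SD, fits a linear
#' maximum-margin classifier (via [e1071::svm()], cost `cost`), and records
#' the held-out accuracy and decision scores. The single AUC is computed on
#' the decision scores pooled across test folds.
#'
#' @param features `data.frame` of feature columns.
#' @param labels Two-class vector, one per row.
#' @param feature_subset Column names to use (default all columns).
#' @param k Number of folds (default 10).
#' @param cost SVM regularization constant (default 1).
#' @param seed Integer seed for the fold split.
#' @return A `cv_result`: list with `fold_accuracies`, `mean_accuracy`,
#'   `pooled_scores` (original row order; larger = more like the positive
#'   class, the second factor level), `auc`, `roc_points`, `seed`.
#' @export
crossval_linear_svm <- function(features, labels,
                                feature_subset = colnames(features),
                                k = 10, cost = 1, seed = 0) {
  missing_cols <- setdiff(feature_subset, colnames(features))
  if (length(missing_cols) > 0)
    stop("unknown feature(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(features[, feature_subset, drop = FALSE])
  y <- droplevels(as.factor(labels))
  if (nlevels(y) != 2L)
    stop("labels must contain exactly two classes", call. = FALSE)
  if (anyNA(X)) stop("missing feature values", call. = FALSE)
  positive <- levels(y)[2L]
  fold <- .stratified_folds(y, k, seed)
  acc <- numeric(k)
  scores <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    if (length(unique(y[tr])) < 2L)
      stop("a training fold lost one class; reduce k", call. = FALSE)
    mu <- colMeans(X[tr, , drop = FALSE])
    sg <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
    sg[sg == 0] <- 1
    Ztr <- sweep(sweep(X[tr, , drop = FALSE], 2L, mu), 2L, sg, "/")
    Zte <- sweep(sweep(X[te, , drop = FALSE], 2L, mu), 2L, sg, "/")
    fit <- e1071::svm(Ztr, y[tr], kernel = "linear", cost = cost,
                      scale = FALSE)
    pred <- stats::predict(fit, Zte, decision.values = TRUE)
    acc[f] <- mean(pred == y[te])
    dv <- drop(attr(pred, "decision.values"))
    # e1071 orients decision values toward the class named first in the
    # colname; flip so larger always means the positive (second) level
    first <- strsplit(colnames(attr(pred, "decision.values")), "/")[[1L]][1L]
    scores[te] <- if (first == positive) dv else -dv
  }
  ra <- roc_auc(scores, y, positive = positive)
  structure(list(fold_accuracies = acc, mean_accuracy = mean(acc),
                 pooled_scores = scores, auc = ra$auc,
                 roc_points = ra$roc_points, seed = seed,
                 positive = positive, features = feature_subset),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Linear SVM, %d-fold CV on [%s]: accuracy %.4f, AUC %.4f\n",
              length(x$fold_accuracies), paste(x$features, collapse = ", "),
              x$mean_accuracy, x$auc))
  invisible(x)
}
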