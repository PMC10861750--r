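#' Paired comparison of one feature between two conditions
#'
#' Two-sided paired t-test (pairing by subject or seed) with group
#' summaries. When every pairwise difference is identical the t statistic
#' is degenerate: the row is returned with `degenerate = TRUE`, with
#' `statistic = 0, p_value = 1` for the all-equal case and `NA` statistics
#' for a constant nonzero shift.
#'
#' @param a,b Numeric vectors of equal length `>= 3`, paired elementwise.
#' @param conf_level Significance level reference; default 0.95.
#' @return A one-row `data.frame`: `mean_a`, `sd_a`, `mean_b`, `sd_b`,
#'   `statistic`, `p_value`, `significant_at_95`, `degenerate`.
#' @export
paired_compare <- function(a, b, conf_level = 0.95) {
  if (length(a) != length(b))
    stop(sprintf("length mismatch: %d vs %d", length(a), length(b)))
  stopifnot(length(a) >= 3L, is.numeric(a), is.numeric(b),
            all(is.finite(a)), all(is.finite(b)))
  d <- a - b
  if (sd(d) == 0) {
    zero <- all(d == 0)
    return(data.frame(mean_a = mean(a), sd_a = sd(a),
                      mean_b = mean(b), sd_b = sd(b),
                      statistic = if (zero) 0 else NA_real_,
                      p_value = if (zero) 1 else NA_real_,
                      significant_at_95 = FALSE, degenerate = TRUE))
  }
  tt <- t.test(a, b, paired = TRUE)
  data.frame(mean_a = mean(a), sd_a = sd(a),
             mean_b = mean(b), sd_b = sd(b),
             statistic = unname(tt$statistic),
             p_value = tt$p.value,
             significant_at_95 = tt$p.value < (1 - conf_level),
             degenerate = FALSE)
}

#' Sample moments and normality check
#'
#' Bias-corrected sample skewness and excess kurtosis (the convention in
#' which a normal distribution has kurtosis 0), with a Shapiro–Wilk
#' normality test.
#'
#' @param x Numeric vector, `length >= 4`, non-constant.
#' @return List with `skewness`, `kurtosis`, `statistic` (Shapiro–Wilk W),
#'   `p_value`.
#' @export
moments_and_normality <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  if (length(x) < 4L) stop("need at least 4 observations")
  if (sd(x) == 0) stop("input is constant; moments are undefined")
  sw <- shapiro.test(if (length(x) > 5000) x[seq_len(5000)] else x)
  list(skewness = e1071::skewness(x, type = 2),
       kurtosis = e1071::kurtosis(x, type = 2),
       statistic = unname(sw$statistic),
       p_value = sw$p.value)
}

#' Confusion-matrix metrics
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `accuracy = (TP + TN) / (TP + FN + TN + FP)`. A metric whose
#' denominator is zero is returned as `NA` with a warning; all-zero counts
#' are an error.
#'
#' @param tp,fn,tn,fp Non-negative integer counts.
#' @return List with `sensitivity`, `specificity`, `accuracy`.
#' @examples
#' confusion_metrics(tp = 3, fn = 1, tn = 9, fp = 1)
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (!all(counts >= 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  total <- sum(counts)
  if (total == 0) stop("all counts are zero")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined: zero denominator", what))
      return(NA_real_)
    }
    num / den
  }
  list(sensitivity = ratio(tp, tp + fn, "sensitivity"),
       specificity = ratio(tn, tn + fp, "specificity"),
       accuracy = (tp + tn) / total)
}

#' Matched empirical quantiles of two samples
#'
#' Quantile–quantile pairing of two samples on a shared probability grid,
#' for distributional comparison (identical samples fall on the diagonal,
#' a scale change appears as a slope, a shift as an offset).
#'
#' @param a,b Numeric vectors, `length >= 2` each.
#' @param n_points Number of probability points; default the larger sample
#'   size.
#' @return A `data.frame` with columns `prob`, `qa`, `qb`, both quantile
#'   columns monotone nondecreasing.
#' @export
qq_points <- function(a, b, n_points = max(length(a), length(b))) {
  stopifnot(is.numeric(a), is.numeric(b),
            length(a) >= 2L, length(b) >= 2L)
  p <- ppoints(n_points)
  data.frame(prob = p,
             qa = as.numeric(quantile(a, p, names = FALSE)),
             qb = as.numeric(quantile(b, p, names = FALSE)))
}

#' Cross-validated detectability of movement from features
#'
#' A deliberately simple stand-in for a trained classifier: a linear
#' discriminant (`MASS::lda`) on the feature columns, evaluated by
#' stratified k-fold cross-validation on rest-versus-movement examples.
#' Deterministic for a fixed seed. Falls back to a single-feature
#' threshold rule when the discriminant is singular.
#'
#' @param features_rest,features_move Data frames (or matrices) of feature
#'   rows for the rest and movement classes; same columns, `>= 10` rows
#'   each.
#' @param folds Number of cross-validation folds; default 10.
#' @param seed Seed for the fold assignment.
#' @return List with `accuracy`, `sensitivity`, `specificity` (movement is
#'   the positive class).
#' @export
detectability_score <- function(features_rest, features_move, folds = 10,
                                seed = 1) {
  fr <- as.data.frame(features_rest)
  fm <- as.data.frame(features_move)
  if (nrow(fr) < 10L || nrow(fm) < 10L)
    stop("need at least 10 examples per class")
  if (!identical(colnames(fr), colnames(fm)))
    stop("feature columns must match between classes")
  X <- rbind(fr, fm)
  y <- factor(c(rep("rest", nrow(fr)), rep("move", nrow(fm))),
              levels = c("rest", "move"))
  set.seed(seed)
  fold_of <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold_of[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (k in seq_len(folds)) {
    test <- fold_of == k
    if (!any(test)) next
    fit <- tryCatch(
      MASS::lda(X[!test, , drop = FALSE], grouping = y[!test]),
      error = function(e) NULL)
    if (!is.null(fit)) {
      pred[test] <- predict(fit, X[test, , drop = FALSE])$class
    } else {
      # threshold on the first feature at the midpoint of class means
      v <- X[[1]]
      mrest <- mean(v[!test & y == "rest"])
      mmove <- mean(v[!test & y == "move"])
      thr <- (mrest + mmove) / 2
      lab <- if (mmove >= mrest) c("rest", "move") else c("move", "rest")
      pred[test] <- factor(ifelse(v[test] >= thr, lab[2], lab[1]),
                           levels = levels(y))
    }
  }
  tp <- sum(pred == "move" & y == "move")
  fn <- sum(pred == "rest" & y == "move")
  tn <- sum(pred == "rest" & y == "rest")
  fp <- sum(pred == "move" & y == "rest")
  confusion_metrics(tp = tp, fn = fn, tn = tn, fp = fp)
}
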