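#' ROC operating points
#'
#' Candidate thresholds are the distinct observed scores plus `+Inf` and
#' `-Inf` sentinels; a subject is test-positive when `score >= threshold`
#' (higher score predicts disease; no automatic direction flipping).
#' Sensitivity and specificity are returned in percent, ordered by
#' descending threshold.
#'
#' @param scores Numeric vector of finite index values.
#' @param labels Logical vector, `TRUE` = diseased (MetS+).
#' @return Data frame with columns `threshold`, `sensitivity`,
#'   `specificity`.
#' @export
roc_points <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("degenerate labels: need at least one positive and one negative")
  vals <- sort(unique(scores), decreasing = TRUE)
  pos_at <- vapply(vals, function(v) sum(scores[labels] == v), numeric(1))
  neg_at <- vapply(vals, function(v) sum(scores[!labels] == v), numeric(1))
  tp <- cumsum(pos_at)
  fp <- cumsum(neg_at)
  data.frame(
    threshold = c(Inf, vals, -Inf),
    sensitivity = 100 * c(0, tp, n_pos) / n_pos,
    specificity = 100 * c(n_neg, n_neg - fp, 0) / n_neg)
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' The probability that a randomly chosen positive scores above a randomly
#' chosen negative, ties counting one half — computed from midranks, so it
#' equals the trapezoidal area under [roc_points()] exactly.
#'
#' @inheritParams roc_points
#' @return AUC as a fraction in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("degenerate labels: need at least one positive and one negative")
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Trapezoidal area under a set of ROC points
#'
#' Independent geometric computation of the AUC from the curve itself;
#' agrees with [roc_auc()] to numerical precision.
#'
#' @param points Data frame from [roc_points()].
#' @return AUC as a fraction.
#' @export
roc_auc_trapezoid <- function(points) {
  fpr <- 1 - points$specificity / 100
  tpr <- points$sensitivity / 100
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# DeLong placement variance of the AUC, via midranks (O(n log n)).
.delong_var <- function(scores, labels) {
  x <- scores[labels]; y <- scores[!labels]
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  rx <- rank(x); ry <- rank(y)
  v10 <- (r[seq_len(m)] - rx) / n            # placements of positives
  v01 <- 1 - (r[m + seq_len(n)] - ry) / m    # placements of negatives
  stats::var(v10) / m + stats::var(v01) / n
}

#' Confidence interval for the AUC
#'
#' DeLong's nonparametric variance estimator (default, deterministic) or a
#' seeded percentile bootstrap for cross-checking.  Intervals are clamped
#' to \[0, 1\].
#'
#' @inheritParams roc_points
#' @param level Two-sided confidence level in (0, 1).
#' @param method `"delong"` or `"bootstrap"`.
#' @param boot_n Bootstrap resamples (stratified by class).
#' @param boot_seed Seed for the bootstrap.
#' @return Named numeric `c(low, high)`.
#' @export
auc_ci <- function(scores, labels, level = 0.95,
                   method = c("delong", "bootstrap"),
                   boot_n = 2000, boot_seed = 1) {
  method <- match.arg(method)
  stopifnot(level > 0, level < 1)
  labels <- as.logical(labels)
  if (sum(labels) < 2 || sum(!labels) < 2)
    stop("need at least 2 subjects in each class for a CI")
  est <- roc_auc(scores, labels)
  if (method == "delong") {
    se <- sqrt(.delong_var(scores, labels))
    z <- stats::qnorm(1 - (1 - level) / 2)
    lo <- est - z * se; hi <- est + z * se
  } else {
    pos <- scores[labels]; neg <- scores[!labels]
    aucs <- withr_seed(boot_seed, {
      vapply(seq_len(boot_n), function(i) {
        roc_auc(c(sample(pos, replace = TRUE), sample(neg, replace = TRUE)),
                c(rep(TRUE, length(pos)), rep(FALSE, length(neg))))
      }, numeric(1))
    })
    q <- stats::quantile(aucs, c((1 - level) / 2, 1 - (1 - level) / 2),
                         names = FALSE, type = 7)
    lo <- q[1]; hi <- q[2]
  }
  c(low = max(0, min(lo, est)), high = min(1, max(hi, est)))
}

# Evaluate expr with a local RNG state (no leakage into the caller's seed).
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Youden-optimal operating point
#'
#' Maximizes J = sensitivity + specificity - 1 over all candidate
#' thresholds by exhaustive search.  Ties are broken in favour of the
#' higher specificity (fewer false positives in a screening context), then
#' the higher threshold.  The reported cutoff is the observed threshold
#' value itself, not an inter-point midpoint.
#'
#' @param points Data frame from [roc_points()].
#' @return Named list `cutoff`, `sensitivity`, `specificity` (percent),
#'   `youden_j`.
#' @export
youden_cutoff <- function(points) {
  stopifnot(nrow(points) > 0)
  j <- (points$sensitivity + points$specificity) / 100 - 1
  # ties in J are compared at 1e-12 so floating-point noise cannot defeat
  # the specificity-first tie-break
  cand <- which(j >= max(j) - 1e-12)
  best <- cand[order(-points$specificity[cand], -points$threshold[cand])[1]]
  list(cutoff = points$threshold[best],
       sensitivity = points$sensitivity[best],
       specificity = points$specificity[best],
       youden_j = j[best])
}

#' Positive and negative likelihood ratios
#'
#' `LR+ = sensitivity / (100 - specificity)`;
#' `LR- = (100 - sensitivity) / specificity`; sensitivity and specificity
#' in percent.  An undefined denominator yields `Inf`.
#'
#' @param sensitivity,specificity Percentages in \[0, 100\].
#' @return Named numeric `c(lr_pos, lr_neg)`.
#' @export
likelihood_ratios <- function(sensitivity, specificity) {
  stopifnot(sensitivity >= 0, sensitivity <= 100,
            specificity >= 0, specificity <= 100)
  lr_pos <- if (specificity < 100) sensitivity / (100 - specificity) else Inf
  lr_neg <- if (specificity > 0) (100 - sensitivity) / specificity else Inf
  c(lr_pos = lr_pos, lr_neg = lr_neg)
}

#' Full ROC analysis of one index against a disease label
#'
#' Bundles [roc_points()], [roc_auc()], [auc_ci()], [youden_cutoff()] and
#' [likelihood_ratios()] into one result.
#'
#' @inheritParams auc_ci
#' @return Object of class `roc_result`: list with `points`, `auc`,
#'   `ci_low`, `ci_high`, `cutoff`, `sensitivity_at_cutoff`,
#'   `specificity_at_cutoff`, `youden_j`, `lr_pos`, `lr_neg`, `n_pos`,
#'   `n_neg`.
#' @export
roc_analysis <- function(scores, labels, level = 0.95,
                         method = c("delong", "bootstrap"),
                         boot_n = 2000, boot_seed = 1) {
  labels <- as.logical(labels)
  pts <- roc_points(scores, labels)
  auc <- roc_auc(scores, labels)
  ci <- if (sum(labels) >= 2 && sum(!labels) >= 2)
    auc_ci(scores, labels, level = level, method = method,
           boot_n = boot_n, boot_seed = boot_seed)
  else c(low = NA_real_, high = NA_real_)
  yc <- youden_cutoff(pts)
  lr <- likelihood_ratios(yc$sensitivity, yc$specificity)
  structure(list(points = pts, auc = auc,
                 ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
                 cutoff = yc$cutoff,
                 sensitivity_at_cutoff = yc$sensitivity,
                 specificity_at_cutoff = yc$specificity,
                 youden_j = yc$youden_j,
                 lr_pos = unname(lr["lr_pos"]), lr_neg = unname(lr["lr_neg"]),
                 n_pos = sum(labels), n_neg = sum(!labels)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (95%% CI %.3f-%.3f), n+ %d / n- %d\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  cat(sprintf("  Youden cutoff %.4g: sens %.2f%%, spec %.2f%%, LR+ %.2f, LR- %.2f\n",
              x$cutoff, x$sensitivity_at_cutoff, x$specificity_at_cutoff,
              x$lr_pos, x$lr_neg))
  invisible(x)
}
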