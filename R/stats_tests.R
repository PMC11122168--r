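#' Unpaired two-sample t test
#'
#' Pooled-variance Student's t by default; Welch's correction on request.
#' Thin wrapper around [stats::t.test()] returning the statistic and the
#' two-sided p-value.
#'
#' @param group_a,group_b Numeric vectors (each of length >= 2).
#' @param welch Use the Welch (unequal-variance) form.
#' @return Named numeric `c(statistic, p_value)`.
#' @export
unpaired_t_test <- function(group_a, group_b, welch = FALSE) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  tt <- stats::t.test(group_a, group_b, var.equal = !welch)
  c(statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Sums all hypergeometric probabilities (over tables with the observed
#' margins) that do not exceed the probability of the observed table — the
#' classical two-sided definition.  A tiny relative tolerance (1e-7)
#' absorbs floating-point ties, matching [stats::fisher.test()].
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2),
            all(table >= 0), all(table == round(table)))
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ])
  c1 <- sum(table[, 1]); c2 <- sum(table[, 2])
  if (min(r1, r2, c1, c2) == 0) stop("zero margin in 2x2 table")
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(table[1, 1], r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Pearson correlation with qualitative strength band
#'
#' Computes r, r^2 and the two-sided p-value via [stats::cor.test()], and
#' labels the magnitude of r on the conventional half-open bands:
#' |r| < 0.10 negligible, \[0.10, 0.40) weak, \[0.40, 0.70) moderate,
#' \[0.70, 0.90) strong, >= 0.90 very strong.
#'
#' @param x,y Numeric vectors, length >= 3, non-constant.
#' @return Object of class `correlation_result`: list with `r`,
#'   `r_squared`, `p_value`, `strength`.
#' @export
pearson_with_strength <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: Pearson correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  structure(list(r = r, r_squared = r^2, p_value = ct$p.value,
                 strength = correlation_strength(r)),
            class = "correlation_result")
}

#' Strength band of a correlation coefficient
#'
#' @param r Correlation coefficient(s) in \[-1, 1\].
#' @return Character vector of band labels.
#' @export
correlation_strength <- function(r) {
  a <- abs(r)
  cut(a, breaks = c(-Inf, 0.10, 0.40, 0.70, 0.90, Inf), right = FALSE,
      labels = c("negligible", "weak", "moderate", "strong", "very strong")) |>
    as.character()
}

#' Format a p-value as a conventional significance bin
#'
#' @param p P-value(s).
#' @param alpha Significance level below which a p-value stops being "ns".
#' @return Character vector: `"<0.0001"`, `"<0.001"`, `"<0.01"`, `"<0.05"`
#'   or `"ns"`.
#' @export
p_bin <- function(p, alpha = 0.05) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 1e-4) "<0.0001"
    else if (pi < 1e-3) "<0.001"
    else if (pi < 1e-2) "<0.01"
    else if (pi < alpha) "<0.05"
    else "ns"
  }, character(1))
}
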