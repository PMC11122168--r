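# Independent brute-force oracles and fixture builders used across the suite.
# These restate the definitions from first principles and must stay ignorant
# of the package internals they check.

# A valid subject record with overridable fields.
make_record <- function(...) {
  rec <- list(id = "T001", sex = "female", age = 45, weight = 110,
              height = 160, waist = 120, hip = 130, sbp = 125, dbp = 78,
              glucose = 92, total_chol = 190, hdl = 55, triglycerides = 120,
              lipid_treated = FALSE, htn_treated = FALSE,
              t2dm_diagnosed = FALSE)
  over <- list(...)
  rec[names(over)] <- over
  as.data.frame(rec, stringsAsFactors = FALSE)
}

make_cohort_df <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, rows)
  df$id <- sprintf("T%03d", seq_len(nrow(df)))
  df
}

# AUC by explicit enumeration of all (positive, negative) pairs.
brute_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (x in pos) for (y in neg)
    total <- total + (x > y) + 0.5 * (x == y)
  total / (length(pos) * length(neg))
}

# Youden maximization by explicit loop with the documented tie-breaks
# (higher specificity, then higher threshold).
brute_youden <- function(points) {
  best <- NULL
  for (i in seq_len(nrow(points))) {
    j <- (points$sensitivity[i] + points$specificity[i]) / 100 - 1
    cand <- list(cutoff = points$threshold[i],
                 sensitivity = points$sensitivity[i],
                 specificity = points$specificity[i], youden_j = j)
    if (is.null(best) ||
        j > best$youden_j + 1e-12 ||
        (abs(j - best$youden_j) <= 1e-12 &&
         (cand$specificity > best$specificity + 1e-12 ||
          (abs(cand$specificity - best$specificity) <= 1e-12 &&
           cand$cutoff > best$cutoff))))
      best <- cand
  }
  best
}

# MetS criteria restated literally, one scalar record at a time.
brute_mets <- function(sex, waist, tg, hdl, sbp, dbp, glucose,
                       lipid_treated = FALSE, htn_treated = FALSE,
                       t2dm = FALSE) {
  c1 <- if (sex == "male") waist >= 102 else waist >= 88
  c2 <- tg >= 150 || lipid_treated
  c3 <- (if (sex == "male") hdl < 40 else hdl < 50) || lipid_treated
  c4 <- sbp >= 130 || dbp >= 85 || htn_treated
  c5 <- glucose >= 100 || t2dm
  count <- sum(c1, c2, c3, c4, c5)
  list(criteria = c(c1, c2, c3, c4, c5), count = count, mets = count >= 3)
}

# Two-sided Fisher p by explicit enumeration over all tables with the
# observed margins, probabilities from binomial coefficients.
brute_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  p_obs <- probs[ks == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

within_n <- function(cfg, n) {
  cfg$n <- as.integer(n)
  cfg
}

sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / stats::sd(x)^3
}
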