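test_that("ROC points follow the score >= threshold convention", {
  pts <- roc_points(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  at3 <- pts[pts$threshold == 3, ]
  expect_equal(at3$sensitivity, 100)
  expect_equal(at3$specificity, 100)

  # uninformative score: only the two sentinel corners
  flat <- roc_points(rep(2, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  corners <- unique(flat[, c("sensitivity", "specificity")])
  expect_setequal(paste(corners$sensitivity, corners$specificity),
                  c("0 100", "100 0"))

  # tied scores across classes
  tied <- roc_points(c(1, 2, 2, 3), c(FALSE, TRUE, FALSE, TRUE))
  at2 <- tied[tied$threshold == 2, ]
  expect_equal(at2$sensitivity, 100)
  expect_equal(at2$specificity, 50)

  expect_error(roc_points(1:3, c(TRUE, TRUE, TRUE)), "degenerate")
})

test_that("AUC equals the Mann-Whitney pair probability", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(F, F, T, T)), 1.0)
  expect_equal(roc_auc(c(1, 2, 2, 3), c(F, T, F, T)), 0.875)
  expect_equal(roc_auc(c(1, 2, 2, 3), c(F, T, F, T)),
               brute_auc(c(1, 2, 2, 3), c(F, T, F, T)))
  # exchangeable: average over complementary labelings is 1/2
  s <- c(3, 1, 4, 1, 5)
  l <- c(T, F, T, F, F)
  expect_equal((roc_auc(s, l) + roc_auc(s, !l)) / 2, 0.5)
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    s <- rnorm(n)
    l <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(l)) < 2) next
    a <- roc_auc(s, l)
    expect_equal(roc_auc(exp(s), l), a, tolerance = 1e-12)
    expect_equal(roc_auc(2 * s + 7, l), a, tolerance = 1e-12)
    expect_equal(roc_auc(atan(s), l), a, tolerance = 1e-12)
  }
})

test_that("Youden cutoff matches exhaustive search with documented tie-breaks", {
  # J ties at 0.5 for thresholds 2 (sens 100/spec 50) and 3 (sens 50/spec
  # 100); the specificity-first tie-break selects 3
  pts <- roc_points(c(1, 2, 2, 3), c(F, T, F, T))
  yc <- youden_cutoff(pts)
  expect_equal(yc$cutoff, 3)
  expect_equal(yc$youden_j, 0.5)
  expect_equal(yc$specificity, 100)
  expect_equal(yc, brute_youden(pts))
  # perfect separation
  yp <- youden_cutoff(roc_points(c(1, 2, 3, 4), c(F, F, T, T)))
  expect_equal(yp$youden_j, 1)
  expect_equal(yp$cutoff, 3)
  # uninformative
  yu <- youden_cutoff(roc_points(rep(1, 4), c(T, T, F, F)))
  expect_equal(yu$youden_j, 0)
  expect_equal(yu$specificity, 100)  # tie at J=0 broken toward specificity
})

test_that("DeLong interval is deterministic, contains the AUC, and matches pROC", {
  set.seed(5)
  s <- c(rnorm(40, 1), rnorm(40))
  l <- rep(c(TRUE, FALSE), each = 40)
  ci1 <- auc_ci(s, l)
  ci2 <- auc_ci(s, l)
  expect_identical(ci1, ci2)
  a <- roc_auc(s, l)
  expect_lte(ci1["low"], a)
  expect_gte(ci1["high"], a)

  ref <- pROC::ci.auc(pROC::roc(l, s, quiet = TRUE, direction = "<"),
                      method = "delong")
  expect_equal(unname(ci1["low"]), ref[1], tolerance = 1e-9)
  expect_equal(a, as.numeric(ref[2]), tolerance = 1e-12)
  expect_equal(unname(ci1["high"]), ref[3], tolerance = 1e-9)

  # wide-margin separation at large n collapses toward 1
  s2 <- c(rnorm(300, 10), rnorm(300))
  l2 <- rep(c(TRUE, FALSE), each = 300)
  ci3 <- auc_ci(s2, l2)
  expect_gt(ci3["low"], 0.99)
  expect_equal(unname(ci3["high"]), 1)
  expect_error(auc_ci(c(1, 2, 3), c(T, F, F)), "at least 2")
})

test_that("bootstrap CI is seeded and brackets the DeLong interval roughly", {
  set.seed(6)
  s <- c(rnorm(60, 0.8), rnorm(60))
  l <- rep(c(TRUE, FALSE), each = 60)
  b1 <- auc_ci(s, l, method = "bootstrap", boot_n = 500, boot_seed = 2)
  b2 <- auc_ci(s, l, method = "bootstrap", boot_n = 500, boot_seed = 2)
  expect_identical(b1, b2)
  d <- auc_ci(s, l)
  expect_lt(abs(b1["low"] - d["low"]), 0.08)
  expect_lt(abs(b1["high"] - d["high"]), 0.08)
})

test_that("likelihood ratios reproduce the published identities", {
  lr <- likelihood_ratios(63.06, 86.55)
  expect_equal(round(unname(lr["lr_pos"]), 2), 4.69)
  expect_equal(round(unname(likelihood_ratios(30.31, 74.48)["lr_pos"]), 2), 1.19)
  perfect <- likelihood_ratios(100, 100)
  expect_equal(unname(perfect["lr_pos"]), Inf)
  expect_equal(unname(perfect["lr_neg"]), 0)
})

test_that("unpaired t test matches hand-computed pooled form", {
  a <- c(1.1, 2.3, 3.0)
  b <- c(2.0, 2.8, 4.1)
  sp2 <- ((2) * var(a) + (2) * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  got <- unpaired_t_test(a, b)
  expect_equal(unname(got["statistic"]), t_hand, tolerance = 1e-9)
  expect_equal(unname(got["p_value"]),
               2 * pt(-abs(t_hand), df = 4), tolerance = 1e-9)
  same <- unpaired_t_test(a, a)
  expect_equal(unname(same["statistic"]), 0)
  expect_equal(unname(same["p_value"]), 1)
  # shifting the higher group further away strictly increases |t|
  shifted <- unpaired_t_test(a, b + 1.5)
  expect_gt(abs(shifted["statistic"]), abs(got["statistic"]))
  # Welch agrees with stats::t.test default
  w <- unpaired_t_test(a, b, welch = TRUE)
  expect_equal(unname(w["p_value"]), t.test(a, b)$p.value)
})

test_that("Fisher exact p matches stats::fisher.test and published row", {
  big <- matrix(c(161, 61, 1030, 660), 2, byrow = TRUE)
  expect_lt(fisher_exact(big), 0.001)
  expect_equal(fisher_exact(big), fisher.test(big)$p.value, tolerance = 1e-9)
  expect_equal(fisher_exact(matrix(5, 2, 2)), 1)
  set.seed(17)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6) + 1, 2)
    expect_equal(fisher_exact(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact(matrix(c(0, 0, 3, 4), 2)), "zero margin")
})

test_that("Pearson correlation carries r-squared and strength bands", {
  x <- 1:20
  p <- pearson_with_strength(x, 2 * x + 1)
  expect_equal(p$r, 1)
  expect_equal(p$strength, "very strong")
  set.seed(23)
  y <- rnorm(5000)
  q <- pearson_with_strength(rnorm(5000), y)
  expect_lt(abs(q$r), 0.1)
  expect_equal(q$strength, "negligible")
  expect_equal(q$r_squared, q$r^2, tolerance = 1e-12)
  # half-open band boundaries
  expect_equal(correlation_strength(c(0.099, 0.10, 0.399, 0.40, 0.699,
                                      0.70, 0.899, 0.90, -0.95)),
               c("negligible", "weak", "weak", "moderate", "moderate",
                 "strong", "strong", "very strong", "very strong"))
  expect_error(pearson_with_strength(rep(1, 5), 1:5), "constant")
})

test_that("p-value bins follow the conventional cutpoints", {
  expect_equal(p_bin(c(0.5, 0.04, 0.004, 4e-4, 4e-5)),
               c("ns", "<0.05", "<0.01", "<0.001", "<0.0001"))
})
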