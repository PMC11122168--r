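test_that("criterion evaluation matches the printed thresholds at boundaries", {
  # abdominal obesity only
  a <- evaluate_criteria(make_record(sex = "female", waist = 120,
                                     triglycerides = 100, hdl = 55,
                                     sbp = 120, dbp = 75, glucose = 90))
  expect_equal(a$criteria_count, 1L)
  expect_true(a$abdominal_obesity)
  expect_false(a$mets)

  # inclusive >= for waist/TG, strict < for HDL: exactly 3 criteria
  b <- evaluate_criteria(make_record(sex = "male", waist = 102,
                                     triglycerides = 150, hdl = 39.9,
                                     sbp = 129, dbp = 84, glucose = 99))
  expect_equal(b$criteria_count, 3L)
  expect_true(b$mets)
  expect_true(b$abdominal_obesity && b$high_tg && b$low_hdl)
  expect_false(b$high_bp || b$high_glucose)

  # HDL exactly at threshold is NOT reduced (strict <)
  b2 <- evaluate_criteria(make_record(sex = "male", waist = 102,
                                      triglycerides = 150, hdl = 40,
                                      sbp = 129, dbp = 84, glucose = 99))
  expect_false(b2$low_hdl)
  expect_false(b2$mets)

  # all-negative record
  c0 <- evaluate_criteria(make_record(sex = "female", waist = 87.9,
                                      triglycerides = 149, hdl = 50,
                                      sbp = 125, dbp = 84, glucose = 99))
  expect_equal(c0$criteria_count, 0L)
  expect_false(c0$mets)
})

test_that("treatment flags override laboratory values", {
  rec <- make_record(sex = "female", waist = 80, triglycerides = 80,
                     hdl = 70, sbp = 110, dbp = 70, glucose = 80,
                     lipid_treated = TRUE)
  a <- evaluate_criteria(rec)
  expect_true(a$high_tg && a$low_hdl)
  expect_equal(a$criteria_count, 2L)
  rec$htn_treated <- TRUE; rec$t2dm_diagnosed <- TRUE
  a2 <- evaluate_criteria(rec)
  expect_true(a2$high_bp && a2$high_glucose)
  expect_equal(a2$criteria_count, 4L)
  expect_true(a2$mets)
})

test_that("worsening any single measurement never decreases the count", {
  set.seed(9)
  for (i in 1:100) {
    rec <- make_record(sex = sample(c("male", "female"), 1),
                       waist = runif(1, 70, 150),
                       triglycerides = runif(1, 60, 250),
                       hdl = runif(1, 25, 80), sbp = runif(1, 100, 160),
                       dbp = runif(1, 60, 100), glucose = runif(1, 70, 140))
    base <- evaluate_criteria(rec)$criteria_count
    worse <- list(waist = 5, triglycerides = 30, sbp = 10, dbp = 5,
                  glucose = 15, hdl = -10)
    for (f in names(worse)) {
      r2 <- rec; r2[[f]] <- r2[[f]] + worse[[f]]
      expect_gte(evaluate_criteria(r2)$criteria_count, base)
    }
  }
})

test_that("classification agrees with the brute-force oracle on random records", {
  set.seed(13)
  for (i in 1:150) {
    sex <- sample(c("male", "female"), 1)
    rec <- make_record(sex = sex, waist = runif(1, 70, 160),
                       triglycerides = runif(1, 50, 300),
                       hdl = runif(1, 20, 90), sbp = runif(1, 95, 170),
                       dbp = runif(1, 55, 110), glucose = runif(1, 65, 160),
                       lipid_treated = runif(1) < 0.2,
                       htn_treated = runif(1) < 0.2,
                       t2dm_diagnosed = runif(1) < 0.2)
    got <- evaluate_criteria(rec)
    want <- brute_mets(sex, rec$waist, rec$triglycerides, rec$hdl, rec$sbp,
                       rec$dbp, rec$glucose, rec$lipid_treated,
                       rec$htn_treated, rec$t2dm_diagnosed)
    expect_equal(got$criteria_count, want$count)
    expect_equal(got$mets, want$mets)
  }
})

test_that("cohort classification aggregates prevalence and histogram", {
  df <- make_cohort_df(
    make_record(sex = "female", waist = 120, triglycerides = 100, hdl = 55,
                sbp = 120, dbp = 75, glucose = 90),                  # count 1
    make_record(sex = "male", waist = 102, triglycerides = 150, hdl = 39.9,
                sbp = 129, dbp = 84, glucose = 99))                  # count 3
  cls <- classify_cohort(df)
  expect_equal(cls$prevalence_pct, 50.0)
  expect_equal(cls$n_mets, 1L)

  df4 <- make_cohort_df(
    make_record(waist = 80, triglycerides = 80, hdl = 60, sbp = 110,
                dbp = 70, glucose = 80),                             # 0
    make_record(waist = 120, triglycerides = 160, hdl = 60, sbp = 110,
                dbp = 70, glucose = 80),                             # 2
    make_record(waist = 120, triglycerides = 160, hdl = 40, sbp = 110,
                dbp = 70, glucose = 80),                             # 3
    make_record(waist = 120, triglycerides = 160, hdl = 40, sbp = 135,
                dbp = 90, glucose = 120))                            # 5
  cls4 <- classify_cohort(df4)
  expect_equal(cls4$prevalence_pct, 50.0)
  expect_equal(as.integer(cls4$count_histogram[c("0", "2", "3", "5")]),
               c(1L, 1L, 1L, 1L))
  expect_equal(as.integer(cls4$count_histogram[c("1", "4")]), c(0L, 0L))
  expect_error(classify_cohort(df4[0, ]), "empty")
})

test_that("strict IDF rule coincides with >=3-of-5 when waist is met", {
  set.seed(21)
  co <- simulate_cohort(default_config(n = 300), seed = 21)
  loose <- evaluate_criteria(co)
  strict <- evaluate_criteria(co, idf_strict = TRUE)
  waist_met <- loose$abdominal_obesity
  expect_equal(strict$mets[waist_met], loose$mets[waist_met])
  # without abdominal obesity the strict rule can never call MetS
  rec <- make_record(sex = "female", waist = 80, triglycerides = 200,
                     hdl = 30, sbp = 140, dbp = 90, glucose = 120)
  expect_true(evaluate_criteria(rec)$mets)
  expect_false(evaluate_criteria(rec, idf_strict = TRUE)$mets)
})
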