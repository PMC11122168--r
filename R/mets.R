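#' Evaluate the five IDF metabolic-syndrome component criteria
#'
#' Sex-specific thresholds with treatment overrides:
#' \itemize{
#'   \item abdominal obesity: waist >= 102 cm (males) / >= 88 cm (females);
#'   \item elevated triglycerides: >= 150 mg/dL, or lipid-lowering treatment;
#'   \item reduced HDL-C: < 40 mg/dL (males) / < 50 mg/dL (females), or
#'     lipid-lowering treatment;
#'   \item raised blood pressure: SBP >= 130 or DBP >= 85 mmHg, or treated
#'     hypertension;
#'   \item raised fasting glucose: >= 100 mg/dL, or diagnosed type 2 diabetes.
#' }
#' All `>=` thresholds are inclusive and the HDL threshold is strict `<`.
#' The lipid-treatment flag satisfies both lipid criteria, because specific
#' treatment for "this lipid abnormality" attaches to each.
#'
#' By default MetS is called when three or more of the five criteria are
#' met.  `idf_strict = TRUE` switches to the canonical IDF rule (mandatory
#' abdominal obesity plus at least two of the remaining four); the two
#' coincide in cohorts where everyone is centrally obese.
#'
#' @param cohort A `cohort` or data frame with the canonical columns.
#' @param idf_strict Use the mandatory-waist IDF variant.
#' @return Data frame with `id`, the five criterion logicals
#'   (`abdominal_obesity`, `high_tg`, `low_hdl`, `high_bp`, `high_glucose`),
#'   `criteria_count` (0-5) and the `mets` call.
#' @export
evaluate_criteria <- function(cohort, idf_strict = FALSE) {
  df <- as.data.frame(cohort)
  req <- c("sex", "waist", "triglycerides", "hdl", "sbp", "dbp", "glucose")
  for (f in req)
    if (any(is.na(df[[f]]))) stop("missing required field for criteria: ", f)
  male <- df$sex == "male"
  abdominal <- df$waist >= ifelse(male, 102, 88)
  high_tg <- df$triglycerides >= 150 | df$lipid_treated
  low_hdl <- df$hdl < ifelse(male, 40, 50) | df$lipid_treated
  high_bp <- df$sbp >= 130 | df$dbp >= 85 | df$htn_treated
  high_glucose <- df$glucose >= 100 | df$t2dm_diagnosed
  count <- abdominal + high_tg + low_hdl + high_bp + high_glucose
  mets <- if (idf_strict) abdominal & (count - abdominal) >= 2 else count >= 3
  data.frame(id = df$id,
             abdominal_obesity = abdominal,
             high_tg = high_tg,
             low_hdl = low_hdl,
             high_bp = high_bp,
             high_glucose = high_glucose,
             criteria_count = as.integer(count),
             mets = mets,
             stringsAsFactors = FALSE)
}

#' Classify a cohort and summarise MetS prevalence
#'
#' @inheritParams evaluate_criteria
#' @return List with `assessments` (per-subject data frame from
#'   [evaluate_criteria()]), `n`, `n_mets`, `prevalence_pct`
#'   (100 * MetS+ / n), `criterion_frequency` (count and percentage per
#'   criterion) and `count_histogram` (table of criteria_count).
#' @export
classify_cohort <- function(cohort, idf_strict = FALSE) {
  df <- as.data.frame(cohort)
  if (nrow(df) == 0) stop("empty cohort")
  a <- evaluate_criteria(df, idf_strict = idf_strict)
  crit <- c("abdominal_obesity", "high_tg", "low_hdl", "high_bp", "high_glucose")
  freq <- data.frame(
    criterion = crit,
    n = vapply(crit, function(k) sum(a[[k]]), integer(1)),
    pct = vapply(crit, function(k) 100 * mean(a[[k]]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  hist <- table(factor(a$criteria_count, levels = 0:5))
  list(assessments = a,
       n = nrow(a),
       n_mets = sum(a$mets),
       prevalence_pct = 100 * mean(a$mets),
       criterion_frequency = freq,
       count_histogram = hist)
}

#' Write per-subject MetS assessments to CSV
#'
#' @param assessments Data frame from [evaluate_criteria()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_assessments <- function(assessments, path) {
  out <- assessments
  for (f in setdiff(names(out), c("id", "criteria_count")))
    out[[f]] <- as.integer(out[[f]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
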