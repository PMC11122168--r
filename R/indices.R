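#' Body mass index
#'
#' @param weight Body weight in kg.
#' @param height Height in cm.
#' @return BMI in kg/m^2.
#' @examples
#' compute_bmi(81, 180)  # 25
#' @export
compute_bmi <- function(weight, height) {
  stopifnot(all(weight > 0), all(height > 0))
  weight / (height / 100)^2
}

#' Body adiposity index (BAI)
#'
#' Anthropometry-only adiposity surrogate: hip circumference divided by
#' height (in metres) to the power 1.5, minus 18.  Identical for both sexes.
#'
#' @param hip Hip circumference in cm.
#' @param height Height in cm.
#' @return Dimensionless BAI.
#' @export
compute_bai <- function(hip, height) {
  stopifnot(all(hip > 0), all(height > 0))
  hip / (height / 100)^1.5 - 18
}

# Sex-specific LAP waist anchors (cm): the waist circumference at which the
# lipid accumulation product is zero in the originating definition.
.lap_anchor <- function(sex) {
  a <- c(male = 65, female = 58)[sex]
  if (any(is.na(a))) stop("unknown sex: ", paste(unique(sex[is.na(a)]), collapse = ", "))
  unname(a)
}

#' Lipid accumulation product (LAP)
#'
#' `(WC - 65) * TG` for males and `(WC - 58) * TG` for females, with TG in
#' mmol/L.  The sex anchor is subtracted from waist circumference *before*
#' multiplying; the occasionally seen unparenthesized form `WC - 65 * TG` is
#' a typographical artefact and is numerically inconsistent with published
#' cohort means, so it is not offered.
#'
#' A subject whose waist does not exceed the anchor yields a non-positive
#' LAP; such values are flagged via the `"degenerate"` attribute rather than
#' raising, since they cannot occur in severely obese cohorts but must not
#' crash general use.
#'
#' @param waist Waist circumference in cm.
#' @param tg Fasting triglycerides in mmol/L.
#' @param sex `"male"` or `"female"` (recycled).
#' @return Numeric LAP values with logical attribute `degenerate`.
#' @export
compute_lap <- function(waist, tg, sex) {
  stopifnot(all(waist > 0), all(tg > 0))
  anchor <- .lap_anchor(sex)
  out <- (waist - anchor) * tg
  attr(out, "degenerate") <- waist <= anchor
  out
}

#' Cardiometabolic index (CMI)
#'
#' `(TG / HDL) / (WC / HC)` with both lipids in mmol/L: the
#' triglyceride-to-HDL ratio scaled by the inverse waist-to-hip ratio.
#'
#' @param tg Triglycerides in mmol/L.
#' @param hdl HDL cholesterol in mmol/L.
#' @param waist Waist circumference in cm.
#' @param hip Hip circumference in cm.
#' @return Dimensionless CMI.
#' @export
compute_cmi <- function(tg, hdl, waist, hip) {
  stopifnot(all(tg > 0), all(hdl > 0), all(waist > 0), all(hip > 0))
  (tg / hdl) / (waist / hip)
}

#' Compute the four-index panel for a cohort
#'
#' Computes BMI, BAI, LAP and CMI for every subject.  Lipids are taken in
#' mg/dL from the data model (the cohort CSV dialect) and converted to
#' mmol/L internally via [convert_units()]; callers never pre-convert.
#'
#' @param cohort A `cohort` or data frame with the canonical columns
#'   (lipids in mg/dL).
#' @return Data frame with columns `id`, `bmi`, `bai`, `lap`, `cmi`,
#'   `lap_degenerate`.
#' @export
compute_panel <- function(cohort) {
  df <- as.data.frame(cohort)
  if (nrow(df) == 0) stop("empty cohort")
  for (i in seq_len(nrow(df))) {
    iss <- validate_record(df[i, ])
    if (length(iss))
      stop("record ", df$id[i], " fails validation: ", paste(iss, collapse = "; "))
  }
  tg <- convert_units(df$triglycerides, "triglycerides", "mgdl_to_mmol")
  hdl <- convert_units(df$hdl, "cholesterol", "mgdl_to_mmol")
  lap <- compute_lap(df$waist, tg, df$sex)
  data.frame(id = df$id,
             bmi = compute_bmi(df$weight, df$height),
             bai = compute_bai(df$hip, df$height),
             lap = as.numeric(lap),
             cmi = compute_cmi(tg, hdl, df$waist, df$hip),
             lap_degenerate = attr(lap, "degenerate"),
             stringsAsFactors = FALSE)
}

#' Write an index panel to CSV (6 significant digits)
#'
#' @param panel Output of [compute_panel()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  out <- panel
  for (f in c("bmi", "bai", "lap", "cmi")) out[[f]] <- signif(out[[f]], 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
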