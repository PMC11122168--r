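#' Convert laboratory concentrations between mg/dL and mmol/L
#'
#' Multiplicative conversion with the standard molar-mass factors:
#' triglycerides 88.57 mg/dL per mmol/L, cholesterol (total and HDL) 38.67,
#' glucose 18.016.  These reproduce the usual paired clinical thresholds to
#' their printed precision (150 mg/dL ~ 1.7 mmol/L triglycerides,
#' 40 mg/dL ~ 1.0 mmol/L HDL, 100 mg/dL ~ 5.6 mmol/L glucose), and the
#' round trip is the identity to 1e-9 relative error.
#'
#' @param value Non-negative concentration(s).
#' @param analyte One of `"triglycerides"`, `"cholesterol"`, `"glucose"`.
#'   HDL cholesterol uses the `"cholesterol"` factor.
#' @param direction `"mgdl_to_mmol"` or `"mmol_to_mgdl"`.
#' @return Converted concentration(s).
#' @examples
#' convert_units(150, "triglycerides", "mgdl_to_mmol")  # ~1.69 mmol/L
#' @export
convert_units <- function(value,
                          analyte = c("triglycerides", "cholesterol", "glucose"),
                          direction = c("mgdl_to_mmol", "mmol_to_mgdl")) {
  analyte <- match.arg(analyte)
  direction <- match.arg(direction)
  stopifnot(all(is.na(value) | value >= 0))
  factor <- switch(analyte,
                   triglycerides = 88.57,
                   cholesterol   = 38.67,
                   glucose       = 18.016)
  if (direction == "mgdl_to_mmol") value / factor else value * factor
}
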