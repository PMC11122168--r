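#' Canonical column dictionary for cohort CSV files
#'
#' One row per subject; comma-separated, period decimal mark, UTF-8, one
#' header row.  Header matching is case-insensitive.  Sex is coded
#' `"M"`/`"F"`; the three treatment/diagnosis flags are coded `"0"`/`"1"`
#' and default to 0 when the column is absent.
#'
#' @return Named character vector mapping canonical column names to a short
#'   description (units in brackets).
#' @export
cohort_columns <- function() {
  c(id            = "subject identifier [text]",
    sex           = "biological sex [M/F]",
    age           = "age [years]",
    weight        = "body weight [kg]",
    height        = "standing height [cm]",
    waist         = "waist circumference [cm]",
    hip           = "hip circumference [cm]",
    sbp           = "systolic blood pressure [mmHg]",
    dbp           = "diastolic blood pressure [mmHg]",
    glucose       = "fasting plasma glucose [mg/dL]",
    total_chol    = "total cholesterol [mg/dL]",
    hdl           = "HDL cholesterol [mg/dL]",
    triglycerides = "fasting triglycerides [mg/dL]",
    lipid_treated = "on lipid-lowering treatment [0/1]",
    htn_treated   = "on antihypertensive treatment [0/1]",
    t2dm_diagnosed = "previously diagnosed type 2 diabetes [0/1]")
}

# Fields a row must carry (non-missing, numeric where numeric) to be
# retained: everything the index panel and the five MetS criteria consume.
# total_chol is descriptive only and may be NA.
.required_fields <- function() {
  c("sex", "age", "weight", "height", "waist", "hip",
    "sbp", "dbp", "glucose", "hdl", "triglycerides")
}

.flag_fields <- function() c("lipid_treated", "htn_treated", "t2dm_diagnosed")

.numeric_fields <- function() {
  c("age", "weight", "height", "waist", "hip", "sbp", "dbp",
    "glucose", "total_chol", "hdl", "triglycerides")
}

#' Validate a subject record
#'
#' Checks the data-model invariants: continuous fields strictly positive,
#' adult age (>= 18 years), and plausibility guardrails (height 100-230 cm,
#' waist and hip 40-250 cm).  Validation never raises; it returns a
#' character vector of issues, empty when the record is clean.
#'
#' @param record A one-row data frame (or list) with the canonical fields.
#' @return Character vector of issue descriptors, each naming the offending
#'   field and the violated rule; `character(0)` if all invariants hold.
#' @export
validate_record <- function(record) {
  issues <- character(0)
  num <- .numeric_fields()
  for (f in num) {
    v <- record[[f]]
    if (is.null(v) || length(v) == 0 || is.na(v)) {
      if (f %in% .required_fields())
        issues <- c(issues, sprintf("%s: required field missing", f))
      next
    }
    if (!is.numeric(v) || !is.finite(v)) {
      issues <- c(issues, sprintf("%s: non-numeric or non-finite value", f))
      next
    }
    if (v <= 0)
      issues <- c(issues, sprintf("%s: must be strictly positive", f))
  }
  sx <- record[["sex"]]
  if (is.null(sx) || length(sx) == 0 || is.na(sx) ||
      !tolower(as.character(sx)) %in% c("m", "f", "male", "female"))
    issues <- c(issues, "sex: must be coded M or F")
  age <- record[["age"]]
  if (!is.null(age) && length(age) && !is.na(age) && is.numeric(age) &&
      age < 18)
    issues <- c(issues, "age: below adult inclusion bound (>= 18 years)")
  h <- record[["height"]]
  if (!is.null(h) && length(h) && !is.na(h) && is.numeric(h) && h > 0 &&
      (h < 100 || h > 230))
    issues <- c(issues, "height: outside plausibility bounds 100-230 cm")
  for (f in c("waist", "hip")) {
    v <- record[[f]]
    if (!is.null(v) && length(v) && !is.na(v) && is.numeric(v) && v > 0 &&
        (v < 40 || v > 250))
      issues <- c(issues, sprintf("%s: outside plausibility bounds 40-250 cm", f))
  }
  issues
}

# Vectorized restatement of validate_record() over a normalised data frame;
# must stay in lockstep with it (property-tested).
.valid_rows <- function(df) {
  n <- nrow(df)
  ok <- !is.na(df$sex)
  for (f in .required_fields()) {
    if (f == "sex") next
    v <- df[[f]]
    ok <- ok & !is.na(v) & is.finite(v) & v > 0
  }
  opt <- df$total_chol
  ok <- ok & (is.na(opt) | (is.finite(opt) & opt > 0))
  ok & !is.na(df$age) & df$age >= 18 &
    df$height >= 100 & df$height <= 230 &
    df$waist >= 40 & df$waist <= 250 &
    df$hip >= 40 & df$hip <= 250
}

.normalise_sex <- function(x) {
  s <- tolower(as.character(x))
  out <- rep(NA_character_, length(s))
  out[s %in% c("m", "male")] <- "male"
  out[s %in% c("f", "female")] <- "female"
  out
}

.coerce_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  s <- tolower(trimws(as.character(x)))
  s %in% c("1", "true", "t", "yes", "y")
}

#' Read a cohort CSV
#'
#' Reads a subject-level cohort in the canonical CSV dialect (see
#' [cohort_columns()]).  In the default non-strict mode, rows missing any
#' field required for index computation or MetS classification are excluded
#' and counted rather than raising, mirroring the usual epidemiological
#' exclusion step; in strict mode any invalid row is an error.
#'
#' @param path Path to a CSV file with a header row.
#' @param strict If `TRUE`, any invalid or incomplete row is an error.
#' @param col_map Optional named character vector mapping canonical names to
#'   the CSV's header names (e.g. `c(waist = "WC_cm")`).
#' @return An object of class `cohort` — a data frame with the canonical
#'   columns plus attributes `excluded_count` (rows dropped) and
#'   `exclusion_log` (per-row reasons).
#' @export
read_cohort <- function(path, strict = FALSE, col_map = NULL) {
  if (!file.exists(path)) stop("cannot read cohort file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, na.strings = c("", "NA"))
  as_cohort(raw, strict = strict, col_map = col_map)
}

#' Coerce a data frame to a validated cohort
#'
#' @param df Data frame with (a superset of) the canonical columns.
#' @inheritParams read_cohort
#' @return A `cohort` object; see [read_cohort()].
#' @export
as_cohort <- function(df, strict = FALSE, col_map = NULL) {
  canon <- names(cohort_columns())
  hdr <- names(df)
  lookup <- tolower(hdr)
  if (!is.null(col_map)) {
    for (k in names(col_map)) {
      j <- match(tolower(col_map[[k]]), lookup)
      if (is.na(j)) stop("column mapping refers to absent header: ", col_map[[k]])
      lookup[j] <- tolower(k)
    }
  }
  idx <- match(canon, lookup)
  names(idx) <- canon
  required_cols <- setdiff(canon, c(.flag_fields(), "id", "total_chol"))
  missing_cols <- required_cols[is.na(idx[required_cols])]
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  unknown <- setdiff(lookup, tolower(canon))
  if (length(unknown) && strict)
    stop("unknown column(s): ", paste(unknown, collapse = ", "))

  n_in <- nrow(df)
  out <- data.frame(row.names = seq_len(max(n_in, 0)))
  out$id <- if (!is.na(idx["id"])) as.character(df[[idx["id"]]]) else
    sprintf("S%05d", seq_len(n_in))
  out$sex <- .normalise_sex(df[[idx["sex"]]])
  for (f in .numeric_fields()) {
    if (is.na(idx[f])) { out[[f]] <- rep(NA_real_, n_in); next }
    v <- df[[idx[f]]]
    vn <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & is.na(vn)
    if (any(bad) && strict)
      stop("non-numeric value in column '", f, "' at row(s) ",
           paste(utils::head(which(bad), 5), collapse = ", "))
    out[[f]] <- vn
  }
  defaulted <- character(0)
  for (f in .flag_fields()) {
    if (is.na(idx[f])) {
      out[[f]] <- rep(FALSE, n_in)
      defaulted <- c(defaulted, f)
    } else out[[f]] <- .coerce_flag(df[[idx[f]]])
  }
  if (length(defaulted))
    warning("flag column(s) absent, defaulting to FALSE: ",
            paste(defaulted, collapse = ", "))

  # vectorized fast path; per-row diagnostics only for rejected rows
  keep <- .valid_rows(out)
  log <- character(n_in)
  for (i in which(!keep))
    log[i] <- paste(validate_record(out[i, ]), collapse = "; ")
  if (strict && any(!keep))
    stop("invalid row(s) in strict mode: ",
         paste(sprintf("row %d (%s)", utils::head(which(!keep), 5),
                       utils::head(log[!keep], 5)), collapse = "; "))
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  structure(res,
            excluded_count = sum(!keep),
            exclusion_log = stats::setNames(log[!keep], out$id[!keep]),
            class = c("cohort", "data.frame"))
}

#' Write a cohort to CSV in the canonical dialect
#'
#' @param cohort A `cohort` (or compatible data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  df$sex <- ifelse(df$sex == "male", "M", "F")
  for (f in .flag_fields()) df[[f]] <- as.integer(df[[f]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Number of rows excluded while reading a cohort
#' @param cohort A `cohort` object.
#' @return Non-negative integer.
#' @export
excluded_count <- function(cohort) {
  x <- attr(cohort, "excluded_count")
  if (is.null(x)) 0L else x
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%d excluded on read)\n",
              nrow(x), excluded_count(x)))
  cat(sprintf("  sex: %d male / %d female\n",
              sum(x$sex == "male"), sum(x$sex == "female")))
  NextMethod()
}
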