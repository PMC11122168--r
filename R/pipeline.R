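#' Partition a cohort into analysis strata
#'
#' Deterministic partitions: `"all"` (single stratum), `"sex"`
#' (males/females), `"age50"` (younger = age <= 50 years, inclusive, vs
#' older), `"mets_status"` (requires prior classification via
#' `assessments`).  Strata are disjoint and their union is the input.
#'
#' @param cohort A `cohort` or data frame.
#' @param scheme One of `"all"`, `"sex"`, `"age50"`, `"mets_status"`.
#' @param assessments Output of [evaluate_criteria()], required for
#'   `"mets_status"`.
#' @return Named list of data frames (possibly with zero rows).
#' @export
stratify <- function(cohort, scheme = c("all", "sex", "age50", "mets_status"),
                     assessments = NULL) {
  scheme <- match.arg(scheme)
  df <- as.data.frame(cohort)
  switch(scheme,
    all = list(all = df),
    sex = list(males = df[df$sex == "male", , drop = FALSE],
               females = df[df$sex == "female", , drop = FALSE]),
    age50 = list(younger = df[df$age <= 50, , drop = FALSE],
                 older = df[df$age > 50, , drop = FALSE]),
    mets_status = {
      if (is.null(assessments))
        stop("mets_status stratification requires assessments")
      m <- assessments$mets[match(df$id, assessments$id)]
      list(mets_pos = df[m, , drop = FALSE],
           mets_neg = df[!m, , drop = FALSE])
    })
}

.summary_variables <- function() {
  c("age", "waist", "hip", "weight", "height", "bmi", "sbp", "dbp",
    "glucose", "total_chol", "hdl", "triglycerides", "bai", "lap", "cmi")
}

# mean +/- sd table across two groups with pooled-t p-values
.group_summary <- function(df, group, label_a, label_b) {
  vars <- intersect(.summary_variables(), names(df))
  rows <- lapply(vars, function(v) {
    a <- df[[v]][group]; b <- df[[v]][!group]
    tt <- if (length(a) >= 2 && length(b) >= 2)
      tryCatch(unpaired_t_test(a, b),   # constant data: p undefined
               error = function(e) c(statistic = NA_real_, p_value = NA_real_))
      else c(statistic = NA_real_, p_value = NA_real_)
    data.frame(variable = v,
               mean_total = mean(df[[v]]), sd_total = stats::sd(df[[v]]),
               mean_a = mean(a), sd_a = stats::sd(a),
               mean_b = mean(b), sd_b = stats::sd(b),
               p_value = unname(tt["p_value"]),
               p = p_bin(unname(tt["p_value"])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out) <- sub("_a$", paste0("_", label_a), names(out))
  names(out) <- sub("_b$", paste0("_", label_b), names(out))
  out
}

#' Run the full screening-accuracy analysis on a cohort
#'
#' The complete workflow: index panel, MetS classification, prevalence by
#' stratum, per-stratum ROC analysis of each index (BAI, LAP, CMI) against
#' the MetS label with Youden cutoff and likelihood ratios, MetS+/- and
#' male/female group comparisons (pooled t test for continuous variables,
#' Fisher's exact for the sex-by-MetS table), and the index-versus-variable
#' Pearson correlation table (MetS coded 0/1).  Deterministic given the
#' input cohort.
#'
#' Strata with a single MetS class (or fewer than two subjects per class)
#' are skipped with a notice and listed in `report$skipped`.
#'
#' @param cohort A `cohort` or compatible data frame.
#' @param idf_strict Use the mandatory-waist IDF rule (see
#'   [evaluate_criteria()]).
#' @param ci_level Confidence level for AUC intervals.
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param seed Provenance echo (the analysis itself draws no random
#'   numbers under the default DeLong CI).
#' @return Object of class `analysis_report`: list with blocks
#'   `prevalence`, `roc`, `roc_curves`, `summary_by_mets`,
#'   `summary_by_sex`, `sex_mets_fisher_p`, `correlations`,
#'   `criterion_frequency`, `skipped`, `provenance`.
#' @export
run_full_analysis <- function(cohort, idf_strict = FALSE, ci_level = 0.95,
                              ci_method = c("delong", "bootstrap"),
                              seed = NA_integer_) {
  ci_method <- match.arg(ci_method)
  df <- as.data.frame(cohort)
  if (nrow(df) == 0) stop("empty cohort")
  panel <- compute_panel(df)
  cls <- classify_cohort(df, idf_strict = idf_strict)
  a <- cls$assessments
  df <- cbind(df, panel[match(df$id, panel$id), c("bmi", "bai", "lap", "cmi")])
  df$mets <- a$mets[match(df$id, a$id)]

  strata <- c(stratify(df, "all"), stratify(df, "sex"), stratify(df, "age50"))

  prevalence <- do.call(rbind, lapply(names(strata), function(s) {
    sub <- strata[[s]]
    data.frame(stratum = s, n = nrow(sub), n_mets = sum(sub$mets),
               prevalence_pct = if (nrow(sub)) 100 * mean(sub$mets) else NA_real_,
               stringsAsFactors = FALSE)
  }))

  skipped <- character(0)
  roc_rows <- list()
  roc_curves <- list()
  for (s in names(strata)) {
    sub <- strata[[s]]
    if (sum(sub$mets) < 1 || sum(!sub$mets) < 1) {
      skipped <- c(skipped, s)
      message("stratum '", s, "' skipped: single MetS class (or empty)")
      next
    }
    for (ix in c("bai", "lap", "cmi")) {
      rr <- roc_analysis(sub[[ix]], sub$mets, level = ci_level,
                         method = ci_method)
      roc_rows[[paste(s, ix, sep = ".")]] <- data.frame(
        stratum = s, index = ix, n_pos = rr$n_pos, n_neg = rr$n_neg,
        auc = rr$auc, ci_low = rr$ci_low, ci_high = rr$ci_high,
        cutoff = rr$cutoff,
        sensitivity = rr$sensitivity_at_cutoff,
        specificity = rr$specificity_at_cutoff,
        youden_j = rr$youden_j, lr_pos = rr$lr_pos, lr_neg = rr$lr_neg,
        stringsAsFactors = FALSE)
      roc_curves[[paste(s, ix, sep = ".")]] <- rr$points
    }
  }
  roc <- do.call(rbind, c(roc_rows, list(make.row.names = FALSE)))

  summary_by_mets <- .group_summary(df, df$mets, "mets_pos", "mets_neg")
  has_both_sexes <- length(unique(df$sex)) == 2
  summary_by_sex <- if (has_both_sexes)
    .group_summary(df, df$sex == "male", "males", "females") else NULL
  fisher_p <- if (has_both_sexes)
    fisher_exact(table(factor(df$sex, c("male", "female")),
                       factor(df$mets, c(TRUE, FALSE)))) else NA_real_

  corr_vars <- c("waist", "hip", "height", "weight", "bmi", "glucose",
                 "total_chol", "hdl", "triglycerides", "mets", "bai", "lap", "cmi")
  df$mets01 <- as.numeric(df$mets)
  correlations <- do.call(rbind, lapply(c("bai", "lap", "cmi"), function(ix) {
    do.call(rbind, lapply(setdiff(corr_vars, ix), function(v) {
      y <- if (v == "mets") df$mets01 else df[[v]]
      ct <- tryCatch(pearson_with_strength(df[[ix]], y),
                     error = function(e) list(r = NA_real_, r_squared = NA_real_,
                                              p_value = NA_real_,
                                              strength = NA_character_))
      data.frame(index = ix, variable = v, r = ct$r, r_squared = ct$r_squared,
                 p_value = ct$p_value, p = p_bin(ct$p_value),
                 strength = ct$strength, stringsAsFactors = FALSE)
    }))
  }))

  structure(list(
    prevalence = prevalence,
    roc = roc,
    roc_curves = roc_curves,
    summary_by_mets = summary_by_mets,
    summary_by_sex = summary_by_sex,
    sex_mets_fisher_p = fisher_p,
    correlations = correlations,
    criterion_frequency = cls$criterion_frequency,
    count_histogram = as.list(cls$count_histogram),
    skipped = skipped,
    provenance = list(
      n = nrow(df),
      excluded_on_read = excluded_count(cohort),
      seed = seed,
      idf_strict = idf_strict,
      ci_method = ci_method,
      ci_level = ci_level,
      config_digest = .digest(as.data.frame(cohort)),
      package_version = as.character(utils::packageVersion("metsdx")))),
    class = "analysis_report")
}

# md5 of the canonical serialization of an object (provenance fingerprint)
.digest <- function(object) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf))
  saveRDS(object, tf, compress = FALSE)
  unname(tools::md5sum(tf))
}

#' Render an analysis report to files
#'
#' `"json"` writes the canonical machine-readable form (full precision);
#' `"csv_bundle"` writes one CSV per table block plus the ROC operating
#' points; `"text"` writes an aligned human-readable summary with p-value
#' bins and the provenance (seed, config digest).
#'
#' @param report An `analysis_report`.
#' @param format `"json"`, `"csv_bundle"` or `"text"`.
#' @param dir Output directory (created if absent).
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(report, format = c("json", "csv_bundle", "text"),
                          dir = ".") {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  if (format == "json") {
    path <- file.path(dir, "report.json")
    obj <- report[setdiff(names(report), "roc_curves")]
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null", force = TRUE)
    written <- path
  } else if (format == "csv_bundle") {
    tabs <- list(prevalence = report$prevalence, roc = report$roc,
                 summary_by_mets = report$summary_by_mets,
                 summary_by_sex = report$summary_by_sex,
                 correlations = report$correlations,
                 criterion_frequency = report$criterion_frequency)
    for (nm in names(tabs)) {
      if (is.null(tabs[[nm]])) next
      path <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(tabs[[nm]], path, row.names = FALSE, quote = FALSE)
      written <- c(written, path)
    }
    for (nm in names(report$roc_curves)) {
      pts <- report$roc_curves[[nm]]
      pts$fpr <- 100 - pts$specificity
      path <- file.path(dir, paste0("roc_points_", gsub("\\.", "_", nm), ".csv"))
      utils::write.csv(pts, path, row.names = FALSE, quote = FALSE)
      written <- c(written, path)
    }
  } else {
    path <- file.path(dir, "report.txt")
    con <- file(path, open = "wt")
    on.exit(close(con))
    w <- function(...) writeLines(sprintf(...), con)
    pv <- report$provenance
    w("Metabolic-syndrome screening accuracy report")
    w("n = %d (excluded on read: %d); seed = %s; config digest = %s",
      pv$n, pv$excluded_on_read, as.character(pv$seed), pv$config_digest)
    w("MetS rule: %s; CI: %s %.0f%%",
      if (pv$idf_strict) "IDF strict (mandatory waist + >=2)" else ">=3 of 5 criteria",
      pv$ci_method, 100 * pv$ci_level)
    w("")
    w("Prevalence by stratum")
    for (i in seq_len(nrow(report$prevalence)))
      w("  %-8s n=%5d  MetS+ %5d  (%.1f%%)", report$prevalence$stratum[i],
        report$prevalence$n[i], report$prevalence$n_mets[i],
        report$prevalence$prevalence_pct[i])
    w("")
    w("ROC (index vs MetS)")
    w("  %-8s %-4s %-6s %-13s %-8s %-7s %-7s %-6s", "stratum", "idx",
      "AUC", "95% CI", "cutoff", "sens%", "spec%", "LR+")
    r <- report$roc
    for (i in seq_len(nrow(r)))
      w("  %-8s %-4s %.3f  (%.3f-%.3f)  %-8.4g %7.2f %7.2f %6.2f",
        r$stratum[i], r$index[i], r$auc[i], r$ci_low[i], r$ci_high[i],
        r$cutoff[i], r$sensitivity[i], r$specificity[i], r$lr_pos[i])
    w("")
    w("Correlations (index vs variable)")
    co <- report$correlations
    for (i in seq_len(nrow(co)))
      w("  %-4s ~ %-13s r=%+.3f r2=%.3f  %-8s %s", co$index[i],
        co$variable[i], co$r[i], co$r_squared[i], co$p[i], co$strength[i])
    if (length(report$skipped))
      w("Skipped strata: %s", paste(report$skipped, collapse = ", "))
    written <- path
  }
  invisible(written)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> n = %d, overall MetS prevalence %.1f%%\n",
              x$provenance$n,
              x$prevalence$prevalence_pct[x$prevalence$stratum == "all"]))
  pop <- x$roc[x$roc$stratum == "all", ]
  for (i in seq_len(nrow(pop)))
    cat(sprintf("  %s: AUC %.3f (%.3f-%.3f), cutoff %.4g, sens %.1f%%, spec %.1f%%, LR+ %.2f\n",
                toupper(pop$index[i]), pop$auc[i], pop$ci_low[i], pop$ci_high[i],
                pop$cutoff[i], pop$sensitivity[i], pop$specificity[i],
                pop$lr_pos[i]))
  invisible(x)
}
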