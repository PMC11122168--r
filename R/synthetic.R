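#' Variables carried by the synthetic-cohort generator
#'
#' The eleven continuous measurements drawn per subject, in latent order.
#' Body weight is not drawn: it is derived as `bmi * height_m^2` so the
#' BMI-weight-height identity holds exactly for every subject.
#'
#' @return Character vector of variable names.
#' @export
sim_variables <- function() {
  c("age", "height", "bmi", "waist", "hip", "sbp", "dbp",
    "glucose", "total_chol", "hdl", "triglycerides")
}

# Variables feeding the five MetS component criteria; the prevalence
# calibration multiplier scales the latent correlations *within* this block.
.criterion_variables <- function() {
  c("waist", "sbp", "dbp", "glucose", "hdl", "triglycerides")
}

.default_marginals <- function() {
  vars <- sim_variables()
  fam <- ifelse(vars %in% c("glucose", "triglycerides"), "lognormal", "normal")
  male <- data.frame(
    variable = vars, family = fam,
    mean = c(47.5, 172.0, 42.8, 131.5, 130.1, 131.6, 78.2, 100.8, 191.0, 41.6, 164.7),
    sd   = c(14.7,   7.9,  6.2,  12.6,  13.9,  15.1,  9.5,  35.7,  35.0, 10.0,  87.0),
    stringsAsFactors = FALSE)
  female <- data.frame(
    variable = vars, family = fam,
    mean = c(51.1, 157.4, 43.4, 120.1, 132.1, 128.2, 76.9, 98.5, 196.2, 50.7, 133.4),
    sd   = c(14.0,   6.8,  6.2,  12.4,  12.7,  13.7,  7.6, 31.8,  37.5, 12.7,  61.4),
    stringsAsFactors = FALSE)
  list(male = male, female = female)
}

.default_bounds <- function() {
  # Plausibility / inclusion truncation limits for the normal-family
  # variables (lognormal variables are positive by construction; bounds NA).
  # The BMI lower bound encodes the severe-obesity inclusion criterion
  # (BMI > 35 kg/m^2); age >= 18 encodes the adult inclusion criterion.
  data.frame(
    variable = sim_variables(),
    lo = c(18, 100, 35, 40, 40, 70, 40, NA, 60, 10, NA),
    hi = c(90, 230, 80, 250, 250, 250, 150, NA, 500, 150, NA),
    stringsAsFactors = FALSE)
}

.default_correlation <- function() {
  vars <- sim_variables()
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  set_r <- function(a, b, v) {
    R[a, b] <<- v; R[b, a] <<- v
  }
  # adiposity block: moderate positives
  set_r("waist", "hip", 0.60)
  set_r("waist", "bmi", 0.70)
  set_r("hip", "bmi", 0.65)
  # metabolic couplings: weak
  set_r("glucose", "triglycerides", 0.20)
  set_r("triglycerides", "hdl", -0.30)
  # blood-pressure physiology and age gradient
  set_r("sbp", "dbp", 0.60)
  set_r("age", "sbp", 0.20)
  set_r("age", "glucose", 0.20)
  R
}

#' Default synthetic-cohort configuration
#'
#' Emulates a two-sex severely obese adult cohort: n = 1912 with male
#' fraction 0.116; per-sex marginal means/SDs set to the published per-sex
#' summary statistics of such a cohort (e.g. male triglycerides
#' 164.7 +/- 87.0 mg/dL, female HDL 50.7 +/- 12.7 mg/dL); triglycerides and
#' glucose lognormal (right-skewed), the rest truncated normal; a shared
#' latent correlation matrix with moderate positive adiposity couplings,
#' weak metabolic couplings and an SBP-DBP/age coupling (every entry
#' user-overridable); treatment-flag probabilities 0 (no published
#' comorbidity prevalences).
#'
#' @param n Cohort size.
#' @param seed Default seed carried in the config.
#' @return Object of class `sim_config`.
#' @export
default_config <- function(n = 1912, seed = 1L) {
  cfg <- structure(list(
    n = as.integer(n),
    male_fraction = 0.116,
    marginals = .default_marginals(),
    bounds = .default_bounds(),
    correlation = .default_correlation(),
    treatment_probabilities = c(lipid = 0, htn = 0, t2dm = 0),
    seed = as.integer(seed)),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param config A `sim_config`.
#' @return `config`, invisibly; errors on violation.
#' @export
validate_sim_config <- function(config) {
  stopifnot(config$n >= 1,
            config$male_fraction >= 0, config$male_fraction <= 1,
            all(config$treatment_probabilities >= 0),
            all(config$treatment_probabilities <= 1))
  vars <- sim_variables()
  for (sx in c("male", "female")) {
    m <- config$marginals[[sx]]
    stopifnot(identical(m$variable, vars), all(m$sd > 0),
              all(m$family %in% c("normal", "lognormal")))
  }
  R <- config$correlation
  stopifnot(is.matrix(R), nrow(R) == length(vars),
            identical(rownames(R), vars),
            max(abs(R - t(R))) < 1e-12,
            max(abs(diag(R) - 1)) < 1e-12)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("correlation matrix is not positive definite")
  invisible(config)
}

# --- truncated-normal machinery -------------------------------------------

# Mean and SD of N(mu, sigma) truncated to [lo, hi].
.trunc_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  phi_a <- ifelse(is.finite(a), stats::dnorm(a), 0)
  phi_b <- ifelse(is.finite(b), stats::dnorm(b), 0)
  aphi_a <- ifelse(is.finite(a), a * phi_a, 0)
  bphi_b <- ifelse(is.finite(b), b * phi_b, 0)
  d <- (phi_a - phi_b) / Z
  m <- mu + sigma * d
  v <- sigma^2 * (1 + (aphi_a - bphi_b) / Z - d^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Pre-truncation (mu, sigma) such that the [lo, hi]-truncated normal has the
# target mean/SD.  When the bounds sit further than 6 target SDs away the
# truncation is immaterial and (mean, sd) is returned directly.
.solve_truncnorm <- function(mean, sd, lo, hi) {
  lo <- ifelse(is.na(lo), -Inf, lo)
  hi <- ifelse(is.na(hi), Inf, hi)
  if ((!is.finite(lo) || lo < mean - 6 * sd) &&
      (!is.finite(hi) || hi > mean + 6 * sd))
    return(c(mu = mean, sigma = sd, lo = lo, hi = hi))
  obj <- function(par) {
    mo <- .trunc_moments(par[1], exp(par[2]), lo, hi)
    ((mo["mean"] - mean) / sd)^2 + ((mo["sd"] - sd) / sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  if (fit$value > 1e-10)
    stop(sprintf("cannot match truncated-normal moments (mean %.3g, sd %.3g, bounds [%.3g, %.3g])",
                 mean, sd, lo, hi))
  c(mu = fit$par[1], sigma = exp(fit$par[2]), lo = lo, hi = hi)
}

# Quantile transform u in (0,1) -> truncated normal.
.qtruncnorm <- function(u, mu, sigma, lo, hi) {
  pa <- stats::pnorm(lo, mu, sigma)
  pb <- stats::pnorm(hi, mu, sigma)
  x <- stats::qnorm(pa + u * (pb - pa), mu, sigma)
  pmin(pmax(x, lo), hi)
}

# Lognormal parameters hitting a target mean/SD exactly.
.lnorm_params <- function(mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  c(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a synthetic cohort
#'
#' Gaussian-copula draw: each subject's sex is Bernoulli(male_fraction); a
#' latent multivariate standard normal with the configured correlation
#' matrix is drawn per subject and each coordinate is pushed through its
#' configured marginal — truncated normal via the inverse CDF (with the
#' pre-truncation parameters solved so the truncated marginal hits the
#' configured mean/SD exactly), lognormal via exact moment-matched
#' parameters.  Body weight is derived as `bmi * height_m^2`; blood
#' pressures are rounded to the nearest 5 mmHg, mirroring sphygmomanometer
#' reading conventions; treatment flags are independent Bernoulli draws.
#' Fully reproducible given `(config, seed)`.
#'
#' @param config A `sim_config` from [default_config()] (possibly edited).
#' @param seed Integer seed; defaults to the seed stored in the config.
#' @return A `cohort` (see [read_cohort()]) with attribute `sim_report`
#'   (see [sim_report()]).
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  validate_sim_config(config)
  vars <- sim_variables()
  k <- length(vars)
  L <- chol(config$correlation)
  set.seed(seed)
  n <- config$n
  sex <- ifelse(stats::runif(n) < config$male_fraction, "male", "female")
  X <- matrix(NA_real_, n, k, dimnames = list(NULL, vars))
  bounds <- config$bounds
  for (sx in c("male", "female")) {
    idx <- which(sex == sx)
    if (!length(idx)) next
    Z <- matrix(stats::rnorm(length(idx) * k), ncol = k) %*% L
    U <- stats::pnorm(Z)
    marg <- config$marginals[[sx]]
    for (j in seq_len(k)) {
      if (marg$family[j] == "lognormal") {
        p <- .lnorm_params(marg$mean[j], marg$sd[j])
        X[idx, j] <- stats::qlnorm(U[, j], p["meanlog"], p["sdlog"])
      } else {
        p <- .solve_truncnorm(marg$mean[j], marg$sd[j],
                              bounds$lo[j], bounds$hi[j])
        X[idx, j] <- .qtruncnorm(U[, j], p["mu"], p["sigma"], p["lo"], p["hi"])
      }
    }
  }
  tp <- config$treatment_probabilities
  df <- data.frame(
    id = sprintf("S%05d", seq_len(n)),
    sex = ifelse(sex == "male", "M", "F"),
    age = X[, "age"],
    weight = X[, "bmi"] * (X[, "height"] / 100)^2,
    height = X[, "height"],
    waist = X[, "waist"],
    hip = X[, "hip"],
    sbp = round(X[, "sbp"] / 5) * 5,
    dbp = round(X[, "dbp"] / 5) * 5,
    glucose = X[, "glucose"],
    total_chol = X[, "total_chol"],
    hdl = X[, "hdl"],
    triglycerides = X[, "triglycerides"],
    lipid_treated = stats::rbinom(n, 1, tp["lipid"]),
    htn_treated = stats::rbinom(n, 1, tp["htn"]),
    t2dm_diagnosed = stats::rbinom(n, 1, tp["t2dm"]),
    stringsAsFactors = FALSE)
  cohort <- suppressWarnings(as_cohort(df))
  attr(cohort, "sim_report") <- sim_report(cohort, seed = seed)
  cohort
}

#' Summarise a (simulated) cohort: realized moments and prevalence
#'
#' Everything in the report is recomputable exactly from the emitted
#' cohort; the seed is echoed for provenance.
#'
#' @param cohort A `cohort`.
#' @param seed Seed echo (optional).
#' @return List with `n`, per-sex realized means/SDs (`moments`), realized
#'   MetS prevalence (`prevalence_pct`) and `seed`.
#' @export
sim_report <- function(cohort, seed = NA_integer_) {
  df <- as.data.frame(cohort)
  num <- c("age", "weight", "height", "waist", "hip", "sbp", "dbp",
           "glucose", "total_chol", "hdl", "triglycerides")
  mom <- do.call(rbind, lapply(c("male", "female"), function(sx) {
    sub <- df[df$sex == sx, num, drop = FALSE]
    if (!nrow(sub)) return(NULL)
    data.frame(sex = sx, variable = num,
               mean = vapply(sub, mean, numeric(1)),
               sd = vapply(sub, stats::sd, numeric(1)),
               n = nrow(sub), row.names = NULL, stringsAsFactors = FALSE)
  }))
  list(n = nrow(df), moments = mom,
       prevalence_pct = classify_cohort(df)$prevalence_pct,
       seed = seed)
}

#' Calibrate latent correlations to a target MetS prevalence
#'
#' Scales the latent correlations among the criterion-driving variables
#' (waist, SBP, DBP, glucose, HDL, triglycerides) by a single multiplier in
#' \[0, 1\], searching by bisection (at most `max_iter` iterations, common
#' random numbers, simulation size `n_sim`) until the realized prevalence
#' is within `tol` of the target.  If the current configuration is already
#' within tolerance the config is returned unchanged (multiplier 1).
#'
#' @param config A `sim_config`.
#' @param target_prevalence Target MetS prevalence as a fraction in (0, 1).
#' @param seed Seed used for every calibration simulation.
#' @param n_sim Simulation size per evaluation.
#' @param tol Acceptable absolute deviation (fraction; default 2 points).
#' @param max_iter Bisection iteration cap.
#' @return The adjusted `sim_config`, with attributes `multiplier` and
#'   `realized_prevalence`.
#' @export
calibrate_prevalence <- function(config, target_prevalence, seed = config$seed,
                                 n_sim = 20000, tol = 0.02, max_iter = 30) {
  stopifnot(target_prevalence > 0, target_prevalence < 1)
  crit <- .criterion_variables()
  scale_config <- function(m) {
    cfg <- config
    R <- cfg$correlation
    block <- rownames(R) %in% crit
    scaled <- R[block, block] * m
    diag(scaled) <- 1
    R[block, block] <- scaled
    cfg$correlation <- R
    cfg
  }
  prev_at <- function(m) {
    cfg <- scale_config(m)
    cfg$n <- as.integer(n_sim)
    classify_cohort(simulate_cohort(cfg, seed = seed))$prevalence_pct / 100
  }
  p1 <- prev_at(1)
  if (abs(p1 - target_prevalence) <= tol) {
    out <- config
    attr(out, "multiplier") <- 1
    attr(out, "realized_prevalence") <- p1
    return(out)
  }
  p0 <- prev_at(0)
  if ((target_prevalence - p0) * (target_prevalence - p1) > 0)
    stop(sprintf(paste0("target prevalence %.3f unattainable within ",
                        "correlation multiplier bounds [0, 1] ",
                        "(realized range %.3f-%.3f)"),
                 target_prevalence, min(p0, p1), max(p0, p1)))
  lo <- 0; hi <- 1; p_lo <- p0; p_hi <- p1
  m <- NA_real_; p_m <- NA_real_
  for (i in seq_len(max_iter)) {
    m <- (lo + hi) / 2
    p_m <- prev_at(m)
    if (abs(p_m - target_prevalence) <= tol) break
    if ((target_prevalence - p_lo) * (target_prevalence - p_m) <= 0) {
      hi <- m; p_hi <- p_m
    } else {
      lo <- m; p_lo <- p_m
    }
  }
  if (abs(p_m - target_prevalence) > tol)
    stop("prevalence calibration did not converge within iteration cap")
  out <- scale_config(m)
  attr(out, "multiplier") <- m
  attr(out, "realized_prevalence") <- p_m
  out
}

#' Write a simulation configuration to a flat YAML file
#'
#' @param config A `sim_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  vars <- sim_variables()
  obj <- list(
    n = config$n,
    male_fraction = config$male_fraction,
    seed = config$seed,
    treatment_probabilities = as.list(config$treatment_probabilities),
    marginals = lapply(config$marginals, function(m) {
      stats::setNames(lapply(seq_len(nrow(m)), function(i)
        list(mean = m$mean[i], sd = m$sd[i], family = m$family[i])),
        m$variable)
    }),
    bounds = stats::setNames(lapply(seq_len(nrow(config$bounds)), function(i)
      list(lo = config$bounds$lo[i], hi = config$bounds$hi[i])),
      config$bounds$variable),
    correlation = stats::setNames(
      lapply(seq_len(nrow(config$correlation)),
             function(i) as.list(unname(config$correlation[i, ]))),
      vars))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' @param path Path written by [write_sim_config()].
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  obj <- yaml::read_yaml(path)
  vars <- sim_variables()
  marg <- lapply(obj$marginals, function(m) {
    data.frame(variable = names(m),
               family = vapply(m, function(e) e$family, character(1)),
               mean = vapply(m, function(e) as.numeric(e$mean), numeric(1)),
               sd = vapply(m, function(e) as.numeric(e$sd), numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  bounds <- data.frame(
    variable = names(obj$bounds),
    lo = vapply(obj$bounds, function(e) ifelse(is.null(e$lo), NA_real_, as.numeric(e$lo)), numeric(1)),
    hi = vapply(obj$bounds, function(e) ifelse(is.null(e$hi), NA_real_, as.numeric(e$hi)), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  R <- do.call(rbind, lapply(obj$correlation, function(r) as.numeric(r)))
  dimnames(R) <- list(vars, vars)
  cfg <- structure(list(
    n = as.integer(obj$n),
    male_fraction = as.numeric(obj$male_fraction),
    marginals = marg,
    bounds = bounds,
    correlation = R,
    treatment_probabilities = unlist(obj$treatment_probabilities),
    seed = as.integer(obj$seed)),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> n = %d, male fraction %.3f, seed %d\n",
              x$n, x$male_fraction, x$seed))
  cat("  marginals (male | female):\n")
  m <- x$marginals
  for (i in seq_along(sim_variables()))
    cat(sprintf("    %-13s %7.1f +/- %5.1f | %7.1f +/- %5.1f  [%s]\n",
                m$male$variable[i], m$male$mean[i], m$male$sd[i],
                m$female$mean[i], m$female$sd[i], m$male$family[i]))
  invisible(x)
}
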