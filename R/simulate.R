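#' Simulation configuration for a synthetic activity-genetics cohort
#'
#' Bundles every parameter of the synthetic data-generating process: a
#' proportional-hazards obesity onset model with monthly piecewise-constant
#' hazard, a lognormal daily step process with device-artifact days, an
#' encounter-driven BMI observation process, polygenic scores loaded on
#' ancestry principal components, and covariate missingness.
#'
#' The hazard for obesity onset is piecewise constant over months since
#' monitoring start:
#' \deqn{\lambda(t) = \lambda_0 \exp(\beta_{PRS} \cdot PRS +
#'   \beta_{steps} (S_m - 8000)/1000 + \beta_q ((S_m - 8000)/1000)^2 +
#'   \sum_j \beta_j (Z_j - c_j))}
#' where \eqn{S_m} is the latent (artifact-free) mean daily step count of
#' month \eqn{m} and continuous inputs are centred (steps at 8000/day,
#' age at 52 years, systolic blood pressure at 125 mm Hg) so that
#' `baseline_hazard_rate` is interpretable as the event rate of an average
#' participant; centring shifts only the baseline hazard, not the
#' log-hazard-ratio coefficients a correctly specified model recovers.
#'
#' @param n_participants number of participants.
#' @param follow_up_years follow-up horizon in years (must be at least 1,
#'   otherwise the 6-month incident-obesity landmark is undefined).
#' @param seed integer seed; identical seed and configuration give a
#'   byte-identical cohort.
#' @param baseline_hazard_rate obesity onset rate, events per person-year,
#'   for an average participant.
#' @param beta_prs log hazard ratio per 1 SD of the polygenic score.
#' @param beta_steps log hazard ratio per 1000 steps/day.
#' @param beta_steps_quadratic curvature on the log-hazard scale per
#'   (1000 steps/day)^2, centred at 8000 steps/day; zero gives the linear
#'   truth, a large value lets spline machinery demonstrate nonlinearity.
#' @param beta_covariates named log hazard ratios for the baseline
#'   covariates (age per year, sex male vs female, cancer, coronary artery
#'   disease, systolic blood pressure per mm Hg, alcohol use, educational
#'   level indicators; an optional `baseline_bmi` entry, per BMI unit,
#'   gives true baseline BMI a direct hazard effect).
#' @param step_log_mean population mean of log daily steps.
#' @param step_between_sd between-person SD of the log-step intercept.
#' @param step_within_sd within-person day-to-day SD of log steps
#'   (must be positive).
#' @param p_low_wear probability that a day is a low-wear day
#'   (wear time below 10 hours, removed downstream).
#' @param p_extreme_steps probability that a recorded step count is a
#'   device artifact outside the 100--45000 validity range.
#' @param encounter_rate clinic visits per person-year generating BMI
#'   records.
#' @param documentation_only if `TRUE` (default) obesity is only observable
#'   at the first clinical encounter after latent onset, mimicking EHR
#'   documentation delay; if `FALSE` a BMI record is also placed exactly at
#'   onset.
#' @param missing_rate per-variable probability of a missing baseline
#'   covariate.
#' @param missing_vars covariates subject to missingness.
#' @param mar_on_age if `TRUE`, missingness probability increases with age
#'   (missing at random) instead of being completely at random.
#' @param baseline_bmi_mean,baseline_bmi_sd distribution of true baseline
#'   BMI (kg/m^2).
#' @param pc_loadings length-10 loadings of the polygenic score on the
#'   simulated principal components; nonzero loadings make PC
#'   residualization a nontrivial step.
#' @param origin_date calendar date of monitoring start (absolute dates
#'   never matter downstream; all analysis time is years since each
#'   person's monitoring start).
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
sim_config <- function(n_participants = 1000,
                       follow_up_years = 5,
                       seed = 1,
                       baseline_hazard_rate = 0.08,
                       beta_prs = 0.5,
                       beta_steps = -0.4,
                       beta_steps_quadratic = 0,
                       beta_covariates = c(
                         baseline_age = 0.01, sex = 0.1, cancer = 0.1,
                         cad = 0.15, sbp = 0.004, alcohol = 0.05,
                         education_some_college = -0.05,
                         education_college = -0.1
                       ),
                       step_log_mean = log(8300),
                       step_between_sd = 0.35,
                       step_within_sd = 0.25,
                       p_low_wear = 0.05,
                       p_extreme_steps = 0.01,
                       encounter_rate = 2,
                       documentation_only = TRUE,
                       missing_rate = 0.2,
                       missing_vars = c("sbp", "alcohol", "education", "smoking"),
                       mar_on_age = FALSE,
                       baseline_bmi_mean = 26,
                       baseline_bmi_sd = 2,
                       pc_loadings = c(0.2, 0.2, rep(0, 8)),
                       origin_date = as.Date("2018-01-01")) {
  cfg <- list(
    n_participants = n_participants, follow_up_years = follow_up_years,
    seed = seed, baseline_hazard_rate = baseline_hazard_rate,
    beta_prs = beta_prs, beta_steps = beta_steps,
    beta_steps_quadratic = beta_steps_quadratic,
    beta_covariates = beta_covariates,
    step_log_mean = step_log_mean, step_between_sd = step_between_sd,
    step_within_sd = step_within_sd, p_low_wear = p_low_wear,
    p_extreme_steps = p_extreme_steps, encounter_rate = encounter_rate,
    documentation_only = documentation_only, missing_rate = missing_rate,
    missing_vars = missing_vars, mar_on_age = mar_on_age,
    baseline_bmi_mean = baseline_bmi_mean, baseline_bmi_sd = baseline_bmi_sd,
    pc_loadings = pc_loadings, origin_date = as.Date(origin_date)
  )
  num <- unlist(cfg[c(
    "n_participants", "follow_up_years", "seed", "baseline_hazard_rate",
    "beta_prs", "beta_steps", "beta_steps_quadratic", "beta_covariates",
    "step_log_mean", "step_between_sd", "step_within_sd", "p_low_wear",
    "p_extreme_steps", "encounter_rate", "missing_rate",
    "baseline_bmi_mean", "baseline_bmi_sd", "pc_loadings"
  )])
  if (any(!is.finite(num))) {
    stop("sim_config: all numeric parameters must be finite")
  }
  if (n_participants <= 0) stop("sim_config: n_participants must be > 0")
  if (follow_up_years < 1) {
    stop("sim_config: follow_up_years must be >= 1 (the 6-month landmark is undefined below one year)")
  }
  if (baseline_hazard_rate < 0 || encounter_rate < 0 || missing_rate < 0) {
    stop("sim_config: rates must be >= 0")
  }
  if (step_within_sd <= 0) stop("sim_config: step_within_sd must be > 0")
  if (p_low_wear < 0 || p_low_wear > 1 || p_extreme_steps < 0 || p_extreme_steps > 1) {
    stop("sim_config: mixture probabilities must lie in [0, 1]")
  }
  if (length(pc_loadings) != 10L) stop("sim_config: pc_loadings must have length 10")
  structure(cfg, class = "sim_config")
}

# Month length used by the simulation's piecewise-constant hazard, in days.
.MONTH_DAYS <- 365.25 / 12

# Inverse-CDF sampling of an event time from a piecewise-constant hazard.
# lambda: per-month hazard rates; month_len: month length in years;
# u: uniform draw. Returns the onset time in years, or NA if the total
# cumulative hazard is never reached (censored).
sample_onset <- function(lambda, month_len, u) {
  target <- -log(u)
  cum <- cumsum(lambda * month_len)
  idx <- which(cum >= target)
  if (length(idx) == 0L) return(NA_real_)
  m <- idx[1L]
  before <- if (m == 1L) 0 else cum[m - 1L]
  (m - 1L) * month_len + (target - before) / lambda[m]
}

# Shared daily step-stream machinery: latent lognormal steps plus
# device-artifact corruption and a wear-time mixture.
# Returns a list of vectors of length n * n_days (person-major order).
.step_stream <- function(n, n_days, intercepts, within_sd,
                         p_low_wear, p_extreme_steps) {
  total <- n * n_days
  log_steps <- rep(intercepts, each = n_days) + rnorm(total, 0, within_sd)
  latent <- exp(log_steps)
  steps <- pmax(0L, as.integer(round(latent)))
  is_ext <- runif(total) < p_extreme_steps
  n_ext <- sum(is_ext)
  if (n_ext > 0L) {
    low <- runif(n_ext) < 0.5
    ext_vals <- integer(n_ext)
    ext_vals[low] <- as.integer(floor(runif(sum(low), 0, 100)))
    ext_vals[!low] <- as.integer(floor(runif(sum(!low), 45001, 60001)))
    steps[is_ext] <- ext_vals
  }
  low_wear <- runif(total) < p_low_wear
  wear <- integer(total)
  wear[low_wear] <- as.integer(floor(runif(sum(low_wear), 120, 600)))
  wear[!low_wear] <- as.integer(floor(runif(sum(!low_wear), 600, 1441)))
  list(steps = steps, wear = wear, latent = latent)
}

#' Simulate one person's daily step series
#'
#' Draws a lognormal daily step stream (person intercept plus day-level
#' noise) with a configurable fraction of low-wear days and of
#' device-artifact step counts outside the 100--45000 validity range, so
#' that downstream curation filters are exercised.
#'
#' @param n_days number of days to simulate (must be positive).
#' @param log_mean person-level mean of log daily steps.
#' @param within_sd day-to-day SD of log steps (zero gives a constant
#'   series).
#' @param p_low_wear probability of a day with wear time below 10 hours.
#' @param p_extreme_steps probability of an artifact step count.
#' @param start_date first calendar day.
#' @param person_id identifier attached to the records.
#' @param seed optional seed for standalone reproducibility.
#'
#' @return A `data.frame` with columns `person_id`, `date`, `steps`,
#'   `wear_minutes`.
#' @export
simulate_step_series <- function(n_days, log_mean, within_sd = 0.25,
                                 p_low_wear = 0.05, p_extreme_steps = 0.01,
                                 start_date = as.Date("2018-01-01"),
                                 person_id = "P00001", seed = NULL) {
  if (n_days <= 0) stop("simulate_step_series: n_days must be positive")
  if (within_sd < 0) stop("simulate_step_series: within_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  s <- .step_stream(1L, as.integer(n_days), log_mean, within_sd,
                    p_low_wear, p_extreme_steps)
  data.frame(
    person_id = rep(person_id, n_days),
    date = as.Date(start_date) + 0:(n_days - 1L),
    steps = s$steps,
    wear_minutes = s$wear,
    stringsAsFactors = FALSE
  )
}

#' Generate a complete synthetic cohort
#'
#' Draws a full study population under a known data-generating model:
#' polygenic scores with principal-component loadings, baseline covariates,
#' daily step streams, latent obesity onset from a monthly
#' piecewise-constant proportional-hazards process driven by the latent
#' monthly mean step count, encounter-driven BMI observation (obese values
#' appear only at or after latent onset), and covariate missingness.
#'
#' @param config a [sim_config()] object.
#'
#' @return An object of class `sim_cohort`: a list with elements
#'   `steps` (daily records: `person_id`, `date`, `steps`, `wear_minutes`),
#'   `bmi` (`person_id`, `date`, `bmi`),
#'   `genetics` (`person_id`, `score`, `pc1`..`pc10`),
#'   `covariates` (baseline covariates with injected missingness),
#'   `truth` (per-person ground truth: true score, latent onset time,
#'   step intercept) and `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  n <- as.integer(config$n_participants)
  n_days <- as.integer(round(config$follow_up_years * 365.25))
  fu <- config$follow_up_years
  ids <- sprintf("P%05d", seq_len(n))

  ## --- person-level draws -------------------------------------------------
  pcs <- matrix(rnorm(n * 10L), n, 10L,
                dimnames = list(NULL, paste0("pc", 1:10)))
  z <- rnorm(n)
  prs_true <- as.vector(z + pcs %*% config$pc_loadings)

  baseline_age <- round(pmin(85, pmax(20, rnorm(n, 52, 12))), 1)
  sex <- rbinom(n, 1L, 0.28) # 1 = male, matching the ~72% female cohort
  cancer <- rbinom(n, 1L, 0.23)
  cad <- rbinom(n, 1L, 0.03)
  sbp <- round(rnorm(n, 125, 15), 1)
  alcohol <- rbinom(n, 1L, 0.98)
  education <- sample(c("no_college", "some_college", "college"), n,
                      replace = TRUE, prob = c(0.04, 0.18, 0.78))
  smoking <- rbinom(n, 1L, 0.32)
  intercepts <- config$step_log_mean + rnorm(n, 0, config$step_between_sd)
  baseline_bmi <- round(rnorm(n, config$baseline_bmi_mean, config$baseline_bmi_sd), 1)

  bc <- config$beta_covariates
  bval <- function(nm) if (nm %in% names(bc)) bc[[nm]] else 0
  eta_cov <- bval("baseline_age") * (baseline_age - 52) +
    bval("sex") * sex + bval("cancer") * cancer + bval("cad") * cad +
    bval("sbp") * (sbp - 125) + bval("alcohol") * alcohol +
    bval("education_some_college") * (education == "some_college") +
    bval("education_college") * (education == "college") +
    bval("smoking") * smoking +
    bval("baseline_bmi") * (baseline_bmi - config$baseline_bmi_mean)

  ## --- daily step streams -------------------------------------------------
  stream <- .step_stream(n, n_days, intercepts, config$step_within_sd,
                         config$p_low_wear, config$p_extreme_steps)
  steps_dt <- data.table(
    person_id = rep(ids, each = n_days),
    date = rep(config$origin_date + 0:(n_days - 1L), times = n),
    steps = stream$steps,
    wear_minutes = stream$wear
  )

  ## --- latent monthly exposure and onset ----------------------------------
  month_of_day <- pmin(floor((0:(n_days - 1L)) / .MONTH_DAYS),
                       ceiling(fu * 12) - 1L)
  n_months <- max(month_of_day) + 1L
  latent_mat <- matrix(stream$latent, nrow = n_days, ncol = n) # day x person
  S <- t(rowsum(latent_mat, month_of_day) /
           as.vector(table(month_of_day)))                     # person x month
  month_len <- .MONTH_DAYS / 365.25

  eta_fixed <- config$beta_prs * prs_true + eta_cov
  lam <- config$baseline_hazard_rate *
    exp(eta_fixed + config$beta_steps * (S - 8000) / 1000 +
          config$beta_steps_quadratic * ((S - 8000) / 1000)^2)

  u <- runif(n)
  onset <- vapply(seq_len(n), function(i) {
    sample_onset(lam[i, ], month_len, u[i])
  }, numeric(1))
  onset[!is.na(onset) & onset > fu] <- NA_real_

  ## --- encounter-driven BMI observation -----------------------------------
  n_enc <- rpois(n, config$encounter_rate * fu)
  pid_idx <- c(seq_len(n), rep(seq_len(n), n_enc))   # baseline visit + extras
  t_enc <- c(rep(0, n), runif(sum(n_enc), 0, fu))
  if (!config$documentation_only) {
    onset_obs <- which(!is.na(onset))
    pid_idx <- c(pid_idx, onset_obs)                 # record exactly at onset
    t_enc <- c(t_enc, onset[onset_obs])
  }
  pre <- is.na(onset[pid_idx]) | t_enc < onset[pid_idx]
  prevalent <- baseline_bmi[pid_idx] >= 30
  vals <- numeric(length(t_enc))
  i1 <- pre & !prevalent
  i2 <- pre & prevalent                              # observed obese throughout
  i3 <- !pre
  vals[i1] <- pmin(29.9, baseline_bmi[pid_idx][i1] + rnorm(sum(i1), 0, 0.4))
  vals[i2] <- baseline_bmi[pid_idx][i2] + abs(rnorm(sum(i2), 0, 0.4))
  vals[i3] <- 30 + abs(rnorm(sum(i3), 1, 0.8))
  bmi_dt <- data.table(
    person_id = ids[pid_idx],
    date = config$origin_date + as.integer(round(t_enc * 365.25)),
    bmi = round(pmax(10.1, pmin(99.9, vals)), 1)
  )
  # on same-day collisions keep the higher BMI so documented onsets survive
  setorderv(bmi_dt, c("person_id", "date", "bmi"), order = c(1L, 1L, -1L))
  bmi_dt <- unique(bmi_dt, by = c("person_id", "date"))
  setorderv(bmi_dt, c("person_id", "date"))

  ## --- covariates with missingness ----------------------------------------
  covariates <- data.table(
    person_id = ids, baseline_age = baseline_age, sex = sex,
    cancer = cancer, cad = cad, sbp = sbp, alcohol = alcohol,
    education = education, smoking = smoking, baseline_bmi_true = baseline_bmi
  )
  if (config$missing_rate > 0) {
    for (v in config$missing_vars) {
      if (!v %in% names(covariates)) next
      p <- if (config$mar_on_age) {
        pmin(1, config$missing_rate * 2 *
               stats::plogis((baseline_age - median(baseline_age)) / 10))
      } else {
        rep(config$missing_rate, n)
      }
      miss <- runif(n) < p
      covariates[[v]][miss] <- NA
    }
  }

  genetics <- data.table(person_id = ids, score = prs_true)
  genetics <- cbind(genetics, as.data.table(pcs))

  truth <- data.table(
    person_id = ids, prs_true = prs_true, prs_core = z,
    latent_onset_time = onset, step_intercept = intercepts
  )

  structure(
    list(
      steps = setDF(steps_dt), bmi = setDF(bmi_dt),
      genetics = setDF(genetics), covariates = setDF(covariates),
      truth = setDF(truth), config = config
    ),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic activity-genetics cohort\n")
  cat("  participants:     ", x$config$n_participants, "\n")
  cat("  follow-up:        ", x$config$follow_up_years, "years\n")
  cat("  daily records:    ", nrow(x$steps), "\n")
  cat("  BMI records:      ", nrow(x$bmi), "\n")
  cat("  latent onsets:    ", sum(!is.na(x$truth$latent_onset_time)), "\n")
  invisible(x)
}

#' Write a cohort to plain-text files
#'
#' Writes `steps.csv`, `bmi.csv`, `genetics.csv`, `covariates.csv` (ISO-8601
#' dates, header row, UTF-8) and, for simulated cohorts, `truth.json` with
#' the true parameters and latent onset times.
#'
#' @param x a `sim_cohort` or a compatible list of data frames.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(x$steps, file.path(dir, "steps.csv"), row.names = FALSE)
  utils::write.csv(x$bmi, file.path(dir, "bmi.csv"), row.names = FALSE)
  utils::write.csv(x$genetics, file.path(dir, "genetics.csv"), row.names = FALSE)
  utils::write.csv(x$covariates, file.path(dir, "covariates.csv"), row.names = FALSE)
  if (!is.null(x$truth)) {
    cfg <- x$config
    cfg$origin_date <- as.character(cfg$origin_date)
    jsonlite::write_json(
      list(config = unclass(cfg), participants = x$truth),
      file.path(dir, "truth.json"),
      auto_unbox = TRUE, digits = NA, na = "null"
    )
  }
  invisible(dir)
}

#' Read a cohort from plain-text files
#'
#' Reads the same schema that [write_cohort()] produces (any files absent
#' are returned as `NULL`).
#'
#' @param dir directory containing `steps.csv`, `bmi.csv` and optionally
#'   `genetics.csv`, `covariates.csv`.
#' @return A list with elements `steps`, `bmi`, `genetics`, `covariates`.
#' @export
read_cohort <- function(dir) {
  rd <- function(f, date_cols = NULL) {
    p <- file.path(dir, f)
    if (!file.exists(p)) return(NULL)
    d <- utils::read.csv(p, stringsAsFactors = FALSE)
    for (dc in date_cols) d[[dc]] <- as.Date(d[[dc]])
    d
  }
  list(
    steps = rd("steps.csv", "date"),
    bmi = rd("bmi.csv", "date"),
    genetics = rd("genetics.csv"),
    covariates = rd("covariates.csv")
  )
}
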