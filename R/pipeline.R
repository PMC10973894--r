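#' Hazard-ratio contrast between two percentiles of an exposure
#'
#' Computes `exp(d' beta)` with `d` the design-row difference between the
#' upper and lower percentile of the chosen exposure (PRS at the reference
#' step count, or steps at the reference PRS percentile), with a Wald
#' confidence interval and p-value from the delta-method variance.
#'
#' @param fit a `cox_tv_fit` or `pooled_cox_fit`.
#' @param variable `"prs"` or `"steps"`.
#' @param upper,lower percentiles contrasted (default 75 vs 25).
#' @param reference as in [hr_curve()].
#' @return A list with `hr`, `ci_low`, `ci_high`, `p`, `log_hr`, `se`.
#' @export
hr_contrast <- function(fit, variable = c("prs", "steps"),
                        upper = 75, lower = 25, reference = list()) {
  variable <- match.arg(variable)
  ref_pct <- reference[["prs_percentile"]] %||% 50
  ref_steps <- reference[["steps"]] %||% unname(fit$steps_quantiles["50%"])
  if (variable == "prs") {
    x1 <- .design_rows(fit, ref_steps, .quantile_at(fit$prs_quantiles, upper))
    x0 <- .design_rows(fit, ref_steps, .quantile_at(fit$prs_quantiles, lower))
  } else {
    prs_ref <- .quantile_at(fit$prs_quantiles, ref_pct)
    x1 <- .design_rows(fit, .quantile_at(fit$steps_quantiles, upper), prs_ref)
    x0 <- .design_rows(fit, .quantile_at(fit$steps_quantiles, lower), prs_ref)
  }
  d <- as.vector(x1 - x0)
  est <- sum(d * fit$beta)
  se <- sqrt(drop(t(d) %*% fit$covariance %*% d))
  list(
    hr = exp(est), ci_low = exp(est - 1.96 * se), ci_high = exp(est + 1.96 * se),
    p = pchisq((est / se)^2, 1, lower.tail = FALSE),
    log_hr = est, se = se
  )
}

#' Descriptive characteristics across PRS quartiles
#'
#' Medians with interquartile ranges for continuous variables and counts
#' with percentages for categorical ones, per polygenic-score quartile,
#' with small-cell suppression: counts below the threshold render as
#' `"<threshold"` rather than the exact number.
#'
#' @param x an [assemble_cohort()] result whose cohort carries a `prs`
#'   column.
#' @param suppress_below cell counts below this render as a bound
#'   (default 20).
#' @return A character data frame, one column per quartile.
#' @export
describe_cohort <- function(x, suppress_below = 20) {
  ch <- x$cohort
  if (!"prs" %in% names(ch)) stop("describe_cohort: cohort has no 'prs' column")
  q <- quantile(ch$prs, c(0.25, 0.5, 0.75))
  quart <- cut(ch$prs, c(-Inf, q, Inf), labels = paste0("Q", 1:4))
  med_iqr <- function(v) {
    s <- quantile(v, c(0.5, 0.25, 0.75), na.rm = TRUE)
    sprintf("%.1f (%.1f-%.1f)", s[1], s[2], s[3])
  }
  n_pct <- function(v) {
    k <- sum(v, na.rm = TRUE)
    tot <- sum(!is.na(v))
    ks <- if (k > 0 && k < suppress_below) paste0("<", suppress_below) else as.character(k)
    sprintf("%s/%d (%.0f%%)", ks, tot, 100 * k / tot)
  }
  rows <- list(
    `N` = function(d) as.character(nrow(d)),
    `Age, median (IQR), y` = function(d) med_iqr(d$baseline_age),
    `Women` = function(d) n_pct(d$sex == 0),
    `Baseline BMI, median (IQR)` = function(d) med_iqr(d$baseline_bmi),
    `Baseline steps/d, median (IQR)` = function(d) med_iqr(d$baseline_steps),
    `Cancer` = function(d) n_pct(d$cancer == 1),
    `Coronary artery disease` = function(d) n_pct(d$cad == 1),
    `Alcohol use` = function(d) n_pct(d$alcohol == 1),
    `College degree` = function(d) n_pct(d$education == "college"),
    `Incident obesity` = function(d) n_pct(d$event)
  )
  out <- data.frame(row.names = names(rows))
  for (qq in levels(quart)) {
    d <- ch[quart == qq, , drop = FALSE]
    out[[qq]] <- vapply(rows, function(f) f(d), character(1))
  }
  out
}

#' Pipeline configuration
#'
#' Collects every tunable constant of the end-to-end analysis in one
#' declarative object: input paths (or a simulation configuration),
#' curation thresholds, model name, imputation parameters, inversion grid
#' and incidence table layout.
#'
#' @param simulate a [sim_config()] (or argument list) to generate a
#'   synthetic cohort, or `NULL` to read CSV inputs from `input_dir`.
#' @param input_dir directory with `steps.csv`, `bmi.csv`, `genetics.csv`,
#'   `covariates.csv` (schema of [write_cohort()]).
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param min_wear_hours,step_range,min_valid_days day- and month-level
#'   curation thresholds.
#' @param landmark_months incident-obesity landmark (months).
#' @param baseline_window_days window for the baseline BMI record.
#' @param model `"primary"` or `"bmi_adjusted"`.
#' @param m,k imputation count and donor count.
#' @param seed seed for imputation and bootstrap stages.
#' @param percentiles PRS percentiles for the step-target profile.
#' @param bmi_strata baseline-BMI strata for the profile (used with the
#'   `bmi_adjusted` model).
#' @param step_levels,times incidence-table grid.
#' @param grid_points hazard-ratio curve grid size.
#' @param n_boot bootstrap draws for incidence bands.
#' @param suppress_below small-cell suppression threshold.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = NULL, input_dir = NULL, out_dir = NULL,
                            min_wear_hours = 10, step_range = c(100, 45000),
                            min_valid_days = 15, landmark_months = 6,
                            baseline_window_days = 180,
                            model = "primary", m = 10, k = 5, seed = 7,
                            percentiles = seq(5, 95, by = 5),
                            bmi_strata = NULL,
                            step_levels = c(7500, 10000, 12500),
                            times = c(1, 3, 5), grid_points = 500,
                            n_boot = 200, suppress_below = 20) {
  if (is.null(simulate) && is.null(input_dir)) {
    stop("pipeline_config: provide either a simulation config or an input_dir")
  }
  stopifnot(min_wear_hours > 0, min_valid_days > 0, landmark_months >= 0)
  structure(
    list(
      simulate = simulate, input_dir = input_dir, out_dir = out_dir,
      min_wear_hours = min_wear_hours, step_range = step_range,
      min_valid_days = min_valid_days, landmark_months = landmark_months,
      baseline_window_days = baseline_window_days, model = model,
      m = m, k = k, seed = seed, percentiles = percentiles,
      bmi_strata = bmi_strata, step_levels = step_levels, times = times,
      grid_points = grid_points, n_boot = n_boot,
      suppress_below = suppress_below
    ),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> curate -> score -> fit -> invert ->
#' incidence, logging record counts per stage, and writes a results
#' bundle (`manifest.json`, `attrition.json`, `fit.json`, `targets.csv`,
#' `incidence.csv`, `summary.txt`) when an output directory is
#' configured. A stage failure halts with the stage name; outputs of
#' completed stages are preserved in the returned bundle.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return A list bundle: `cohort_data`, `curated`, `scores`, `fit`
#'   (pooled when imputation ran), `ph_check`, `chunk_tests`,
#'   `contrasts`, `targets`, `baseline_hazard`, `incidence`,
#'   `description`, `nagelkerke`, `summary`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  stage <- "setup"
  bundle <- list()
  on.exit({
    if (!is.null(bundle$error)) message("pipeline halted at stage: ", stage)
  }, add = TRUE)

  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  ## simulate or read ------------------------------------------------------
  dat <- run_stage("input", {
    if (!is.null(config$simulate)) {
      cfg <- config$simulate
      if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, cfg)
      say("simulating cohort: n = ", cfg$n_participants)
      generate_cohort(cfg)
    } else {
      say("reading cohort from ", config$input_dir)
      read_cohort(config$input_dir)
    }
  })
  bundle$cohort_data <- dat

  ## curate ----------------------------------------------------------------
  curated <- run_stage("curate", {
    ages <- NULL
    if (!is.null(dat$covariates) && "baseline_age" %in% names(dat$covariates)) {
      t0 <- as.data.table(dat$steps)[, .(d0 = min(date)), by = person_id]
      idx <- match(t0$person_id, dat$covariates$person_id)
      ages <- data.frame(
        person_id = t0$person_id,
        birth_date = t0$d0 - round(dat$covariates$baseline_age[idx] * 365.25)
      )
    }
    days <- filter_valid_days(
      dat$steps, ages = ages,
      min_wear_minutes = config$min_wear_hours * 60,
      step_range = config$step_range
    )
    say("valid days: ", nrow(days), " of ", nrow(dat$steps))
    monthly <- monthly_means(days, min_valid_days = config$min_valid_days)
    ac <- assemble_cohort(
      monthly, dat$bmi, genetics = dat$genetics, covariates = dat$covariates,
      baseline_window_days = config$baseline_window_days,
      landmark_years = config$landmark_months / 12
    )
    say("analytic cohort: ", nrow(ac$cohort), " persons, ",
        sum(ac$cohort$event), " events")
    ac
  })
  bundle$curated <- curated

  ## score -----------------------------------------------------------------
  curated <- run_stage("score", {
    pcs_cols <- grep("^pc[0-9]+$", names(curated$cohort), value = TRUE)
    if (!"score" %in% names(curated$cohort) || length(pcs_cols) == 0L) {
      stop("cohort carries no polygenic score / principal components")
    }
    resid <- residualize_scores(curated$cohort$score,
                                as.matrix(curated$cohort[, pcs_cols]))
    curated$cohort$prs_residual <- resid
    curated$cohort$prs <- as.vector(scale(resid))
    curated$cohort$prs_percentile <- prs_percentiles(resid)
    say("scores residualized on ", length(pcs_cols), " PCs")
    curated
  })
  bundle$curated <- curated
  bundle$scores <- curated$cohort[, c("person_id", "score", "prs_residual",
                                      "prs", "prs_percentile")]

  nag <- run_stage("score", {
    pcs_cols <- grep("^pc[0-9]+$", names(curated$cohort), value = TRUE)
    covs <- curated$cohort[, c("baseline_age", "sex", pcs_cols)]
    tryCatch(
      incremental_nagelkerke(curated$cohort$event, curated$cohort$prs, covs),
      error = function(e) NULL
    )
  })
  bundle$nagelkerke <- nag

  ## fit ---------------------------------------------------------------------
  fit_res <- run_stage("fit", {
    has_na <- anyNA(curated$cohort[, intersect(
      c("baseline_bmi", "alcohol", "education", "sbp", "smoking"),
      names(curated$cohort)
    )])
    if (has_na) {
      say("fitting ", config$model, " model on m = ", config$m,
          " imputed datasets")
      mi <- fit_cox_mi(curated, m = config$m, k = config$k,
                       seed = config$seed, model = config$model)
      list(fit = mi$pooled, mi = mi)
    } else {
      say("fitting ", config$model, " model (complete data)")
      cp <- build_counting_process(curated)
      list(fit = fit_cox_tv(cp, model = config$model), mi = NULL)
    }
  })
  fit <- fit_res$fit
  bundle$fit <- fit
  bundle$mi <- fit_res$mi

  bundle$chunk_tests <- run_stage("fit", {
    out <- list(interaction = wald_chunk_test(fit, "interaction"))
    for (blk in grep("_nonlinear$", names(fit$term_map), value = TRUE)) {
      out[[blk]] <- wald_chunk_test(fit, blk)
    }
    out
  })
  bundle$ph_check <- run_stage("fit", {
    f1 <- if (!is.null(fit_res$mi)) fit_res$mi$fits[[1]] else fit
    tryCatch(proportional_hazards_check(f1), error = function(e) NULL)
  })
  bundle$contrasts <- run_stage("fit", list(
    prs_75_vs_25 = hr_contrast(fit, "prs"),
    steps_75_vs_25 = hr_contrast(fit, "steps")
  ))

  ## invert ------------------------------------------------------------------
  bundle$targets <- run_stage("invert", {
    say("inverting hazard-ratio curves at ", length(config$percentiles),
        " percentiles")
    steps_vs_prs_profile(
      fit, percentiles = config$percentiles, bmi_strata = config$bmi_strata,
      grid_points = config$grid_points
    )
  })

  ## incidence ---------------------------------------------------------------
  bundle$baseline_hazard <- run_stage("incidence", {
    cp <- if (!is.null(fit_res$mi)) {
      cpx <- build_counting_process(curated)
      ridx <- match(cpx$person_id, curated$cohort$person_id)
      for (v in fit_res$mi$imputations$vars) {
        cpx[[v]] <- fit_res$mi$imputations$datasets[[1]][[v]][ridx]
      }
      cpx
    } else {
      build_counting_process(curated)
    }
    breslow_baseline(fit, cp)
  })
  bundle$incidence <- run_stage("incidence", {
    incidence_table(
      fit, bundle$baseline_hazard, percentiles = c(25, 50, 75),
      step_levels = config$step_levels, times = config$times,
      n_boot = config$n_boot, seed = config$seed
    )
  })

  bundle$description <- run_stage("describe", {
    describe_cohort(curated, suppress_below = config$suppress_below)
  })

  ## summary + manifest ------------------------------------------------------
  bundle$summary <- .pipeline_summary(bundle, config)
  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL
  bundle$manifest <- list(
    package = "steppath",
    version = as.character(utils::packageVersion("steppath")),
    seed = config$seed,
    config_hash = rlang::hash(cfg_for_hash),
    n_analytic = nrow(curated$cohort),
    n_events = sum(curated$cohort$event)
  )

  if (!is.null(config$out_dir)) run_stage("write", .write_bundle(bundle, config))
  say("pipeline complete")
  bundle
}

.pipeline_summary <- function(bundle, config) {
  f <- function(x) formatC(x, format = "fg", digits = 3)
  ct <- bundle$contrasts
  it <- bundle$chunk_tests$interaction
  lines <- c(
    "== steppath analysis summary ==",
    sprintf("Analytic cohort: %d persons, %d incident obesity events",
            nrow(bundle$curated$cohort), sum(bundle$curated$cohort$event)),
    sprintf("HR, 75th vs 25th PRS percentile: %s (95%% CI %s-%s)",
            f(ct$prs_75_vs_25$hr), f(ct$prs_75_vs_25$ci_low),
            f(ct$prs_75_vs_25$ci_high)),
    sprintf("HR, 75th vs 25th steps percentile: %s (95%% CI %s-%s)",
            f(ct$steps_75_vs_25$hr), f(ct$steps_75_vs_25$ci_low),
            f(ct$steps_75_vs_25$ci_high)),
    sprintf("PRS x steps interaction chunk test: chi2 = %s, df = %d, p = %s",
            f(it$chi2), it$df, f(it$p))
  )
  if (!is.null(bundle$nagelkerke)) {
    lines <- c(lines, sprintf(
      "Incremental Nagelkerke R2 of the PRS: %s (beta = %s)",
      f(bundle$nagelkerke$increment), f(bundle$nagelkerke$beta_prs)
    ))
  }
  tg <- bundle$targets
  show <- tg[tg$prs_percentile %in% c(25, 50, 75) &
               (is.na(tg$baseline_bmi) | tg$baseline_bmi == tg$baseline_bmi[1]), ]
  for (i in seq_len(nrow(show))) {
    lines <- c(lines, sprintf(
      "Steps/day at HR 1.00, PRS percentile %g: %s (95%% CI %s-%s)",
      show$prs_percentile[i], f(show$steps_at_unit_hr[i]),
      f(show$ci_low[i]), f(show$ci_high[i])
    ))
  }
  paste(lines, collapse = "\n")
}

.write_bundle <- function(bundle, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  jsonlite::write_json(bundle$manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(bundle$curated$attrition, out("attrition.json"),
                       auto_unbox = TRUE, digits = NA)
  fit <- bundle$fit
  jsonlite::write_json(
    list(
      model = fit$spec$model, beta = as.list(fit$beta),
      covariance = unname(fit$covariance), term_map = fit$term_map,
      n_events = fit$n_events,
      chunk_tests = bundle$chunk_tests,
      contrasts = bundle$contrasts,
      drop_tests = as.list(fit$drop_tests %||% bundle$mi$fits[[1]]$drop_tests)
    ),
    out("fit.json"), auto_unbox = TRUE, digits = NA, na = "null"
  )
  utils::write.csv(bundle$targets, out("targets.csv"), row.names = FALSE)
  utils::write.csv(bundle$incidence, out("incidence.csv"), row.names = FALSE)
  writeLines(bundle$summary, out("summary.txt"))
  utils::write.csv(bundle$description, out("table1.csv"))
  invisible(config$out_dir)
}
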