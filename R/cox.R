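#' Restricted cubic spline basis with three knots
#'
#' Harrell truncated-power parameterization. With knots
#' \eqn{t_1 < t_2 < t_3} and \eqn{d = (t_3 - t_1)^2}, the basis is the
#' identity column plus one nonlinear column
#' \deqn{[(x-t_1)_+^3 - (x-t_2)_+^3 (t_3-t_1)/(t_3-t_2)
#'   + (x-t_3)_+^3 (t_2-t_1)/(t_3-t_2)] / d,}
#' which is linear beyond the boundary knots.
#'
#' @param x numeric vector.
#' @param knots three strictly increasing knot locations.
#' @return Numeric matrix with columns `lin` (= `x`) and `nonlin`.
#' @export
rcs_basis <- function(x, knots) {
  if (length(knots) != 3L) stop("rcs_basis: exactly 3 knots required")
  if (any(diff(knots) <= 0)) stop("rcs_basis: knots must be strictly increasing (no duplicates)")
  t1 <- knots[1]; t2 <- knots[2]; t3 <- knots[3]
  pp3 <- function(u) pmax(u, 0)^3
  d <- (t3 - t1)^2
  nonlin <- (pp3(x - t1) -
               pp3(x - t2) * (t3 - t1) / (t3 - t2) +
               pp3(x - t3) * (t2 - t1) / (t3 - t2)) / d
  cbind(lin = x, nonlin = nonlin)
}

#' Default spline knots at the 10th, 50th and 90th percentiles
#'
#' @param x numeric vector.
#' @param probs knot quantiles (default `c(0.10, 0.50, 0.90)`).
#' @return Numeric vector of knots, or `NULL` when the quantiles are not
#'   strictly increasing (degenerate variable).
#' @export
rcs_knots <- function(x, probs = c(0.10, 0.50, 0.90)) {
  k <- unname(quantile(x, probs, na.rm = TRUE, type = 7))
  if (any(diff(k) <= 0)) return(NULL)
  k
}

#' Expand a curated cohort into counting-process intervals
#'
#' Produces one row per person-month in `(start, stop]` form with that
#' month's mean daily step count as the time-varying exposure. Calendar
#' months that failed the 15-valid-day rule (gaps) carry forward the last
#' observed monthly mean, and are counted in a gap audit; the event is
#' attached to the interval containing the event time, which is truncated
#' there; months after censoring are dropped.
#'
#' @param x an [assemble_cohort()] result.
#' @param covariate_override optional data frame keyed by `person_id`
#'   whose columns replace the cohort's covariate columns (used to push
#'   multiply imputed covariates through without re-curation).
#'
#' @return A `counting_process` data frame with columns `person_id`,
#'   `start`, `stop`, `event`, `steps` (steps/day), `steps_k`
#'   (thousands of steps/day), the person-level covariates, and attributes
#'   `gap_fills` (number of carried-forward months) and `anchor`.
#' @export
build_counting_process <- function(x, covariate_override = NULL) {
  stopifnot(inherits(x, "analytic_cohort"))
  cohort <- x$cohort
  if (!is.null(covariate_override)) {
    idx <- match(cohort$person_id, covariate_override$person_id)
    for (cl in setdiff(names(covariate_override), "person_id")) {
      cohort[[cl]] <- covariate_override[[cl]][idx]
    }
  }
  monthly <- as.data.table(x$monthly)
  anchor <- attr(x$monthly, "anchor")
  if (is.null(anchor)) anchor <- "calendar"
  monthly <- monthly[person_id %in% cohort$person_id]
  setorderv(monthly, c("person_id", "month_index"))

  ms <- data.table(person_id = x$monitoring_start$person_id,
                   t0 = as.Date(x$monitoring_start$start_date))
  ptab <- data.table(person_id = cohort$person_id, time = cohort$time,
                     event = cohort$event)
  ptab <- merge(ptab, ms, by = "person_id", sort = FALSE)

  # full month-index grid per person, gaps carrying the last observed mean
  rng <- monthly[, .(lo = min(month_index), hi = max(month_index)),
                 by = person_id]
  grid <- rng[, .(month_index = seq(lo, hi)), by = person_id]
  grid <- merge(grid, monthly[, .(person_id, month_index, mean_steps)],
                by = c("person_id", "month_index"), all.x = TRUE)
  setorderv(grid, c("person_id", "month_index"))
  gap_fills <- sum(is.na(grid$mean_steps))
  grid[, mean_steps := nafill(mean_steps, type = "locf"), by = person_id]
  grid <- merge(grid, ptab, by = "person_id", sort = FALSE)
  setorderv(grid, c("person_id", "month_index"))

  b <- .month_bounds(grid$t0, grid$month_index, anchor)
  grid[, start := pmax(as.numeric(b$start - t0), 0) / 365.25]
  grid[, stop := as.numeric(b$end - t0) / 365.25]

  # extend beyond the last exposure month up to event/censoring time
  last_rows <- grid[, .I[.N], by = person_id]$V1
  ext <- grid[last_rows][time > stop]
  if (nrow(ext) > 0L) {
    ext[, start := stop]
    ext[, stop := time]
    gap_fills <- gap_fills + nrow(ext)
    grid <- rbind(grid, ext)
    setorderv(grid, c("person_id", "month_index", "start"))
  }

  bad <- grid[, .(first_start = min(start)), by = .(person_id, time)][time <= first_start]
  if (nrow(bad) > 0L) {
    stop("build_counting_process: person(s) ",
         paste(head(bad$person_id, 3), collapse = ", "),
         " have event/censoring before the first exposure month; curation should have excluded them")
  }
  cp <- grid[start < time]
  cp[, stop := pmin(stop, time)]
  cp[, event := event & stop == time]
  cp <- cp[stop > start]
  cp <- cp[, .(person_id, start, stop, event, steps = mean_steps)]
  cp[, steps_k := steps / 1000]

  cov_cols <- setdiff(names(cohort), c("event", "time"))
  cp <- merge(cp, as.data.table(cohort[, cov_cols, drop = FALSE]),
              by = "person_id", sort = FALSE)
  if ("baseline_steps" %in% names(cp)) {
    cp[, baseline_steps_k := baseline_steps / 1000]
  }
  setorder(cp, person_id, start)
  out <- setDF(cp)
  attr(out, "gap_fills") <- gap_fills
  attr(out, "anchor") <- anchor
  class(out) <- c("counting_process", "data.frame")
  out
}

## ---------------------------------------------------------------------------
## Model specification and design construction
## ---------------------------------------------------------------------------

# Internal term table for the named model configurations. Continuous terms
# flagged spline = TRUE start as 3-knot restricted cubic splines; those also
# flagged droppable are subject to the drop-to-linear rule. The interaction
# is linear PRS x (all steps basis columns).
.model_terms <- function(model) {
  terms <- list(
    list(var = "steps", col = "steps_k", type = "spline", droppable = FALSE),
    list(var = "prs", col = "prs", type = "spline", droppable = TRUE),
    list(var = "baseline_age", col = "baseline_age", type = "spline", droppable = TRUE),
    list(var = "sex", col = "sex", type = "binary"),
    list(var = "baseline_steps", col = "baseline_steps_k", type = "linear"),
    list(var = "cancer", col = "cancer", type = "binary"),
    list(var = "cad", col = "cad", type = "binary"),
    list(var = "sbp", col = "sbp", type = "spline", droppable = TRUE),
    list(var = "alcohol", col = "alcohol", type = "binary"),
    list(var = "education", col = "education", type = "factor",
         levels = c("no_college", "some_college", "college"))
  )
  if (model == "bmi_adjusted") {
    terms <- c(terms, list(list(var = "baseline_bmi", col = "baseline_bmi",
                                type = "spline", droppable = TRUE)))
  }
  terms
}

#' Build a Cox model specification
#'
#' Resolves a named model configuration against the data: computes spline
#' knots at the 0.10/0.50/0.90 quantiles of each continuous variable,
#' honours forced-linear terms, and records the interaction structure.
#' Mostly called internally by [fit_cox_tv()]; exposed so a specification
#' fitted on one (e.g. imputed) dataset can be reused verbatim on others.
#'
#' @param data a `counting_process` data frame.
#' @param model `"primary"` (paper adjustment set), `"bmi_adjusted"`
#'   (adds baseline BMI), `"linear"` (all continuous terms linear, for
#'   parameter-recovery work), or `"custom"`.
#' @param linear_terms variables forced to enter linearly.
#' @param interaction include the PRS x steps interaction block.
#' @param knot_probs knot quantiles.
#' @param custom_terms for `model = "custom"`: a list of term definitions,
#'   each a list with `var`, `col`, `type`
#'   (`"spline"`, `"linear"`, `"binary"`, `"factor"`), optional
#'   `droppable` and `levels`.
#'
#' @return An object of class `cox_model_spec`.
#' @export
cox_model_spec <- function(data,
                           model = c("primary", "bmi_adjusted", "linear", "custom"),
                           linear_terms = character(),
                           interaction = TRUE,
                           knot_probs = c(0.10, 0.50, 0.90),
                           custom_terms = NULL) {
  model <- match.arg(model)
  terms <- if (model == "custom") {
    if (is.null(custom_terms)) stop("cox_model_spec: custom model needs custom_terms")
    custom_terms
  } else {
    .model_terms(if (model == "linear") "primary" else model)
  }
  has_interaction <- interaction && model != "custom" ||
    (model == "custom" && interaction && any(vapply(terms, function(t) t$var == "prs", logical(1))))
  for (i in seq_along(terms)) {
    t <- terms[[i]]
    if (!t$col %in% names(data)) {
      stop("cox_model_spec: column '", t$col, "' not found in data")
    }
    if (t$type == "spline") {
      force_lin <- model == "linear" || t$var %in% linear_terms
      k <- if (force_lin) NULL else rcs_knots(data[[t$col]], knot_probs)
      terms[[i]]$knots <- k
      terms[[i]]$is_linear <- is.null(k)
      if (is.null(t$droppable)) terms[[i]]$droppable <- FALSE
    }
    if (t$type %in% c("linear", "binary")) {
      if (length(unique(data[[t$col]][!is.na(data[[t$col]])])) < 2L) {
        stop("cox_model_spec: covariate '", t$col, "' is constant")
      }
    }
  }
  structure(
    list(model = model, terms = terms, interaction = has_interaction,
         knot_probs = knot_probs),
    class = "cox_model_spec"
  )
}

# Build the design matrix and the term -> column map for a specification.
make_design <- function(spec, data) {
  cols <- list()
  term_map <- list()
  add <- function(name, v) {
    cols[[name]] <<- v
    term_map_idx <<- term_map_idx + 1L
    term_map_idx
  }
  term_map_idx <- 0L
  for (t in spec$terms) {
    x <- data[[t$col]]
    if (t$type == "spline" && !t$is_linear) {
      b <- rcs_basis(x, t$knots)
      i1 <- add(t$var, b[, 1])
      i2 <- add(paste0(t$var, "_nl"), b[, 2])
      term_map[[t$var]] <- c(i1, i2)
      term_map[[paste0(t$var, "_nonlinear")]] <- i2
    } else if (t$type == "factor") {
      lv <- t$levels
      f <- factor(as.character(x), levels = lv)
      idx <- integer(0)
      for (l in lv[-1]) {
        idx <- c(idx, add(paste0(t$var, "_", l), as.numeric(f == l)))
      }
      term_map[[t$var]] <- idx
    } else {
      i1 <- add(t$var, as.numeric(x))
      term_map[[t$var]] <- i1
    }
  }
  if (isTRUE(spec$interaction)) {
    prs_lin <- cols[["prs"]]
    if (is.null(prs_lin)) stop("make_design: interaction requested but no prs term")
    steps_idx <- term_map[["steps"]]
    nm <- names(cols)[steps_idx]
    idx <- integer(0)
    for (j in seq_along(steps_idx)) {
      idx <- c(idx, add(paste0("prs_x_", nm[j]), prs_lin * cols[[steps_idx[j]]]))
    }
    term_map[["interaction"]] <- idx
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, term_map = term_map)
}

## ---------------------------------------------------------------------------
## Fitting
## ---------------------------------------------------------------------------

#' Fit the time-varying Cox proportional hazards model
#'
#' Maximizes the counting-process partial likelihood with the Efron tie
#' correction. The default (`"primary"`) model enters current monthly mean
#' steps as a 3-knot restricted cubic spline, the residualized polygenic
#' score, age and systolic blood pressure as 3-knot splines subject to the
#' drop-to-linear rule, sex/cancer/coronary artery disease/alcohol and
#' educational level as indicators, mean baseline step count linearly, and
#' a linear-PRS x steps-spline interaction block (2 df). The
#' `"bmi_adjusted"` model adds baseline BMI; `"linear"` enters every
#' continuous term linearly.
#'
#' The drop-to-linear rule: each droppable spline term's nonlinear column
#' is Wald-tested; terms with p >= `drop_alpha` are refit as linear in a
#' single refit.
#'
#' @param data a `counting_process` data frame (from
#'   [build_counting_process()]), or any data frame with `start`, `stop`,
#'   `event` and the model columns.
#' @param model model configuration name; see [cox_model_spec()].
#' @param spec optionally a ready-made `cox_model_spec` (knots and
#'   linearity decisions are then taken as given and no dropping occurs).
#' @param drop_to_linear apply the drop-to-linear rule (default `TRUE`).
#' @param drop_alpha significance level of the rule (default 0.05).
#' @param interaction,linear_terms,knot_probs,custom_terms passed to
#'   [cox_model_spec()].
#' @param ties tie-handling method, `"efron"` (default) or `"breslow"`.
#'   Efron's correction matters at monthly event-time granularity; exact
#'   invariance of estimates under dataset replication holds only for
#'   Breslow, since Efron deliberately spreads tied events.
#'
#' @return An object of class `cox_tv_fit`: coefficients `beta`,
#'   `covariance`, log partial likelihood `loglik`, `term_map`, the
#'   resolved `spec`, nonlinearity p-values `drop_tests`, event count
#'   `n_events`, reference quantiles of steps and PRS, typical covariate
#'   values `covariate_defaults`, and the underlying [survival::coxph()]
#'   fit.
#' @export
fit_cox_tv <- function(data,
                       model = c("primary", "bmi_adjusted", "linear", "custom"),
                       spec = NULL,
                       drop_to_linear = TRUE,
                       drop_alpha = 0.05,
                       interaction = TRUE,
                       linear_terms = character(),
                       knot_probs = c(0.10, 0.50, 0.90),
                       custom_terms = NULL,
                       ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (sum(data$event) < 1L) stop("fit_cox_tv: no events in data")
  if (is.null(spec)) {
    model <- match.arg(model)
    spec <- cox_model_spec(data, model, linear_terms = linear_terms,
                           interaction = interaction, knot_probs = knot_probs,
                           custom_terms = custom_terms)
    do_drop <- drop_to_linear
  } else {
    do_drop <- FALSE
  }
  fit <- .fit_spec(spec, data, ties)
  drop_tests <- NULL
  if (do_drop) {
    drop_tests <- .nonlinearity_pvalues(fit)
    to_drop <- names(drop_tests)[drop_tests >= drop_alpha]
    droppable <- vapply(spec$terms, function(t) {
      isTRUE(t$droppable) && t$type == "spline" && !t$is_linear
    }, logical(1))
    to_drop <- intersect(to_drop, vapply(spec$terms[droppable], `[[`, "", "var"))
    if (length(to_drop) > 0L) {
      for (i in seq_along(spec$terms)) {
        if (spec$terms[[i]]$var %in% to_drop) {
          spec$terms[[i]]$is_linear <- TRUE
          spec$terms[[i]]$knots <- NULL
        }
      }
      fit <- .fit_spec(spec, data, ties)
    }
  }
  fit$drop_tests <- drop_tests
  fit
}

# Wald p-values of every fitted nonlinear spline column.
.nonlinearity_pvalues <- function(fit) {
  nl <- grep("_nonlinear$", names(fit$term_map), value = TRUE)
  p <- vapply(nl, function(nm) {
    j <- fit$term_map[[nm]]
    z2 <- fit$beta[j]^2 / fit$covariance[j, j]
    pchisq(z2, df = 1, lower.tail = FALSE)
  }, numeric(1))
  names(p) <- sub("_nonlinear$", "", nl)
  p
}

.fit_spec <- function(spec, data, ties = "efron") {
  des <- make_design(spec, data)
  X <- des$X
  if (anyNA(X)) {
    bad <- colnames(X)[colSums(is.na(X)) > 0]
    stop("fit_cox_tv: missing values in model column(s) ",
         paste(bad, collapse = ", "),
         "; impute first (see pmm_impute / fit_cox_mi)")
  }
  surv <- survival::Surv(data$start, data$stop, data$event)
  cf <- withCallingHandlers(
    survival::coxph(surv ~ X, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge|out of iterations", conditionMessage(w))) {
        stop("fit_cox_tv: partial likelihood maximization failed (",
             conditionMessage(w), "); check for monotone likelihood or separation")
      }
      invokeRestart("muffleWarning")
    }
  )
  beta <- coef(cf)
  names(beta) <- colnames(X)
  if (anyNA(beta)) {
    stop("fit_cox_tv: inestimable coefficient(s): ",
         paste(names(beta)[is.na(beta)], collapse = ", "))
  }
  V <- vcov(cf)
  dimnames(V) <- list(names(beta), names(beta))

  # reference summaries used for hazard-ratio curves and profiles
  probs <- 0:100 / 100
  person_rows <- if ("person_id" %in% names(data)) {
    !duplicated(data$person_id)
  } else {
    rep(TRUE, nrow(data))
  }
  steps_q <- if ("steps" %in% names(data)) {
    quantile(data$steps, probs, na.rm = TRUE, type = 7)
  } else {
    NULL
  }
  prs_q <- if ("prs" %in% names(data)) {
    quantile(data$prs[person_rows], probs, na.rm = TRUE, type = 7)
  } else {
    NULL
  }
  # typical covariate values per model column (median for continuous,
  # mode for binary/factor), used when profiling the fitted surface
  covariate_defaults <- list()
  for (t in spec$terms) {
    if (t$col %in% c("steps_k", "prs")) next
    v <- data[[t$col]][person_rows]
    covariate_defaults[[t$col]] <- if (t$type %in% c("binary", "factor")) {
      tb <- sort(table(v), decreasing = TRUE)
      val <- names(tb)[1L]
      if (t$type == "binary") as.numeric(val) else val
    } else {
      median(v, na.rm = TRUE)
    }
  }

  structure(
    list(
      beta = beta, covariance = V, loglik = cf$loglik[2],
      term_map = des$term_map, spec = spec,
      n_events = sum(data$event), n_persons = sum(person_rows),
      steps_quantiles = steps_q, prs_quantiles = prs_q,
      covariate_defaults = covariate_defaults,
      coxph = cf
    ),
    class = "cox_tv_fit"
  )
}

#' @export
print.cox_tv_fit <- function(x, ...) {
  cat("Time-varying Cox model (", x$spec$model, "), ",
      x$n_persons, " persons, ", x$n_events, " events\n", sep = "")
  se <- sqrt(diag(x$covariance))
  tab <- data.frame(
    coef = round(x$beta, 4), `exp(coef)` = round(exp(x$beta), 4),
    se = round(se, 4),
    p = signif(pchisq((x$beta / se)^2, 1, lower.tail = FALSE), 3),
    check.names = FALSE
  )
  print(tab)
  invisible(x)
}

#' Test and apply the drop-to-linear rule for one variable
#'
#' Wald-tests the nonlinear spline column of `variable`; when its p-value
#' is at or above `alpha` the model is refit with the variable entered
#' linearly. Returns the final spline specification together with the
#' nonlinearity p-value and the linear coefficient's p-value in the final
#' model.
#'
#' @param fit a `cox_tv_fit` in which `variable` is fitted as a spline.
#' @param variable variable name (e.g. `"steps"`, `"prs"`).
#' @param data the data the fit was computed on (needed for the refit).
#' @param alpha significance level (default 0.05).
#'
#' @return A list: `variable`, `knots` (`NULL` when linear), `is_linear`,
#'   `p_nonlinear`, `p_linear`, and `fit` (the final model fit).
#' @export
drop_to_linear <- function(fit, variable, data, alpha = 0.05) {
  nl_name <- paste0(variable, "_nonlinear")
  if (!nl_name %in% names(fit$term_map)) {
    stop("drop_to_linear: '", variable, "' is not fitted as a spline")
  }
  j <- fit$term_map[[nl_name]]
  z2 <- fit$beta[j]^2 / fit$covariance[j, j]
  p_nl <- pchisq(z2, 1, lower.tail = FALSE)
  spec <- fit$spec
  final <- fit
  is_linear <- FALSE
  knots <- NULL
  for (i in seq_along(spec$terms)) {
    if (spec$terms[[i]]$var == variable) knots <- spec$terms[[i]]$knots
  }
  if (p_nl >= alpha) {
    for (i in seq_along(spec$terms)) {
      if (spec$terms[[i]]$var == variable) {
        spec$terms[[i]]$is_linear <- TRUE
        spec$terms[[i]]$knots <- NULL
      }
    }
    final <- .fit_spec(spec, data)
    is_linear <- TRUE
    knots <- NULL
  }
  jl <- final$term_map[[variable]][1L]
  zl2 <- final$beta[jl]^2 / final$covariance[jl, jl]
  list(
    variable = variable, knots = knots, is_linear = is_linear,
    p_nonlinear = unname(p_nl),
    p_linear = unname(pchisq(zl2, 1, lower.tail = FALSE)),
    fit = final
  )
}

#' Joint Wald (chunk) test of a coefficient block
#'
#' Computes \eqn{\chi^2 = b' V^{-1} b} over the block's coefficients with
#' degrees of freedom equal to the block size. The PRS x steps interaction
#' block of the default model has 2 df.
#'
#' @param fit a `cox_tv_fit` or pooled fit.
#' @param block block name in the fit's term map (e.g. `"interaction"`,
#'   `"steps"`, `"prs_nonlinear"`).
#' @return A list with `chi2`, `df`, `p`.
#' @export
wald_chunk_test <- function(fit, block) {
  if (!block %in% names(fit$term_map)) {
    stop("wald_chunk_test: block '", block, "' not in term map (",
         paste(names(fit$term_map), collapse = ", "), ")")
  }
  j <- fit$term_map[[block]]
  b <- fit$beta[j]
  V <- fit$covariance[j, j, drop = FALSE]
  Vi <- tryCatch(solve(V), error = function(e) {
    stop("wald_chunk_test: singular covariance for block '", block, "'")
  })
  chi2 <- drop(t(b) %*% Vi %*% b)
  list(chi2 = chi2, df = length(j), p = pchisq(chi2, length(j), lower.tail = FALSE))
}

#' Proportional hazards diagnostics
#'
#' Scaled Schoenfeld residual tests against event time
#' (Kaplan-Meier transform), per model column plus the global test, via
#' [survival::cox.zph()].
#'
#' @param fit a `cox_tv_fit` (must carry its underlying coxph object;
#'   pooled fits do not).
#' @param transform time transform passed to `cox.zph`.
#' @return A data frame with columns `term`, `chisq`, `df`, `p`; the last
#'   row is the global test.
#' @export
proportional_hazards_check <- function(fit, transform = "km") {
  if (is.null(fit$coxph)) {
    stop("proportional_hazards_check: fit does not carry a coxph object (pooled fits cannot be checked directly)")
  }
  if (fit$n_events < 1L) stop("proportional_hazards_check: no events")
  if (fit$n_events == 1L) {
    # a single event defines a residual but no correlation-with-time test
    res <- residuals(fit$coxph, type = "schoenfeld")
    res <- matrix(res, nrow = 1, dimnames = list(NULL, names(fit$beta)))
    out <- data.frame(term = c(names(fit$beta), "GLOBAL"), chisq = NA_real_,
                      df = NA_real_, p = NA_real_)
    attr(out, "residuals") <- res
    return(out)
  }
  z <- survival::cox.zph(fit$coxph, transform = transform, terms = FALSE)
  tab <- as.data.frame(z$table)
  out <- data.frame(
    term = sub("^X", "", rownames(tab)),
    chisq = tab$chisq, df = tab$df, p = tab$p,
    row.names = NULL
  )
  attr(out, "residuals") <- z$y  # scaled Schoenfeld residuals, one row per event
  out
}
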