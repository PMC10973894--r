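# Interpolate a stored percentile table (quantiles at 0..100%) at p.
.quantile_at <- function(q_table, p) {
  stats::approx(0:100, q_table, xout = p, rule = 2)$y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Full design row(s) for given steps (steps/day), PRS value, and a profile
# of fixed covariates; anything unspecified falls back to the typical
# values stored in the fit. Works for any model specification.
.design_rows <- function(fit, steps, prs = NULL, profile = list()) {
  n <- max(length(steps), length(prs), 1L)
  df <- list()
  for (t in fit$spec$terms) {
    val <- if (t$col == "steps_k") {
      steps / 1000
    } else if (t$col == "prs") {
      prs %||% fit$covariate_defaults[["prs"]]
    } else if (t$col == "baseline_steps_k" && !is.null(profile[["baseline_steps"]])) {
      profile[["baseline_steps"]] / 1000
    } else {
      profile[[t$var]] %||% profile[[t$col]] %||% fit$covariate_defaults[[t$col]]
    }
    if (is.null(val)) {
      stop("no value or default for model column '", t$col, "'")
    }
    df[[t$col]] <- rep_len(val, n)
  }
  make_design(fit$spec, as.data.frame(df, stringsAsFactors = FALSE))$X
}

#' Hazard-ratio curve over daily steps for a PRS percentile
#'
#' Evaluates the fitted log hazard ratio of obesity across a grid of mean
#' daily step counts for a person at a given polygenic-score percentile,
#' relative to a reference (by default the 50th PRS percentile at the
#' cohort-median step count, so the reference point is indexed to
#' HR = 1.00). The pointwise variance comes from the delta method,
#' \eqn{v = d' \Sigma d}, with \eqn{d} the design-row difference; the band
#' is \eqn{\pm 1.96 \sqrt{v}}.
#'
#' @param fit a `cox_tv_fit` or `pooled_cox_fit`.
#' @param prs_percentile percentile in (0, 100) at which to evaluate.
#' @param step_grid grid of steps/day; default 500 equally spaced points
#'   spanning the 1st--99th percentile of the observed monthly means.
#' @param reference list with `prs_percentile` (default 50), `steps`
#'   (default the cohort median monthly mean) and optionally
#'   `baseline_bmi`.
#' @param baseline_bmi optional baseline BMI at which to evaluate the
#'   curve side (for BMI-stratified profiles with the `bmi_adjusted`
#'   model); the reference side stays at `reference[["baseline_bmi"]]`.
#' @param grid_points number of grid points when `step_grid` is `NULL`.
#'
#' @return An `hr_curve` data frame with columns `steps`, `log_hr`, `se`,
#'   `lower`, `upper`, and attributes `prs_percentile`, `reference`,
#'   `baseline_bmi`.
#' @export
hr_curve <- function(fit, prs_percentile, step_grid = NULL,
                     reference = list(), baseline_bmi = NULL,
                     grid_points = 500) {
  if (is.null(fit$prs_quantiles)) {
    stop("hr_curve: fit carries no PRS percentile table (was 'prs' in the data?)")
  }
  ref_pct <- reference[["prs_percentile"]] %||% 50
  ref_steps <- reference[["steps"]] %||% unname(fit$steps_quantiles["50%"])
  ref_bmi <- reference[["baseline_bmi"]]
  if (is.null(step_grid)) {
    lo <- .quantile_at(fit$steps_quantiles, 1)
    hi <- .quantile_at(fit$steps_quantiles, 99)
    step_grid <- seq(lo, hi, length.out = grid_points)
  }
  obs_range <- range(fit$steps_quantiles)
  if (min(step_grid) < obs_range[1] || max(step_grid) > obs_range[2]) {
    warning("hr_curve: step grid extends beyond the observed step range; ",
            "spline terms extrapolate linearly there")
  }
  prs_val <- .quantile_at(fit$prs_quantiles, prs_percentile)
  prs_ref <- .quantile_at(fit$prs_quantiles, ref_pct)

  X1 <- .design_rows(fit, step_grid, prs_val,
                     profile = list(baseline_bmi = baseline_bmi))
  X0 <- .design_rows(fit, rep(ref_steps, length(step_grid)), prs_ref,
                     profile = list(baseline_bmi = ref_bmi))
  D <- X1 - X0
  est <- as.vector(D %*% fit$beta)
  v <- rowSums((D %*% fit$covariance) * D)
  se <- sqrt(pmax(v, 0))
  out <- data.frame(
    steps = step_grid, log_hr = est, se = se,
    lower = est - 1.96 * se, upper = est + 1.96 * se
  )
  attr(out, "prs_percentile") <- prs_percentile
  attr(out, "reference") <- list(prs_percentile = ref_pct, steps = ref_steps,
                                 baseline_bmi = ref_bmi)
  attr(out, "baseline_bmi") <- baseline_bmi
  class(out) <- c("hr_curve", "data.frame")
  out
}

#' Dense cubic spline through a hazard-ratio curve
#'
#' Fits a natural interpolating cubic spline through the evaluated
#' log-hazard-ratio grid (the fitted function reproduces the grid values
#' exactly, and is linear beyond the boundary grid points). Errors when
#' the grid has fewer points than the requested knot count.
#'
#' @param curve an [hr_curve()] result.
#' @param knots minimum number of supporting grid points (default 100).
#' @param band which curve to smooth: the estimate or a confidence band
#'   edge.
#' @return A function of steps returning log hazard ratios.
#' @export
fit_dense_spline <- function(curve, knots = 100,
                             band = c("estimate", "lower", "upper")) {
  band <- match.arg(band)
  if (nrow(curve) < knots) {
    stop("fit_dense_spline: ", nrow(curve), " grid points but ", knots,
         " knots requested; evaluate the curve on a denser grid")
  }
  y <- switch(band, estimate = curve$log_hr, lower = curve$lower,
              upper = curve$upper)
  f <- stats::splinefun(curve$steps, y, method = "natural")
  attr(f, "range") <- range(curve$steps)
  f
}

#' Invert a fitted log-hazard-ratio spline at HR = 1.00
#'
#' Finds the step count where the fitted curve crosses zero log hazard
#' ratio by bracketed root finding to 1-step tolerance. Multiple crossings
#' return the smallest with a multiplicity flag; no crossing in bounds
#' returns `NA` together with the sign of the curve (absence is a value,
#' not an error).
#'
#' @param f a function from [fit_dense_spline()].
#' @param bounds search interval in steps/day (defaults to the spline's
#'   grid range).
#' @param tol root tolerance in steps (default 1).
#' @return A list with `steps` (smallest root or `NA`), `roots` (all
#'   crossings), `multiple` flag, and `sign` (sign of the curve when no
#'   crossing exists, otherwise `0`).
#' @export
invert_to_unit_hr <- function(f, bounds = NULL, tol = 1) {
  if (is.null(bounds)) bounds <- attr(f, "range")
  if (is.null(bounds)) stop("invert_to_unit_hr: bounds required")
  xs <- seq(bounds[1], bounds[2], by = tol)
  if (xs[length(xs)] < bounds[2]) xs <- c(xs, bounds[2])
  v <- f(xs)
  roots <- numeric(0)
  exact <- which(v == 0)
  roots <- c(roots, xs[exact])
  flips <- which(v[-1] * v[-length(v)] < 0)
  for (j in flips) {
    r <- uniroot(f, c(xs[j], xs[j + 1]), tol = tol * 1e-3)$root
    roots <- c(roots, r)
  }
  roots <- sort(unique(roots))
  if (length(roots) == 0L) {
    return(list(steps = NA_real_, roots = numeric(0), multiple = FALSE,
                sign = sign(mean(v))))
  }
  list(steps = roots[1L], roots = roots, multiple = length(roots) > 1L,
       sign = 0)
}

#' Invert a hazard-ratio curve and its confidence band to a step target
#'
#' Inverts the point estimate and both 95% band edges of an
#' [hr_curve()] at HR = 1.00 and assembles a step target. For a
#' decreasing curve, inverting the lower log-HR band yields the smaller
#' step bound and the upper band the larger; bounds are sorted so this
#' holds for either curve direction. A band edge with no crossing leaves a
#' one-sided interval; no crossings at all flag the target unattainable
#' within the grid.
#'
#' @param curve an [hr_curve()] result.
#' @param bounds,tol passed to [invert_to_unit_hr()].
#' @param knots passed to [fit_dense_spline()].
#' @return A one-row `data.frame`: `prs_percentile`, `baseline_bmi`,
#'   `steps_at_unit_hr`, `ci_low`, `ci_high`, `flag`
#'   (`"ok"`, `"multiple_crossings"`, `"one_sided"`, `"unattainable"`).
#' @export
ci_band_inversion <- function(curve, bounds = NULL, tol = 1, knots = 100) {
  inv <- function(band) {
    invert_to_unit_hr(fit_dense_spline(curve, knots = knots, band = band),
                      bounds = bounds, tol = tol)
  }
  est <- inv("estimate")
  lo <- inv("lower")
  hi <- inv("upper")
  band_roots <- sort(c(lo$steps, hi$steps), na.last = NA)
  ci <- c(NA_real_, NA_real_)
  flag <- "ok"
  if (length(band_roots) == 2L) {
    ci <- band_roots
  } else if (length(band_roots) == 1L) {
    ci <- if (!is.na(lo$steps)) c(band_roots, NA_real_) else c(NA_real_, band_roots)
    flag <- "one_sided"
  } else {
    flag <- "one_sided"
  }
  if (is.na(est$steps)) flag <- "unattainable"
  if (est$multiple) flag <- "multiple_crossings"
  data.frame(
    prs_percentile = attr(curve, "prs_percentile") %||% NA_real_,
    baseline_bmi = attr(curve, "baseline_bmi") %||% NA_real_,
    steps_at_unit_hr = est$steps, ci_low = ci[1], ci_high = ci[2],
    flag = flag, stringsAsFactors = FALSE
  )
}

#' Daily step targets across the PRS spectrum
#'
#' The signature computation: for each polygenic-score percentile (and
#' optionally each baseline-BMI stratum, using a model that includes
#' baseline BMI) the fitted hazard-ratio curve over daily steps is
#' inverted at HR = 1.00, with confidence limits from inverting the
#' pointwise 95% band edges. Under a direct PRS effect the resulting
#' profile is nondecreasing in percentile.
#'
#' @param fit a `cox_tv_fit` or `pooled_cox_fit`.
#' @param percentiles PRS percentiles to profile (default 5, 10, ..., 95).
#' @param bmi_strata optional baseline BMI values (e.g.
#'   `c(22, 24, 26, 28)`); requires a fit of the `bmi_adjusted` model.
#' @param step_grid,reference,grid_points passed to [hr_curve()].
#' @param tol,knots passed to the inversion.
#'
#' @return A `step_targets` data frame, one row per percentile (x stratum).
#' @export
steps_vs_prs_profile <- function(fit, percentiles = seq(5, 95, by = 5),
                                 bmi_strata = NULL, step_grid = NULL,
                                 reference = list(), grid_points = 500,
                                 tol = 1, knots = 100) {
  strata <- if (is.null(bmi_strata)) list(NULL) else as.list(bmi_strata)
  if (!is.null(bmi_strata) &&
      !"baseline_bmi" %in% vapply(fit$spec$terms, `[[`, "", "var")) {
    stop("steps_vs_prs_profile: baseline-BMI strata need the 'bmi_adjusted' model")
  }
  rows <- list()
  for (b in strata) {
    for (p in percentiles) {
      cv <- hr_curve(fit, p, step_grid = step_grid, reference = reference,
                     baseline_bmi = b, grid_points = grid_points)
      rows[[length(rows) + 1L]] <- ci_band_inversion(cv, tol = tol, knots = knots)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("step_targets", "data.frame")
  out
}
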