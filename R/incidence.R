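#' Breslow baseline cumulative hazard from a fitted Cox model
#'
#' Nonparametric baseline hazard increments at each event time:
#' \deqn{d\Lambda_0(t_k) = d_k / \sum_{(start, stop] \ni t_k} \exp(x'\beta),}
#' with risk-set membership honouring the half-open `(start, stop]`
#' counting-process intervals.
#'
#' @param fit a `cox_tv_fit` or `pooled_cox_fit` (its specification is
#'   used to rebuild the design matrix on `data`).
#' @param data the counting-process data the model was fitted on.
#' @param null_model if `TRUE` the linear predictor is forced to zero, in
#'   which case the estimator reduces exactly to Nelson-Aalen.
#'
#' @return An object of class `breslow_hazard`: a data frame with columns
#'   `time`, `n_events`, `increment`, `cumulative` (a nondecreasing,
#'   right-continuous step function), plus a `max_time` attribute.
#' @export
breslow_baseline <- function(fit, data, null_model = FALSE) {
  if (sum(data$event) < 1L) stop("breslow_baseline: no events in data")
  lp <- if (null_model) {
    rep(0, nrow(data))
  } else {
    as.vector(make_design(fit$spec, data)$X %*% fit$beta)
  }
  w <- exp(lp)
  te <- sort(unique(data$stop[data$event]))
  k <- length(te)
  # each row is at risk for event times te with start < te <= stop:
  # accumulate exp(lp) over te index ranges via a difference array
  lo <- findInterval(data$start, te) + 1L       # first te strictly > start
  hi <- findInterval(data$stop, te)             # last te <= stop
  delta <- numeric(k + 1L)
  act <- lo <= hi
  for (r in which(act)) {
    delta[lo[r]] <- delta[lo[r]] + w[r]
    delta[hi[r] + 1L] <- delta[hi[r] + 1L] - w[r]
  }
  denom <- cumsum(delta[seq_len(k)])
  d <- vapply(te, function(t) sum(data$event & data$stop == t), numeric(1))
  if (any(denom <= 0)) {
    stop("breslow_baseline: empty risk set at event time(s) ",
         paste(signif(te[denom <= 0], 6), collapse = ", "),
         "; counting-process intervals are inconsistent")
  }
  inc <- d / denom
  out <- data.frame(time = te, n_events = d, increment = inc,
                    cumulative = cumsum(inc))
  attr(out, "max_time") <- max(data$stop)
  class(out) <- c("breslow_hazard", "data.frame")
  out
}

# Evaluate the cumulative baseline hazard step function at times t.
.cumhaz_at <- function(baseline, t) {
  idx <- findInterval(t, baseline$time)
  c(0, baseline$cumulative)[idx + 1L]
}

#' Model-based cumulative incidence for a covariate profile
#'
#' \deqn{risk(t) = 1 - \exp(-\Lambda_0(t) e^{x'\beta})} with the profile's
#' mean daily step count held constant over the prediction horizon.
#' Unspecified profile entries default to typical cohort values stored in
#' the fit.
#'
#' @param baseline a [breslow_baseline()] result.
#' @param fit the corresponding model fit.
#' @param profile named list; `steps` (steps/day), and either
#'   `prs_percentile` or `prs`, plus any fixed covariates to override.
#' @param times prediction times in years (default 1, 3, 5).
#'
#' @return A data frame with columns `time` and `risk` (nondecreasing in
#'   time, all values in `[0, 1]`).
#' @export
cumulative_incidence <- function(baseline, fit, profile = list(),
                                 times = c(1, 3, 5)) {
  if (any(times > attr(baseline, "max_time"))) {
    warning("cumulative_incidence: time(s) beyond observed follow-up; ",
            "the baseline hazard is flat there")
  }
  steps <- profile[["steps"]] %||%
    (if (!is.null(fit$steps_quantiles)) unname(fit$steps_quantiles["50%"]) else NULL)
  prs <- profile[["prs"]] %||%
    (if (!is.null(fit$prs_quantiles)) {
      .quantile_at(fit$prs_quantiles, profile[["prs_percentile"]] %||% 50)
    } else NULL)
  if (!is.null(fit$steps_quantiles) && !is.null(steps)) {
    srange <- range(fit$steps_quantiles)
    if (steps < srange[1] || steps > srange[2]) {
      warning("cumulative_incidence: profile steps outside the observed range; ",
              "spline terms extrapolate linearly")
    }
  }
  x <- .design_rows(fit, steps, prs, profile = profile)
  lp <- drop(x %*% fit$beta)
  risk <- 1 - exp(-.cumhaz_at(baseline, times) * exp(lp))
  data.frame(time = times, risk = risk)
}

#' Cumulative incidence table over PRS percentiles and step levels
#'
#' Expected cumulative incidence of obesity on a grid of polygenic-score
#' percentiles and assumed constant mean daily step counts, at the
#' requested horizons. Confidence bands come from a parametric bootstrap:
#' coefficient draws from \eqn{N(\beta, \Sigma)} with the baseline hazard
#' held fixed.
#'
#' @param fit a `cox_tv_fit` or `pooled_cox_fit`.
#' @param baseline a [breslow_baseline()] result.
#' @param percentiles PRS percentiles (default 25, 50, 75).
#' @param step_levels assumed mean daily steps (default 7500, 10000,
#'   12500).
#' @param times horizons in years (default 1, 3, 5).
#' @param ci compute bootstrap bands.
#' @param n_boot bootstrap draws (default 200).
#' @param seed optional seed for the draws.
#'
#' @return An `incidence_table` data frame: `prs_percentile`, `steps`,
#'   `year`, `risk`, `ci_low`, `ci_high`.
#' @export
incidence_table <- function(fit, baseline, percentiles = c(25, 50, 75),
                            step_levels = c(7500, 10000, 12500),
                            times = c(1, 3, 5), ci = TRUE, n_boot = 200,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(prs_percentile = percentiles, steps = step_levels,
                      year = times, KEEP.OUT.ATTRS = FALSE)
  prs_vals <- .quantile_at(fit$prs_quantiles, grid$prs_percentile)
  X <- .design_rows(fit, grid$steps, prs_vals)
  lp <- as.vector(X %*% fit$beta)
  L0 <- .cumhaz_at(baseline, grid$year)
  risk <- 1 - exp(-L0 * exp(lp))
  out <- data.frame(grid, risk = risk, ci_low = NA_real_, ci_high = NA_real_)
  if (ci) {
    draws <- MASS::mvrnorm(n_boot, fit$beta, fit$covariance)
    lp_draws <- X %*% t(draws)                       # cells x draws
    risk_draws <- 1 - exp(-L0 * exp(lp_draws))
    qs <- t(apply(risk_draws, 1L, quantile, probs = c(0.025, 0.975)))
    out$ci_low <- qs[, 1]
    out$ci_high <- qs[, 2]
  }
  class(out) <- c("incidence_table", "data.frame")
  out
}
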