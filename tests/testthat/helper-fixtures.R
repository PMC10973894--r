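# Shared fixtures, built once per test run. Problem sizes are chosen so the
# whole suite stays comfortably within a routine CI run while leaving the
# Monte Carlo checks statistically meaningful.

.fx_env <- new.env(parent = emptyenv())

# Medium cohort (n = 2000, 3 y, linear truth, immediate event
# documentation, no missingness) with both a spline+interaction fit of the
# primary model and a plain linear fit.
fx_medium <- function() {
  if (is.null(.fx_env$medium)) {
    sc <- sim_curated(2000, 3, seed = 2024)
    cp <- build_counting_process(sc$curated)
    fit_primary <- fit_cox_tv(cp, model = "primary")
    fit_linear <- fit_cox_tv(cp, model = "linear", interaction = FALSE)
    sc$cohort$steps <- NULL # free the big daily table
    .fx_env$medium <- list(
      config = sc$config, curated = sc$curated, cp = cp,
      fit = fit_primary, fit_linear = fit_linear
    )
  }
  .fx_env$medium
}

# Large cohort (n = 4000) with a clear PRS effect, used for inversion and
# profile recovery, plus a matched null-PRS cohort for flatness checks.
fx_large <- function() {
  if (is.null(.fx_env$large)) {
    sc <- sim_curated(4000, 3, seed = 77)
    cp <- build_counting_process(sc$curated)
    .fx_env$large <- list(
      config = sc$config, curated = sc$curated, cp = cp,
      fit = fit_cox_tv(cp, model = "linear", interaction = FALSE)
    )
  }
  .fx_env$large
}

fx_large_null <- function() {
  if (is.null(.fx_env$large_null)) {
    sc <- sim_curated(4000, 3, seed = 78, beta_prs = 0)
    cp <- build_counting_process(sc$curated)
    .fx_env$large_null <- list(
      config = sc$config, cp = cp,
      fit = fit_cox_tv(cp, model = "linear", interaction = FALSE)
    )
  }
  .fx_env$large_null
}
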