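# single-interval survival data with one binary covariate
make_simple_surv <- function(n, rate = 0.3, beta = 0, cens = 5, seed = 1) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, rate * exp(beta * x))
  data.frame(person_id = as.character(seq_len(n)), start = 0,
             stop = pmin(t, cens) + seq_len(n) * 1e-9,
             event = t < cens, x = x)
}

fit_simple <- function(d) {
  fit_cox_tv(d, model = "custom", interaction = FALSE,
             custom_terms = list(list(var = "x", col = "x", type = "binary")))
}

test_that("under a null linear predictor Breslow equals Nelson-Aalen exactly", {
  d <- make_simple_surv(300, seed = 2)
  fit <- fit_simple(d)
  bh <- breslow_baseline(fit, d, null_model = TRUE)
  na <- survival::survfit(survival::Surv(stop, event) ~ 1, data = d,
                          ctype = 1, stype = 2)
  expect_equal(bh$cumulative, na$cumhaz[na$n.event > 0], tolerance = 1e-12)
  # and risk reduces to 1 - exp(-Nelson-Aalen), the Breslow survival form
  fit0 <- fit
  fit0$beta[] <- 0
  ci <- cumulative_incidence(bh, fit0, profile = list(x = 0), times = c(1, 3))
  expect_equal(ci$risk, 1 - exp(-steppath:::.cumhaz_at(bh, c(1, 3))))
})

test_that("one event among identical persons gives increment 1/(n exp(x'b))", {
  n <- 8
  d <- data.frame(person_id = as.character(1:n), start = 0,
                  stop = c(1, 2:n + 0.5), event = c(TRUE, rep(FALSE, n - 1)),
                  x = rep(1, n))
  # a constant covariate cannot be fit; use a hand-made coefficient
  stub <- list(
    beta = c(x = 0.7),
    spec = cox_model_spec(
      data.frame(x = c(0, 1), start = 0, stop = 1:2, event = c(FALSE, TRUE)),
      model = "custom", interaction = FALSE,
      custom_terms = list(list(var = "x", col = "x", type = "binary"))
    )
  )
  bh <- breslow_baseline(stub, d)
  expect_equal(nrow(bh), 1)
  expect_equal(bh$increment, 1 / (n * exp(0.7)), tolerance = 1e-12)
})

test_that("risk-set membership honours the (start, stop] convention", {
  # person B enters at t = 1; the event at t = 1 must not count them
  d <- data.frame(person_id = c("A", "B"), start = c(0, 1),
                  stop = c(1, 3), event = c(TRUE, FALSE), x = c(1, 1))
  stub <- list(beta = c(x = 0),
               spec = cox_model_spec(
                 data.frame(x = c(0, 1), start = 0, stop = 1:2,
                            event = c(FALSE, TRUE)),
                 model = "custom", interaction = FALSE,
                 custom_terms = list(list(var = "x", col = "x", type = "binary"))))
  bh <- breslow_baseline(stub, d)
  expect_equal(bh$increment, 1) # only A is at risk at t = 1
})

test_that("empty risk sets are reported as interval construction errors", {
  stub <- list(beta = c(x = 0),
               spec = cox_model_spec(
                 data.frame(x = c(0, 1), start = 0, stop = 1:2,
                            event = c(FALSE, TRUE)),
                 model = "custom", interaction = FALSE,
                 custom_terms = list(list(var = "x", col = "x", type = "binary"))))
  # a zero-length interval (start == stop) covers no event time under the
  # half-open (start, stop] convention, so nobody is at risk at t = 2
  d <- data.frame(person_id = c("A", "B"), start = c(0, 2), stop = c(1, 2),
                  event = c(FALSE, TRUE), x = c(1, 1))
  expect_error(breslow_baseline(stub, d), "empty risk set")
})

test_that("cumulative hazard matches the exponential closed form at scale", {
  n <- 5000
  d <- make_simple_surv(n, rate = 0.25, beta = 0.4, cens = 6, seed = 3)
  fit <- fit_simple(d)
  bh <- breslow_baseline(fit, d)
  # baseline (x = 0) truth: Lambda0(t) = 0.25 t
  for (t in c(1, 3, 5)) {
    got <- steppath:::.cumhaz_at(bh, t)
    expect_lt(abs(got - 0.25 * t) / (0.25 * t), 0.05)
  }
  # model-based cumulative incidence within 5% of the closed form, x = 1
  ci <- cumulative_incidence(bh, fit, profile = list(x = 1), times = c(1, 3, 5))
  truth <- 1 - exp(-0.25 * exp(0.4) * c(1, 3, 5))
  expect_lt(max(abs(ci$risk - truth) / truth), 0.05)
})

test_that("risk is zero at time zero and follows the closed form", {
  fx <- fx_medium()
  bh <- breslow_baseline(fx$fit_linear, fx$cp)
  ci0 <- cumulative_incidence(bh, fx$fit_linear, times = 0)
  expect_equal(ci0$risk, 0)
  # with the coefficient vector zeroed, risk = 1 - exp(-Lambda0)
  fit0 <- fx$fit_linear
  fit0$beta[] <- 0
  bh0 <- breslow_baseline(fit0, fx$cp)
  # engineered baseline: cumulative hazard 0.1 -> risk 0.09516
  bh_stub <- data.frame(time = 0.5, n_events = 1, increment = 0.1,
                        cumulative = 0.1)
  attr(bh_stub, "max_time") <- 3
  class(bh_stub) <- c("breslow_hazard", "data.frame")
  ci <- cumulative_incidence(bh_stub, fit0, times = 1)
  expect_equal(ci$risk, 1 - exp(-0.1), tolerance = 1e-12)
})

test_that("model-based risk agrees with the generating process at a profile", {
  fx <- fx_medium()
  fit <- fx$fit_linear
  bh <- breslow_baseline(fit, fx$cp)
  cfg <- fx$config
  profile <- list(steps = 8000, prs_percentile = 50)
  ci <- cumulative_incidence(bh, fit, profile = profile, times = 3)
  # independent truth: a person with these exact covariate values and
  # constant 8000 steps/day has constant hazard from the generating model
  defs <- fit$covariate_defaults
  bc <- cfg$beta_covariates
  prs_val <- steppath:::.quantile_at(fit$prs_quantiles, 50)
  eta <- cfg$beta_prs * prs_val +
    bc[["baseline_age"]] * (defs$baseline_age - 52) +
    bc[["sex"]] * defs$sex + bc[["cancer"]] * defs$cancer +
    bc[["cad"]] * defs$cad + bc[["sbp"]] * (defs$sbp - 125) +
    bc[["alcohol"]] * defs$alcohol +
    bc[["education_college"]] * (defs$education == "college") +
    bc[["education_some_college"]] * (defs$education == "some_college")
  lam <- cfg$baseline_hazard_rate * exp(eta + cfg$beta_steps * (8000 - 8000) / 1000)
  truth <- 1 - exp(-lam * 3)
  # calibrated agreement: compare cumulative hazards on the log scale with
  # the fit's own uncertainty (delta-method lp variance + Breslow variance
  # of the baseline cumulative hazard, var = sum d_k / denom_k^2)
  x <- steppath:::.design_rows(fit, 8000, prs_val)
  lp <- drop(x %*% fit$beta)
  L0 <- steppath:::.cumhaz_at(bh, 3)
  upto <- bh$time <= 3
  var_L0 <- sum(bh$increment[upto]^2 / bh$n_events[upto])
  se_log <- sqrt(var_L0 / L0^2 + drop(t(as.vector(x)) %*% fit$covariance %*% as.vector(x)))
  z <- abs(log(L0 * exp(lp)) - log(lam * 3)) / se_log
  expect_lt(z, 4)
  # and the crude relative error stays moderate
  expect_lt(abs(ci$risk - truth) / truth, 0.3)
})

test_that("incidence table shows the expected monotonicities in every cell", {
  fx <- fx_medium()
  fit <- fx$fit_linear
  bh <- breslow_baseline(fit, fx$cp)
  tab <- incidence_table(fit, bh, seed = 5)
  expect_true(all(tab$risk >= 0 & tab$risk <= 1))
  expect_true(all(tab$ci_low <= tab$risk & tab$risk <= tab$ci_high))
  # protective steps fitted: risk falls with steps within time x percentile
  expect_lt(fit$beta[["steps"]], 0)
  for (yy in unique(tab$year)) {
    for (p in unique(tab$prs_percentile)) {
      r <- tab$risk[tab$year == yy & tab$prs_percentile == p]
      expect_true(all(diff(r[order(unique(tab$steps))]) <= 0))
    }
    # risk rises with PRS percentile within time x steps
    for (s in unique(tab$steps)) {
      r <- tab$risk[tab$year == yy & tab$steps == s]
      expect_true(all(diff(r[order(unique(tab$prs_percentile))]) >= 0))
    }
  }
  # risk rises with time in every percentile x steps cell
  for (p in unique(tab$prs_percentile)) {
    for (s in unique(tab$steps)) {
      r <- tab$risk[tab$prs_percentile == p & tab$steps == s]
      expect_true(all(diff(r[order(unique(tab$year))]) >= 0))
    }
  }
})

test_that("a null-effect simulation yields a flat incidence table", {
  sc <- sim_curated(1500, 3, seed = 92, beta_prs = 0, beta_steps = 0,
                    beta_covariates = c(sex = 0))
  cp <- build_counting_process(sc$curated)
  fit <- fit_cox_tv(cp, model = "linear", interaction = FALSE)
  bh <- breslow_baseline(fit, cp)
  tab <- incidence_table(fit, bh, ci = FALSE)
  # the table varies only through the fitted (null-truth) step and PRS
  # coefficients; the spread between extreme cells must be explained by
  # their estimation noise (calibrated z bound on the linear predictor)
  x_hi <- steppath:::.design_rows(fit, 7500,
                                  steppath:::.quantile_at(fit$prs_quantiles, 75))
  x_lo <- steppath:::.design_rows(fit, 12500,
                                  steppath:::.quantile_at(fit$prs_quantiles, 25))
  d <- as.vector(x_hi - x_lo)
  z <- abs(sum(d * fit$beta)) / sqrt(drop(t(d) %*% fit$covariance %*% d))
  expect_lt(z, 4)
  # and the fitted null effects themselves are within noise of zero
  for (v in c("steps", "prs")) {
    j <- fit$term_map[[v]]
    expect_lt(abs(fit$beta[j]) / sqrt(fit$covariance[j, j]), 4)
  }
})
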