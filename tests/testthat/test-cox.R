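# --- restricted cubic spline basis ----------------------------------------

test_that("RCS basis matches independently computed symbolic values", {
  # frozen from a symbolic evaluation of the truncated-power formula with
  # knots (2, 5, 11)
  k <- c(2, 5, 11)
  b <- rcs_basis(c(2, 5, 11, 0.5, 7.25, 13), k)
  expect_equal(unname(b[, "lin"]), c(2, 5, 11, 0.5, 7.25, 13))
  expect_equal(unname(b[, "nonlin"]),
               c(0, 1 / 3, 5, 0, 1.5755208333333333, 7),
               tolerance = 1e-12)
})

test_that("RCS nonlinear column vanishes below the first knot", {
  k <- c(10, 20, 30)
  x <- seq(-5, 10, by = 0.5)
  expect_true(all(rcs_basis(x, k)[, "nonlin"] == 0))
})

test_that("RCS is linear beyond the boundary knots (finite differences)", {
  k <- c(2, 5, 11)
  h <- 0.01
  for (x0 in c(12, 15, 40)) {
    f <- function(x) rcs_basis(x, k)[, "nonlin"]
    second <- (f(x0 + h) - 2 * f(x0) + f(x0 - h)) / h^2
    expect_lt(abs(second), 1e-6)
  }
  # and genuinely curved between the knots
  x0 <- 6
  f <- function(x) rcs_basis(x, k)[, "nonlin"]
  expect_gt(abs((f(x0 + h) - 2 * f(x0) + f(x0 - h)) / h^2), 0.1)
})

test_that("degenerate knots are rejected", {
  expect_error(rcs_basis(1:10, c(1, 1, 2)), "strictly increasing")
  expect_error(rcs_basis(1:10, c(1, 2)), "3 knots")
  expect_null(rcs_knots(rep(5, 100)))
})

# --- counting-process construction -----------------------------------------

# build a minimal analytic_cohort by hand
make_ac <- function(monthly_df, cohort_df, start_dates) {
  ms <- data.frame(person_id = names(start_dates),
                   start_date = as.Date(unname(start_dates)))
  attr(monthly_df, "monitoring_start") <- ms
  attr(monthly_df, "anchor") <- "calendar"
  class(monthly_df) <- c("monthly_exposure", "data.frame")
  structure(list(cohort = cohort_df, monthly = monthly_df,
                 attrition = NULL, monitoring_start = ms,
                 landmark_years = 0.5),
            class = "analytic_cohort")
}

month_df <- function(pid, idx, means, t0) {
  b <- steppath:::.month_bounds(as.Date(t0), idx, "calendar")
  data.frame(person_id = pid, month_index = idx, mean_steps = means,
             n_valid_days = 20L, month_start = b$start, month_end = b$end)
}

test_that("censored persons expand to one row per month, all non-events", {
  m <- month_df("A", 0:2, c(7000, 8000, 9000), "2020-01-01")
  stop3 <- as.numeric(as.Date("2020-04-01") - as.Date("2020-01-01")) / 365.25
  ac <- make_ac(m, data.frame(person_id = "A", event = FALSE, time = stop3,
                              prs = 0.5), c(A = "2020-01-01"))
  cp <- build_counting_process(ac)
  expect_equal(nrow(cp), 3)
  expect_false(any(cp$event))
  expect_equal(cp$steps, c(7000, 8000, 9000))
  expect_equal(cp$start[1], 0)
  expect_equal(cp$stop, cummax(cp$stop)) # ordered, disjoint
  expect_true(all(cp$start[-1] == cp$stop[-3]))
})

test_that("the event lands in its containing month, truncated at the event", {
  m <- month_df("A", 0:9, seq(7000, 9700, by = 300), "2020-01-01")
  ac <- make_ac(m, data.frame(person_id = "A", event = TRUE, time = 0.7,
                              prs = 0), c(A = "2020-01-01"))
  cp <- build_counting_process(ac)
  last <- cp[nrow(cp), ]
  expect_equal(last$stop, 0.7)
  expect_true(last$event)
  expect_equal(sum(cp$event), 1)
  # month 9 (index 8 onward) never appears: the event is during month 9
  expect_lt(nrow(cp), 10)
  expect_true(all(cp$stop <= 0.7))
})

test_that("a single month gives a single row starting at zero", {
  m <- month_df("A", 0, 8000, "2020-01-15")
  ac <- make_ac(m, data.frame(person_id = "A", event = FALSE, time = 0.04,
                              prs = 0), c(A = "2020-01-15"))
  cp <- build_counting_process(ac)
  expect_equal(nrow(cp), 1)
  expect_equal(cp$start, 0)
  expect_equal(cp$stop, 0.04)
})

test_that("gap months carry the last observed mean and are audited", {
  m <- month_df("A", c(0, 1, 3), c(7000, 8000, 9000), "2020-01-01")
  ac <- make_ac(m, data.frame(person_id = "A", event = FALSE, time = 0.45,
                              prs = 0), c(A = "2020-01-01"))
  cp <- build_counting_process(ac)
  expect_equal(nrow(cp), 4 + 1) # months 0-3 plus the extension to 0.45
  expect_equal(cp$steps[3], 8000) # gap month 2 carries month 1's mean
  expect_equal(attr(cp, "gap_fills"), 2) # one gap month + one extension
})

test_that("an event before the first exposure month is an error", {
  m <- month_df("A", 2, 8000, "2020-01-01")
  ac <- make_ac(m, data.frame(person_id = "A", event = TRUE, time = 0.05,
                              prs = 0), c(A = "2020-01-01"))
  expect_error(build_counting_process(ac), "before the first exposure month")
})

# --- partial likelihood maximization ---------------------------------------

test_that("the fitter matches the brute-force partial-likelihood oracle", {
  set.seed(501)
  for (i in 1:5) {
    td <- random_tiny_cox_data()
    fit <- fit_cox_tv(
      td$data, model = "custom",
      custom_terms = list(list(var = "x", col = "x", type = "binary")),
      interaction = FALSE
    )
    expect_equal(unname(fit$beta), td$oracle, tolerance = 1e-6)
  }
})

test_that("the score vector vanishes at the maximizer", {
  fx <- fx_medium()
  sc <- colSums(residuals(fx$fit$coxph, type = "score"))
  expect_lt(max(abs(sc)), 1e-6)
})

test_that("coefficients are invariant to replicating the dataset", {
  # replication turns unique event times into ties; the partial likelihood
  # itself is replication-invariant, which the Breslow tie convention
  # preserves exactly (Efron deliberately spreads tied events, so it is
  # only asymptotically invariant)
  set.seed(502)
  td <- random_tiny_cox_data()
  d2 <- td$data
  d2$person_id <- paste0(d2$person_id, "_copy")
  both <- rbind(td$data, d2)
  trm <- list(list(var = "x", col = "x", type = "binary"))
  f1 <- fit_cox_tv(td$data, model = "custom", interaction = FALSE,
                   custom_terms = trm, ties = "breslow")
  f2 <- fit_cox_tv(both, model = "custom", interaction = FALSE,
                   custom_terms = trm, ties = "breslow")
  expect_equal(unname(f1$beta), unname(f2$beta), tolerance = 1e-6)
})

test_that("rescaling a covariate rescales its coefficient inversely", {
  set.seed(503)
  n <- 60
  d <- data.frame(person_id = as.character(1:n), start = 0,
                  stop = sort(rexp(n, 0.3)) + 1e-5 * (1:n),
                  event = rbinom(n, 1, 0.5) > 0, x = rnorm(n, 8000, 2000))
  d$x_k <- d$x / 1000
  t1 <- list(list(var = "x", col = "x", type = "linear"))
  t2 <- list(list(var = "x", col = "x_k", type = "linear"))
  f1 <- fit_cox_tv(d, model = "custom", custom_terms = t1, interaction = FALSE)
  f2 <- fit_cox_tv(d, model = "custom", custom_terms = t2, interaction = FALSE)
  expect_equal(unname(f1$beta) * 1000, unname(f2$beta), tolerance = 1e-6)
})

test_that("the primary model wires splines, indicators and the interaction", {
  fx <- fx_medium()
  tm <- fx$fit$term_map
  expect_true(all(c("steps", "interaction", "sex", "education") %in% names(tm)))
  expect_length(tm$steps, 2)       # spline: linear + nonlinear column
  expect_length(tm$interaction, 2) # linear PRS x both steps columns: 2 df
  expect_length(tm$education, 2)   # three levels -> two indicators
  V <- fx$fit$covariance
  expect_equal(V, t(V), tolerance = 1e-12)
  expect_true(all(eigen(V, symmetric = TRUE, only.values = TRUE)$values > 0))
})

test_that("missing covariates abort the fit with advice to impute", {
  sc <- sim_curated(200, 2, seed = 71, missing_rate = 0.3)
  cp <- build_counting_process(sc$curated)
  expect_error(fit_cox_tv(cp, model = "primary"), "impute")
})

# --- drop-to-linear rule ----------------------------------------------------

test_that("drop_to_linear reports both p-values and refits consistently", {
  fx <- fx_medium()
  cp <- fx$cp
  fit <- fit_cox_tv(cp, model = "primary", drop_to_linear = FALSE)
  out <- drop_to_linear(fit, "prs", cp)
  expect_true(is.finite(out$p_nonlinear) && is.finite(out$p_linear))
  if (out$p_nonlinear >= 0.05) {
    expect_true(out$is_linear)
    expect_null(out$knots)
    expect_false("prs_nonlinear" %in% names(out$fit$term_map))
  } else {
    expect_false(out$is_linear)
    expect_true("prs_nonlinear" %in% names(out$fit$term_map))
  }
  expect_error(drop_to_linear(fit, "sex", cp), "not fitted as a spline")
})

test_that("automatic dropping removes exactly the nonsignificant nonlinearities", {
  fx <- fx_medium()
  fit <- fx$fit # fitted with drop_to_linear = TRUE
  p <- fit$drop_tests
  expect_true(all(c("prs", "baseline_age", "sbp") %in% names(p)))
  for (v in c("prs", "baseline_age", "sbp")) {
    if (p[[v]] >= 0.05) {
      expect_false(paste0(v, "_nonlinear") %in% names(fit$term_map))
    } else {
      expect_true(paste0(v, "_nonlinear") %in% names(fit$term_map))
    }
  }
  # steps is never dropped in the default model
  expect_true("steps_nonlinear" %in% names(fit$term_map))
})

# --- chunk tests ------------------------------------------------------------

test_that("chunk test reproduces chi2 = 1.98, df = 2 -> p = 0.372", {
  # stub fit with an interaction block engineered to chi2 = 1.98
  stub <- list(beta = c(a = sqrt(0.99), b = sqrt(0.99)),
               covariance = diag(2),
               term_map = list(interaction = c(1L, 2L)))
  out <- wald_chunk_test(stub, "interaction")
  expect_equal(out$chi2, 1.98, tolerance = 1e-12)
  expect_equal(out$df, 2)
  expect_equal(out$p, 0.3716, tolerance = 1e-4)
})

test_that("zero coefficients give chi2 = 0, p = 1", {
  stub <- list(beta = c(0, 0), covariance = diag(2),
               term_map = list(blk = c(1L, 2L)))
  out <- wald_chunk_test(stub, "blk")
  expect_equal(out$chi2, 0)
  expect_equal(out$p, 1)
})

test_that("a 1-df chunk equals the squared z-test", {
  fx <- fx_medium()
  fit <- fx$fit_linear
  j <- fit$term_map[["sex"]]
  z2 <- (fit$beta[j] / sqrt(fit$covariance[j, j]))^2
  out <- wald_chunk_test(fit, "sex")
  expect_equal(out$chi2, unname(z2), tolerance = 1e-12)
  expect_equal(out$df, 1)
  expect_error(wald_chunk_test(fit, "nope"), "not in term map")
})

# --- proportional hazards diagnostics ---------------------------------------

test_that("PH check returns per-term rows plus a global test", {
  fx <- fx_medium()
  tab <- proportional_hazards_check(fx$fit_linear)
  expect_equal(tab$term[nrow(tab)], "GLOBAL")
  expect_equal(nrow(tab), length(fx$fit_linear$beta) + 1)
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  res <- attr(tab, "residuals")
  expect_equal(nrow(res), fx$fit_linear$n_events)
})

test_that("a single-event dataset yields a one-row residual table", {
  # the event person sits at the centre of a symmetric covariate so the
  # single-event likelihood has an interior maximum (at zero)
  d <- data.frame(person_id = as.character(1:7), start = 0,
                  stop = c(1, 2, 3, 4, 5, 6, 7),
                  event = c(TRUE, rep(FALSE, 6)),
                  x = c(0, -1, 1, -1, 1, -1, 1))
  fit <- fit_cox_tv(d, model = "custom", interaction = FALSE,
                    custom_terms = list(list(var = "x", col = "x", type = "linear")))
  tab <- proportional_hazards_check(fit)
  expect_equal(nrow(attr(tab, "residuals")), 1)
})

test_that("a strongly time-varying effect is detected, a proportional one rarely", {
  # power side: effect that reverses over time
  set.seed(86)
  n <- 600
  mk <- function(time_varying) {
    x <- rbinom(n, 1, 0.5)
    # piecewise hazard: effect +1.5 before t = 1, -1.5 after
    b1 <- if (time_varying) 1.5 else 0.5
    b2 <- if (time_varying) -1.5 else 0.5
    t1 <- rexp(n, 0.4 * exp(b1 * x))
    t <- ifelse(t1 < 1, t1, 1 + rexp(n, 0.4 * exp(b2 * x)))
    ev <- t < 4
    data.frame(person_id = as.character(1:n), start = 0,
               stop = pmin(t, 4) + (1:n) * 1e-7, event = ev, x = x)
  }
  d <- mk(TRUE)
  fit <- fit_cox_tv(d, model = "custom", interaction = FALSE,
                    custom_terms = list(list(var = "x", col = "x", type = "binary")))
  tab <- proportional_hazards_check(fit)
  expect_lt(tab$p[tab$term == "GLOBAL"], 0.01)

  rejections <- replicate(20, {
    d <- mk(FALSE)
    fit <- fit_cox_tv(d, model = "custom", interaction = FALSE,
                      custom_terms = list(list(var = "x", col = "x", type = "binary")))
    proportional_hazards_check(fit)$p[1] < 0.05
  })
  expect_lte(mean(rejections), 0.25) # nominal 5% level, generous binomial slack
})
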