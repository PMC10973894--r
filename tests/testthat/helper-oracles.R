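# Independent oracles used across the suite. Everything here is written
# deliberately naively (loops, direct enumeration, numeric integration) so
# it stays independent of the package's implementation paths.

# Brute-force Cox partial likelihood for a single coefficient on
# counting-process data with no tied event times: enumerates the product
# of risk-set ratios directly and maximizes by golden-section search.
oracle_cox_1d <- function(d, xcol = "x", interval = c(-15, 15)) {
  negloglik <- function(b) {
    ll <- 0
    for (j in which(d$event)) {
      t <- d$stop[j]
      rs <- d$start < t & t <= d$stop
      ll <- ll + b * d[[xcol]][j] - log(sum(exp(b * d[[xcol]][rs])))
    }
    -ll
  }
  optimize(negloglik, interval, tol = 1e-12)$minimum
}

# Piecewise-constant hazard inversion by numeric integration: integrates
# Lambda(t) on a fine grid and inverts at the exponential draw -log(u).
oracle_onset <- function(lambda, month_len, u, grid_n = 20000) {
  horizon <- length(lambda) * month_len
  ts <- seq(0, horizon, length.out = grid_n)
  lam_at <- lambda[pmin(floor(ts / month_len) + 1L, length(lambda))]
  Lam <- c(0, cumsum(diff(ts) * lam_at[-1]))
  target <- -log(u)
  if (max(Lam) < target) return(NA_real_)
  stats::approx(Lam, ts, xout = target, ties = "ordered")$y
}

# Naive double-loop dot product for genotype scoring.
oracle_score <- function(d, w) {
  out <- numeric(nrow(d))
  for (i in seq_len(nrow(d))) {
    for (j in seq_len(ncol(d))) out[i] <- out[i] + d[i, j] * w[j]
  }
  out
}

# Draw a small random counting-process dataset with a single binary
# covariate, rejecting configurations with ties, fewer than 2 events, a
# constant covariate, or a monotone partial likelihood (oracle optimum at
# the search boundary), so that the maximizer is well-defined.
random_tiny_cox_data <- function() {
  repeat {
    n <- sample(5:8, 1)
    d <- data.frame(
      person_id = as.character(seq_len(n)), start = 0,
      stop = round(sort(runif(n, 0.5, 5)), 3) + 1e-4 * seq_len(n),
      event = rbinom(n, 1, 0.6) > 0, x = rbinom(n, 1, 0.5)
    )
    if (sum(d$event) < 2 || length(unique(d$x)) < 2) next
    if (anyDuplicated(d$stop[d$event])) next
    ob <- oracle_cox_1d(d)
    if (abs(ob) > 4) next
    return(list(data = d, oracle = ob))
  }
}

# One fully curated + scored synthetic cohort, optionally fitted.
sim_curated <- function(n, years, seed, documentation_only = FALSE,
                        missing_rate = 0, ...) {
  cfg <- sim_config(n_participants = n, follow_up_years = years, seed = seed,
                    documentation_only = documentation_only,
                    missing_rate = missing_rate, ...)
  ch <- generate_cohort(cfg)
  mm <- monthly_means(filter_valid_days(ch$steps))
  ac <- assemble_cohort(mm, ch$bmi, genetics = ch$genetics,
                        covariates = ch$covariates)
  res <- residualize_scores(ac$cohort$score,
                            as.matrix(ac$cohort[, paste0("pc", 1:10)]))
  ac$cohort$prs <- as.vector(scale(res))
  ac$cohort$prs_percentile <- prs_percentiles(res)
  list(config = cfg, cohort = ch, curated = ac)
}
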