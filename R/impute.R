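#' Multiple imputation by bootstrap and predictive mean matching
#'
#' For each of `m` rounds and each incomplete variable: draw a bootstrap
#' sample of the rows observed on that variable, fit an additive linear
#' model of the variable on the observed predictors, compute predicted
#' means for both observed and missing rows, and for every missing value
#' copy the observed value of one of the `k` donors whose predicted means
#' are nearest (chosen at random). Categorical variables are matched on a
#' predicted numeric score, so every imputed value is by construction a
#' member of the variable's observed value set.
#'
#' @param data person-level data frame (typically the `cohort` element of
#'   an [assemble_cohort()] result). Missingness must be confined to
#'   baseline BMI, alcohol use, educational level, systolic blood pressure
#'   and smoking status.
#' @param m number of completed datasets (default 10).
#' @param k number of donors (default 5).
#' @param seed optional seed.
#' @param impute_vars variables to impute; defaults to the allowed
#'   variables that actually contain missing values.
#' @param predictors predictor columns; defaults to the complete baseline
#'   variables, the outcome indicator and follow-up time, plus the other
#'   imputation targets (initialized by mean/mode fill).
#'
#' @return An object of class `pmm_imputations`: a list with `datasets`
#'   (list of `m` completed data frames), `m`, `k`, and an `audit` of
#'   missing counts per variable.
#' @export
pmm_impute <- function(data, m = 10, k = 5, seed = NULL,
                       impute_vars = NULL, predictors = NULL) {
  allowed <- c("baseline_bmi", "alcohol", "education", "sbp", "smoking")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  na_cols <- names(data)[vapply(data, anyNA, logical(1))]
  bad <- setdiff(na_cols, allowed)
  if (length(bad) > 0L) {
    stop("pmm_impute: missingness outside the supported variables: ",
         paste(bad, collapse = ", "))
  }
  if (is.null(impute_vars)) impute_vars <- intersect(allowed, na_cols)
  for (v in impute_vars) {
    frac <- mean(is.na(data[[v]]))
    if (frac == 1) stop("pmm_impute: variable '", v, "' is entirely missing")
    if (frac > 0.5) {
      warning("pmm_impute: variable '", v, "' is ",
              round(100 * frac), "% missing; imputations will be weakly informed")
    }
  }
  if (is.null(predictors)) {
    cand <- c("baseline_age", "sex", "baseline_steps", "prs", "score",
              "event", "time", "cancer", "cad", allowed)
    predictors <- setdiff(intersect(cand, names(data)), impute_vars)
    predictors <- c(predictors, intersect(allowed, impute_vars))
    predictors <- unique(predictors)
  }

  # numeric predictor matrix with initial mean/mode fill
  num_col <- function(x) {
    if (is.factor(x) || is.character(x)) as.numeric(factor(x)) else as.numeric(x)
  }
  P <- vapply(predictors, function(cl) num_col(data[[cl]]), numeric(n))
  for (j in seq_len(ncol(P))) {
    nas <- is.na(P[, j])
    if (any(nas)) P[nas, j] <- mean(P[, j], na.rm = TRUE)
  }

  audit <- vapply(impute_vars, function(v) sum(is.na(data[[v]])), integer(1))
  datasets <- vector("list", m)
  for (imp in seq_len(m)) {
    completed <- data
    for (v in impute_vars) {
      yv <- data[[v]]
      mis <- which(is.na(yv))
      if (length(mis) == 0L) next
      obs <- which(!is.na(yv))
      y <- num_col(yv)
      # drop this variable from its own predictor set
      Pj <- P[, setdiff(colnames(P), v), drop = FALSE]
      X <- cbind(1, Pj)
      boot <- sample(obs, length(obs), replace = TRUE)
      b <- stats::lm.fit(X[boot, , drop = FALSE], y[boot])$coefficients
      b[is.na(b)] <- 0
      yhat <- as.vector(X %*% b)
      yhat_obs <- yhat[obs]
      for (mi in mis) {
        dist <- abs(yhat[mi] - yhat_obs)
        kk <- min(k, length(obs))
        donors <- obs[order(dist)[seq_len(kk)]]
        completed[[v]][mi] <- yv[sample(donors, 1L)]
      }
    }
    datasets[[imp]] <- completed
  }
  structure(
    list(datasets = datasets, m = m, k = k, vars = impute_vars, audit = audit),
    class = "pmm_imputations"
  )
}

#' @export
print.pmm_imputations <- function(x, ...) {
  cat("Predictive mean matching imputation: m =", x$m, ", k =", x$k, "\n")
  cat("Missing values imputed per variable:\n")
  print(x$audit)
  invisible(x)
}

#' Pool Cox fits across imputed datasets by Rubin's rules
#'
#' Pooled coefficients are the mean across completed-data fits; the total
#' covariance is the mean within-imputation covariance plus
#' `(1 + 1/m)` times the between-imputation covariance. Per-coefficient
#' degrees of freedom follow the Barnard-Rubin small-sample formula.
#'
#' @param fits list of `cox_tv_fit` objects sharing the same term map.
#' @return An object of class `pooled_cox_fit` (also usable wherever a
#'   `cox_tv_fit`'s coefficients/covariance/term map are needed), with
#'   elements `beta`, `covariance` (total), `within`, `between`, `df`,
#'   `m`, plus the term map, spec and reference quantiles of the first
#'   fit.
#' @export
pool_fits <- function(fits) {
  m <- length(fits)
  if (m == 0L) stop("pool_fits: empty fit list")
  tm0 <- fits[[1]]$term_map
  for (f in fits[-1]) {
    if (!identical(names(f$term_map), names(tm0)) ||
        !identical(unname(f$term_map), unname(tm0))) {
      stop("pool_fits: fits have mismatched term maps; refit with a shared cox_model_spec")
    }
  }
  B_mat <- matrix(0, length(fits[[1]]$beta), length(fits[[1]]$beta))
  betas <- do.call(rbind, lapply(fits, `[[`, "beta"))
  qbar <- colMeans(betas)
  W <- Reduce(`+`, lapply(fits, `[[`, "covariance")) / m
  if (m > 1L) {
    dev <- sweep(betas, 2L, qbar)
    B_mat <- crossprod(dev) / (m - 1)
  } else {
    warning("pool_fits: single imputation; between-imputation variance is zero")
  }
  Tmat <- W + (1 + 1 / m) * B_mat
  dimnames(Tmat) <- dimnames(W)

  # Barnard-Rubin degrees of freedom, per coefficient
  p <- length(qbar)
  nu_com <- max(fits[[1]]$n_events - p, 1)
  bdiag <- pmax(diag(B_mat), 0)
  riv <- (1 + 1 / m) * bdiag / diag(W)
  lam <- pmin(pmax(riv / (1 + riv), 1e-12), 1 - 1e-12)
  nu_old <- (m - 1) / lam^2
  nu_obs <- ((nu_com + 1) / (nu_com + 3)) * nu_com * (1 - lam)
  df <- if (m > 1L) 1 / (1 / nu_old + 1 / nu_obs) else rep(nu_com, p)

  structure(
    list(
      beta = qbar, covariance = Tmat, within = W, between = B_mat,
      df = df, m = m, term_map = tm0, spec = fits[[1]]$spec,
      loglik = mean(vapply(fits, `[[`, numeric(1), "loglik")),
      n_events = fits[[1]]$n_events, n_persons = fits[[1]]$n_persons,
      steps_quantiles = fits[[1]]$steps_quantiles,
      prs_quantiles = fits[[1]]$prs_quantiles,
      covariate_defaults = fits[[1]]$covariate_defaults,
      coxph = NULL
    ),
    class = c("pooled_cox_fit", "cox_tv_fit")
  )
}

#' @export
print.pooled_cox_fit <- function(x, ...) {
  cat("Rubin-pooled time-varying Cox model over m =", x$m, "imputations\n")
  se <- sqrt(diag(x$covariance))
  tab <- data.frame(
    coef = round(x$beta, 4), `exp(coef)` = round(exp(x$beta), 4),
    se = round(se, 4), df = round(x$df, 1),
    check.names = FALSE
  )
  print(tab)
  invisible(x)
}

#' Fit the Cox model on a multiply imputed cohort
#'
#' Convenience wrapper tying [pmm_impute()], [build_counting_process()],
#' [fit_cox_tv()] and [pool_fits()] together. The model specification
#' (spline knots and drop-to-linear decisions) is resolved on the first
#' completed dataset and reused for all others so that coefficients are
#' poolable; covariate overrides are pushed through the counting process
#' without re-curation.
#'
#' @param x an [assemble_cohort()] result.
#' @param m,k,seed imputation parameters; see [pmm_impute()].
#' @param model,... passed to [fit_cox_tv()].
#'
#' @return A list with `pooled` (a `pooled_cox_fit`), `fits`,
#'   `imputations`, and the shared `spec`.
#' @export
fit_cox_mi <- function(x, m = 10, k = 5, seed = NULL, model = "primary", ...) {
  stopifnot(inherits(x, "analytic_cohort"))
  imp <- pmm_impute(x$cohort, m = m, k = k, seed = seed)
  cp <- build_counting_process(x)
  ridx <- match(cp$person_id, x$cohort$person_id)
  fits <- vector("list", m)
  spec <- NULL
  for (i in seq_len(m)) {
    # imputed variables are person-level, so patch the expanded rows in
    # place rather than rebuilding the counting process
    cpi <- cp
    for (v in imp$vars) cpi[[v]] <- imp$datasets[[i]][[v]][ridx]
    if (i == 1L) {
      fits[[i]] <- fit_cox_tv(cpi, model = model, ...)
      spec <- fits[[i]]$spec
    } else {
      fits[[i]] <- fit_cox_tv(cpi, spec = spec)
    }
  }
  list(pooled = pool_fits(fits), fits = fits, imputations = imp, spec = spec)
}
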