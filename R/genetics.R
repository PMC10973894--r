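#' Score genotypes as a weighted allele-dosage sum
#'
#' Computes per-person polygenic scores `score_i = sum_j dosage_ij * w_j`.
#' Missing dosages are mean-imputed per SNP before scoring.
#'
#' @param dosages numeric matrix or data frame, persons in rows, SNPs in
#'   columns, entries in `[0, 2]`.
#' @param weights per-SNP effect sizes: a numeric vector aligned with the
#'   dosage columns, or a data frame with columns `snp_id` and `weight`
#'   matched to the dosage column names.
#'
#' @return Named numeric vector of raw scores.
#' @export
score_genotypes <- function(dosages, weights) {
  d <- as.matrix(dosages)
  if (is.data.frame(weights)) {
    stopifnot(all(c("snp_id", "weight") %in% names(weights)))
    if (is.null(colnames(d))) stop("score_genotypes: dosage columns must be named to match weights by snp_id")
    idx <- match(colnames(d), weights$snp_id)
    if (anyNA(idx)) {
      stop("score_genotypes: no weight for SNP(s) ",
           paste(colnames(d)[is.na(idx)], collapse = ", "))
    }
    w <- weights$weight[idx]
  } else {
    w <- as.numeric(weights)
  }
  if (ncol(d) != length(w)) {
    stop("score_genotypes: ", ncol(d), " dosage columns but ",
         length(w), " weights")
  }
  if (anyNA(d)) {
    for (j in seq_len(ncol(d))) {
      nas <- is.na(d[, j])
      if (any(nas)) d[nas, j] <- mean(d[, j], na.rm = TRUE)
    }
  }
  s <- as.vector(d %*% w)
  names(s) <- rownames(dosages)
  s
}

#' Residualize polygenic scores on principal components
#'
#' Ordinary least squares of the raw score on the ancestry principal
#' components (plus intercept); the residuals, which are orthogonal to
#' every PC column and have mean zero by construction, carry forward as
#' the working polygenic score.
#'
#' @param scores numeric vector of raw scores.
#' @param pcs numeric matrix or data frame of principal components
#'   (persons in rows, typically 10 columns).
#'
#' @return Numeric vector of residuals (names preserved from `scores`).
#' @export
residualize_scores <- function(scores, pcs) {
  p <- as.matrix(pcs)
  n <- length(scores)
  if (nrow(p) != n) stop("residualize_scores: scores and pcs disagree on n")
  if (n <= ncol(p) + 1L) {
    stop("residualize_scores: need more persons than predictors (",
         n, " persons, ", ncol(p), " PCs)")
  }
  x <- cbind(`(Intercept)` = 1, p)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    stop("residualize_scores: PC matrix is rank-deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  res <- stats::lm.fit(x, scores)$residuals
  names(res) <- names(scores)
  res
}

#' Rank-based percentiles of a polygenic score
#'
#' Maps scores to percentiles in (0, 100) using average ranks for ties:
#' `100 * (rank - 0.5) / n`. The mapping is monotone in the score.
#'
#' @param x numeric vector (typically residualized scores).
#' @return Numeric vector of percentiles in (0, 100).
#' @export
prs_percentiles <- function(x) {
  100 * (rank(x, ties.method = "average") - 0.5) / length(x)
}

# Nagelkerke pseudo R-squared from fitted log-likelihoods:
# Cox-Snell R2 = 1 - exp((2/n) (l0 - l1)), divided by its maximum
# 1 - exp((2/n) l0).
.nagelkerke <- function(l1, l0, n) {
  cs <- 1 - exp((2 / n) * (l0 - l1))
  cs / (1 - exp((2 / n) * l0))
}

#' Incremental Nagelkerke R-squared of a polygenic score
#'
#' Fits two maximum-likelihood logistic regressions of a binary obesity
#' status -- the full model with covariates plus the score, and the subset
#' model with covariates only -- and returns the difference of their
#' Nagelkerke R-squared values, together with the score's Wald test.
#' Fitting uses iteratively reweighted least squares (Newton-Raphson for
#' the canonical logit link) with relative log-likelihood convergence
#' tolerance `1e-10` and at most 100 iterations.
#'
#' @param outcome binary 0/1 vector (both classes must be present).
#' @param prs numeric score vector.
#' @param covariates data frame of adjustment covariates (e.g. age, sex,
#'   principal components).
#'
#' @return A list with `increment`, `r2_full`, `r2_subset`, `beta_prs`,
#'   `se_prs`, `p_wald`, `n`, and a `separation` flag.
#' @export
incremental_nagelkerke <- function(outcome, prs, covariates) {
  y <- as.integer(outcome)
  if (length(unique(y[!is.na(y)])) < 2L) {
    stop("incremental_nagelkerke: outcome must have both classes")
  }
  df <- data.frame(y = y, prs = prs, covariates)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  ctrl <- stats::glm.control(epsilon = 1e-10, maxit = 100)
  full <- stats::glm(y ~ ., data = df, family = binomial(), control = ctrl)
  subset_fit <- stats::glm(y ~ . - prs, data = df, family = binomial(), control = ctrl)
  null_fit <- stats::glm(y ~ 1, data = df, family = binomial(), control = ctrl)
  for (f in list(full = full, subset = subset_fit)) {
    if (!f$converged) {
      stop("incremental_nagelkerke: logistic fit did not converge after ",
           f$iter, " iterations (deviance ", format(f$deviance), ")")
    }
  }
  separation <- any(abs(stats::predict(full, type = "link")) > 15)
  if (separation) {
    warning("incremental_nagelkerke: near-complete separation detected; estimates may be unstable")
  }
  l1 <- as.numeric(stats::logLik(full))
  ls <- as.numeric(stats::logLik(subset_fit))
  l0 <- as.numeric(stats::logLik(null_fit))
  sm <- summary(full)$coefficients["prs", ]
  list(
    increment = .nagelkerke(l1, l0, n) - .nagelkerke(ls, l0, n),
    r2_full = .nagelkerke(l1, l0, n),
    r2_subset = .nagelkerke(ls, l0, n),
    beta_prs = unname(sm[1]), se_prs = unname(sm[2]),
    p_wald = unname(sm[4]), n = n, separation = separation
  )
}
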