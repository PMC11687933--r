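# Compositional immunophenotyping
#
# Statistics on immune-cell cluster relative frequencies: extreme-outlier
# fencing, a mean-precision beta regression with logit link fitted by
# maximum likelihood, odds-scale fold-changes with BH correction, and
# age/sex residualization for display.

#' Mask extreme outliers within groups
#'
#' Within each group (conventionally karyotype, per cluster), masks values
#' more than three interquartile ranges below the first or above the third
#' quartile. Groups with fewer than 4 values are skipped with a warning
#' (nothing masked). Masking is idempotent: the mask is computed once from
#' the full data, not re-applied.
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @param k fence multiplier.
#' @param type percentile convention for the quartiles.
#' @return list: `keep` logical vector (`FALSE` = masked), `report` tibble
#'   of masked values, `skipped` group labels too small to fence.
#' @export
mask_outliers <- function(values, groups, k = 3, type = 7) {
  keep <- rep(TRUE, length(values))
  skipped <- character(0)
  for (g in unique(groups)) {
    idx <- which(groups == g & is.finite(values))
    if (length(idx) < 4) {
      warning("group '", g, "' has fewer than 4 values; outlier fencing skipped")
      skipped <- c(skipped, as.character(g))
      next
    }
    out <- iqr_outliers(values[idx], k = k, type = type)
    keep[idx[out]] <- FALSE
  }
  report <- tibble::tibble(
    index = which(!keep),
    group = as.character(groups[!keep]),
    value = values[!keep]
  )
  list(keep = keep, report = report, skipped = skipped)
}

#' Squeeze proportions into the open unit interval
#'
#' y' = (y (n - 1) + 0.5) / n, the standard compression that keeps the beta
#' likelihood defined at observed 0s and 1s; 0.5 is a fixed point for any n.
#'
#' @param y proportions in \[0, 1\].
#' @param n_samples the sample size n used for the compression.
#' @return proportions strictly inside (0, 1).
#' @export
squeeze_proportions <- function(y, n_samples) {
  if (any(y < 0 | y > 1, na.rm = TRUE)) stop_config("proportions must be in [0,1]")
  (y * (n_samples - 1) + 0.5) / n_samples
}

# Negative log-likelihood and analytic gradient of the mean-precision beta
# regression: E[y] = mu = plogis(X beta), precision phi = exp(theta[p+1]),
# shape parameters (mu phi, (1-mu) phi).
betareg_negll <- function(theta, X, y) {
  p <- ncol(X)
  eta <- drop(X %*% theta[seq_len(p)])
  mu <- plogis(eta)
  phi <- exp(theta[p + 1])
  -sum(dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

betareg_grad <- function(theta, X, y) {
  p <- ncol(X)
  eta <- drop(X %*% theta[seq_len(p)])
  mu <- plogis(eta)
  phi <- exp(theta[p + 1])
  ystar <- log(y) - log(1 - y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  dmu <- phi * (ystar - mustar) * mu * (1 - mu)
  gbeta <- -drop(crossprod(X, dmu))
  dphi <- digamma(phi) - mu * digamma(mu * phi) -
    (1 - mu) * digamma((1 - mu) * phi) +
    mu * log(y) + (1 - mu) * log(1 - y)
  glogphi <- -sum(dphi) * phi
  c(gbeta, glogphi)
}

#' Beta regression with logit link
#'
#' Maximum-likelihood fit of the mean-precision beta regression: the outcome
#' (a cluster's relative frequency, strictly in (0,1)) has a beta density
#' with shapes (mu phi, (1 - mu) phi), logit(mu) = X beta, and a single
#' precision phi. Optimized by BFGS on (beta, log phi) with analytic
#' gradients, starting from a logit-scale least-squares fit and a
#' method-of-moments precision. Standard errors come from the inverse
#' observed information (numerical Hessian); Wald two-sided p-values per
#' coefficient. Under the logit link, exp(beta) for a group indicator is an
#' odds-scale fold-change.
#'
#' @param y proportions strictly in (0, 1); use [squeeze_proportions()]
#'   first if the data contain exact 0s or 1s.
#' @param design model matrix including the intercept column (full rank,
#'   n > p + 1).
#' @return object of class `betareg_fit`: `coefficients`, `se`, `z`, `p`,
#'   `phi`, `loglik`, `fitted`, `converged`.
#' @export
fit_beta_regression <- function(y, design) {
  X <- as.matrix(design)
  if (any(y <= 0 | y >= 1)) {
    stop_config("y must be strictly inside (0,1); see squeeze_proportions()")
  }
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1) stop_config("need n > p + 1 observations")
  if (qr(X)$rank < p) stop_config("design matrix is rank deficient")
  # starting values: logit-scale least squares + method-of-moments precision
  eta0 <- qlogis(y)
  beta0 <- qr.coef(qr(X), eta0)
  mu0 <- plogis(drop(X %*% beta0))
  e <- eta0 - drop(X %*% beta0)
  sigma2 <- sum(e^2) / (n - p) * mean((mu0 * (1 - mu0))^2)
  phi0 <- max(mean(mu0 * (1 - mu0)) / max(sigma2, 1e-8) - 1, 1.1)
  theta0 <- c(beta0, log(phi0))
  opt <- stats::optim(theta0, betareg_negll, gr = betareg_grad, X = X, y = y,
                      method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0) {
    stop_config("beta regression did not converge (optim code %d): %s",
                opt$convergence, paste(opt$message, collapse = " "))
  }
  coefs <- opt$par[seq_len(p)]
  names(coefs) <- colnames(X)
  vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  if (is.null(vc) || any(!is.finite(diag(vc))) || any(diag(vc)[seq_len(p)] < 0)) {
    stop_config("beta regression information matrix is singular")
  }
  se <- sqrt(diag(vc)[seq_len(p)])
  z <- coefs / se
  structure(
    list(
      coefficients = coefs, se = setNames(se, names(coefs)),
      z = z, p = 2 * pnorm(-abs(z)),
      phi = exp(opt$par[p + 1]),
      loglik = -opt$value,
      fitted = plogis(drop(X %*% coefs)),
      n = n, converged = TRUE
    ),
    class = "betareg_fit"
  )
}

#' Per-cluster beta-regression results with fold-changes and q-values
#'
#' Collects per-cluster fits into a results table: the group coefficient,
#' its odds-scale fold-change exp(beta), Wald p, BH q across the clusters
#' (within a gating level), and a significance flag at q < `fdr`. A
#' companion column `mean_ratio` gives the implied ratio of fitted means at
#' reference covariates, since exp(beta) under a logit link is an odds
#' ratio, not a frequency ratio.
#'
#' @param fits named list of `betareg_fit` objects (names = cluster ids).
#' @param group_coef name of the group coefficient in each fit.
#' @param fdr significance threshold on q.
#' @return tibble: `cluster`, `beta`, `se`, `p`, `q`, `fold_change`,
#'   `mean_ratio`, `phi`, `significant`.
#' @export
summarize_fold_changes <- function(fits, group_coef, fdr = 0.1) {
  stopifnot(length(fits) >= 1)
  rows <- lapply(names(fits), function(cl) {
    f <- fits[[cl]]
    b <- f$coefficients[group_coef]
    b0 <- f$coefficients[1]
    tibble::tibble(
      cluster = cl,
      beta = unname(b),
      se = unname(f$se[group_coef]),
      p = unname(f$p[group_coef]),
      fold_change = exp(unname(b)),
      mean_ratio = plogis(b0 + b) / plogis(b0),
      phi = f$phi
    )
  })
  out <- dplyr::bind_rows(rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < fdr
  out[, c("cluster", "beta", "se", "p", "q", "fold_change", "mean_ratio",
          "phi", "significant")]
}

#' Age/sex adjustment of proportions for display
#'
#' Residualizes logit-transformed proportions on age and sex and re-centers
#' at the grand mean, returning adjusted proportions for plotting only —
#' inference always uses the unadjusted values through the regression
#' model itself.
#'
#' @param values proportions strictly in (0, 1).
#' @param age,sex covariates (complete, same length as `values`).
#' @return adjusted proportions.
#' @export
adjust_for_display <- function(values, age, sex) {
  if (anyNA(age) || anyNA(sex)) stop_config("covariates must be complete")
  if (any(values <= 0 | values >= 1)) {
    stop_config("proportions must be strictly inside (0,1)")
  }
  eta <- qlogis(values)
  fit <- stats::lm(eta ~ age + factor(sex))
  plogis(mean(eta) + unname(resid(fit)))
}
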