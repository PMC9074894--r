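# Internal regression engines for the screens.
#
# The screens run on the order of 1e4-1e5 model fits, so both engines work
# directly on prebuilt model matrices. The negative-binomial fitter
# alternates IRLS for the coefficients (stats::glm.fit with
# MASS::negative.binomial) with maximum-likelihood estimation of the
# dispersion (MASS::theta.ml) until the dispersion stabilizes — the same
# alternation MASS::glm.nb performs; agreement with glm.nb to machine
# precision is asserted in the test suite. Wald standard errors come from
# the inverse weighted cross-product at the final IRLS weights, as in
# summary.glm.
#
# When the dispersion estimate diverges (theta above `theta_max`, i.e. no
# evidence of over-dispersion) or theta.ml fails, the fit falls back to
# Poisson with HC0 robust (sandwich) standard errors and is flagged via
# `fallback = TRUE`.

glm_se <- function(fit) {
  p <- fit$rank
  Qr <- fit$qr
  cov <- chol2inv(Qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  se <- rep(NA_real_, length(fit$coefficients))
  se[Qr$pivot[seq_len(p)]] <- sqrt(diag(cov))
  names(se) <- names(fit$coefficients)
  se
}

poisson_hc0_se <- function(X, y, fit) {
  # HC0 sandwich for Poisson ML: bread (X'WX)^-1, meat X' diag((y-mu)^2) X
  mu <- fit$fitted.values
  bread <- chol2inv(chol(crossprod(X * sqrt(mu))))
  meat <- crossprod(X * (y - mu))
  v <- bread %*% meat %*% bread
  stats::setNames(sqrt(diag(v)), colnames(X))
}

nb_ml_fit <- function(X, y, theta_max = 1e4, max_iter = 30L, tol = 1e-8) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::poisson()))
  th <- tryCatch(
    suppressWarnings(MASS::theta.ml(y, fit$fitted.values, limit = 30)),
    error = function(e) NA_real_)
  fallback <- FALSE
  if (is.na(th) || th > theta_max) {
    fallback <- TRUE
  } else {
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      fam <- MASS::negative.binomial(th)
      fit <- suppressWarnings(stats::glm.fit(X, y, family = fam,
                                             mustart = fit$fitted.values))
      th_new <- tryCatch(
        suppressWarnings(MASS::theta.ml(y, fit$fitted.values, limit = 30)),
        error = function(e) NA_real_)
      if (is.na(th_new) || th_new > theta_max) { fallback <- TRUE; break }
      if (abs(th_new - th) < tol * (abs(th) + 1)) {
        th <- th_new; converged <- TRUE; break
      }
      th <- th_new
    }
    if (!fallback && !converged) fallback <- !fit$converged
  }
  if (fallback) {
    fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::poisson()))
    se <- poisson_hc0_se(X, y, fit)
    return(list(coef = fit$coefficients, se = se, theta = Inf,
                converged = fit$converged, fallback = TRUE,
                fitted = fit$fitted.values))
  }
  list(coef = fit$coefficients, se = glm_se(fit), theta = as.numeric(th),
       converged = fit$converged, fallback = FALSE,
       fitted = fit$fitted.values)
}

gaussian_ols_fit <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  p <- fit$rank
  df <- length(y) - p
  if (df <= 0) stop("no residual degrees of freedom")
  sigma2 <- sum(fit$residuals^2) / df
  Qr <- fit$qr
  cov <- chol2inv(Qr$qr[seq_len(p), seq_len(p), drop = FALSE]) * sigma2
  se <- rep(NA_real_, length(fit$coefficients))
  se[Qr$pivot[seq_len(p)]] <- sqrt(diag(cov))
  names(se) <- names(fit$coefficients)
  list(coef = fit$coefficients, se = se, df = df, rank = p,
       fitted = fit$fitted.values, residuals = fit$residuals)
}
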