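#' Direct / indirect effect decomposition on the link scale
#'
#' For a selected (exposure, outcome) pair and its mediator CpG M-residuals:
#' the *total* effect is the exposure coefficient from the outcome model
#' without mediators (outcome ~ exposure + sex + ethnicity + age, Gaussian or
#' NB log-link by outcome family); the *direct* effect is the exposure
#' coefficient from the same model with all mediators added; and the
#' *indirect* effect is their difference (difference-of-coefficients on the
#' link scale — well-defined for both families, and equal to the
#' product-of-coefficients `a*b` in the linear-Gaussian case when the
#' mediator and outcome models share covariates).
#'
#' Per-mediator contributions are `a_k * b_k` — `a_k` from
#' `mediator_k ~ exposure + sex + ethnicity` (the exposure-methylation model
#' carries no age-at-testing term) and `b_k` from the full outcome model —
#' rescaled to sum exactly to the indirect effect. The covariate asymmetry
#' (mediator models adjust sex + ethnicity; outcome models also adjust age)
#' mirrors the screening models; `mediator_covariates` can force equal sets,
#' under which the product and difference estimators coincide exactly in the
#' linear-Gaussian case.
#'
#' @param y Outcome vector.
#' @param x Exposure vector.
#' @param mediators Numeric vector or samples x mediators matrix of CpG
#'   M-residuals (column names = CpG ids).
#' @param covs Data frame with columns `sex`, `ethnicity`, `age`.
#' @param family `"continuous"` or `"count"`.
#' @param mediator_covariates Covariate columns used in the mediator models
#'   (default `c("sex", "ethnicity")`).
#' @return A list of class `mediation_effects`: `total`, `direct`,
#'   `indirect`, `contributions` (named, summing to `indirect`), `a`, `b`,
#'   `proportion` (see [mediation_proportion()]), `n`, `family`.
#'   Non-convergence or a collinear design is an error (the triple is
#'   reported as failed, not silently dropped).
#' @examples
#' set.seed(1)
#' x <- rnorm(80); m <- 0.5 * x + rnorm(80)
#' y <- 0.25 * x + 0.5 * m + rnorm(80)
#' covs <- data.frame(sex = rbinom(80, 1, 0.5), ethnicity = rbinom(80, 1, 0.5),
#'                    age = runif(80, 6.5, 7.5))
#' estimate_effects(y, x, m, covs, "continuous")$proportion
#' @export
estimate_effects <- function(y, x, mediators, covs, family,
                             mediator_covariates = c("sex", "ethnicity")) {
  stopifnot(family %in% c("continuous", "count"))
  M <- as.matrix(mediators)
  if (is.null(colnames(M))) colnames(M) <- paste0("med", seq_len(ncol(M)))
  df <- data.frame(.y = y, .x = x, covs, check.names = TRUE)
  cc <- stats::complete.cases(df) & stats::complete.cases(M)
  df <- df[cc, , drop = FALSE]
  M <- M[cc, , drop = FALSE]
  n <- nrow(df)
  if (n < 20) stop("fewer than 20 complete cases for mediation")

  Xc <- stats::model.matrix(~ ., df[, -(1:2), drop = FALSE])
  X_total <- cbind(Xc[, 1, drop = FALSE], exposure = df$.x,
                   Xc[, -1, drop = FALSE])
  X_full <- cbind(Xc[, 1, drop = FALSE], exposure = df$.x, M,
                  Xc[, -1, drop = FALSE])
  if (qr(X_full)$rank < ncol(X_full))
    stop("full mediation design is rank deficient (collinear mediators?)")

  if (family == "continuous") {
    f_tot <- gaussian_ols_fit(X_total, df$.y)
    f_full <- gaussian_ols_fit(X_full, df$.y)
  } else {
    f_tot <- nb_ml_fit(X_total, df$.y)
    f_full <- nb_ml_fit(X_full, df$.y)
    if (!f_tot$converged || !f_full$converged)
      stop("negative binomial mediation model did not converge")
  }
  total <- unname(f_tot$coef["exposure"])
  direct <- unname(f_full$coef["exposure"])
  indirect <- total - direct
  b <- f_full$coef[colnames(M)]

  med_covs <- covs[cc, mediator_covariates, drop = FALSE]
  Xm <- stats::model.matrix(~ ., med_covs)
  Xa <- cbind(Xm[, 1, drop = FALSE], exposure = df$.x, Xm[, -1, drop = FALSE])
  a <- vapply(seq_len(ncol(M)), function(k)
    unname(stats::lm.fit(Xa, M[, k])$coefficients["exposure"]), numeric(1))
  names(a) <- colnames(M)

  ab <- a * b
  contributions <- if (sum(ab) != 0) ab * (indirect / sum(ab)) else ab
  structure(list(total = total, direct = direct, indirect = indirect,
                 contributions = contributions, a = a, b = b,
                 proportion = mediation_proportion(indirect, direct),
                 n = n, family = family), class = "mediation_effects")
}

#' Mediation proportion
#'
#' The share of the total effect carried by the mediators, on absolute
#' values: `|IE| / (|IE| + |DE|)`. Lies in \[0, 1\] and is well-defined even
#' when direct and indirect effects have opposite signs; it is undefined
#' (returned as `NA` with a warning) only when both effects are exactly
#' zero.
#'
#' @param indirect,direct Indirect and direct effects on the link scale.
#' @return A fraction in \[0, 1\], or `NA` if both effects are zero.
#' @examples
#' mediation_proportion(0.3, 0.7)   # 0.30
#' mediation_proportion(-0.7, 0.3)  # 0.70
#' @export
mediation_proportion <- function(indirect, direct) {
  if (indirect == 0 && direct == 0) {
    warning("mediation proportion undefined: both effects are zero")
    return(NA_real_)
  }
  abs(indirect) / (abs(indirect) + abs(direct))
}

#' Bootstrap mediation analysis for one exposure-outcome-CpG triple
#'
#' Point estimates come from [estimate_effects()] on the full sample;
#' uncertainty comes from resampling individuals with replacement `n_boot`
#' times, re-estimating all effects per resample, and taking percentile
#' confidence intervals. Resampling rows preserves the joint
#' exposure-mediator-outcome distribution. If more than 20% of resamples
#' fail to converge the result is flagged unstable.
#'
#' When the mediators were obtained by cell-composition residualization, that
#' regression is itself an estimation step; pass the mediators' M-values and
#' the cell-proportion matrix via `m_values`/`cells` and the residualization
#' is then re-estimated inside every resample, so its uncertainty propagates
#' into the intervals (the point estimates still use the full-sample
#' residuals, exactly as the screens do). Without these arguments the
#' supplied mediator values are treated as fixed covariates.
#'
#' @inheritParams estimate_effects
#' @param n_boot Number of bootstrap resamples (default 500, minimum 100).
#' @param ci_level Confidence level (default 0.95).
#' @param seed Integer seed; identical seed gives identical intervals.
#' @param exposure_id,outcome_id Labels carried into the result.
#' @param m_values Optional samples x mediators matrix of M-values (pre
#'   residualization) for the mediator CpGs.
#' @param cells Optional samples x cell-types proportion matrix aligned with
#'   `m_values`; required with `m_values`.
#' @return A list of class `mediation_result`: ids, `total`, `direct`,
#'   `indirect`, `contributions`, `proportion`, `ci` (data frame with
#'   percentile bounds for direct, indirect and proportion), `n`, `n_boot`,
#'   `n_failed`, `unstable`, `seed`, `ci_level`.
#' @export
bootstrap_mediation <- function(y, x, mediators = NULL, covs, family,
                                n_boot = 500L, ci_level = 0.95, seed = 1L,
                                mediator_covariates = c("sex", "ethnicity"),
                                exposure_id = "exposure",
                                outcome_id = "outcome",
                                m_values = NULL, cells = NULL) {
  if (n_boot < 100) stop("`n_boot` must be at least 100")
  reresid <- !is.null(m_values)
  if (reresid) {
    if (is.null(cells)) stop("`cells` is required with `m_values`")
    m_values <- as.matrix(m_values)
    cells <- as.matrix(cells)
    Xc <- cbind(1, cells[, -ncol(cells), drop = FALSE])
    M <- apply(m_values, 2, function(m) stats::lm.fit(Xc, m)$residuals)
    if (is.null(colnames(M))) colnames(M) <- colnames(m_values)
  } else {
    if (is.null(mediators)) stop("supply `mediators` or `m_values` + `cells`")
    M <- as.matrix(mediators)
  }
  if (is.null(colnames(M))) colnames(M) <- paste0("med", seq_len(ncol(M)))
  point <- estimate_effects(y, x, M, covs, family, mediator_covariates)

  set.seed(seed)
  n <- length(y)
  draws <- matrix(NA_real_, n_boot, 3,
                  dimnames = list(NULL, c("direct", "indirect", "proportion")))
  n_failed <- 0L
  for (bi in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    Mb <- if (reresid) {
      tryCatch(apply(m_values[idx, , drop = FALSE], 2, function(m)
        stats::lm.fit(Xc[idx, , drop = FALSE], m)$residuals),
        error = function(e) NULL)
    } else M[idx, , drop = FALSE]
    if (is.null(Mb)) { n_failed <- n_failed + 1L; next }
    if (is.null(dim(Mb))) Mb <- matrix(Mb, ncol = ncol(M),
                                       dimnames = list(NULL, colnames(M)))
    colnames(Mb) <- colnames(M)
    est <- tryCatch(
      suppressWarnings(estimate_effects(y[idx], x[idx], Mb,
                                        covs[idx, , drop = FALSE], family,
                                        mediator_covariates)),
      error = function(e) NULL)
    if (is.null(est)) { n_failed <- n_failed + 1L; next }
    draws[bi, ] <- c(est$direct, est$indirect, est$proportion)
  }
  if (n_failed > 0.2 * n_boot)
    warning(sprintf("unstable bootstrap: %d of %d resamples failed",
                    n_failed, n_boot))
  probs <- c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2)
  ci <- as.data.frame(t(apply(draws, 2, stats::quantile, probs = probs,
                              na.rm = TRUE)))
  names(ci) <- c("lower", "upper")
  ci <- cbind(quantity = rownames(ci), ci, row.names = NULL,
              stringsAsFactors = FALSE)

  structure(list(exposure = exposure_id, outcome = outcome_id,
                 mediator_cpgs = colnames(M),
                 total = point$total, direct = point$direct,
                 indirect = point$indirect,
                 contributions = point$contributions,
                 proportion = point$proportion, ci = ci,
                 n = point$n, n_boot = n_boot, n_failed = n_failed,
                 unstable = n_failed > 0.2 * n_boot,
                 seed = seed, ci_level = ci_level),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> %s -> [%s] -> %s\n", x$exposure,
              paste(x$mediator_cpgs, collapse = ", "), x$outcome))
  cat(sprintf("  total %.4f | direct %.4f | indirect %.4f | proportion %.1f%%\n",
              x$total, x$direct, x$indirect, 100 * x$proportion))
  pci <- x$ci[x$ci$quantity == "proportion", ]
  cat(sprintf("  %d%% bootstrap CI for proportion: [%.3f, %.3f] (%d resamples)\n",
              round(100 * x$ci_level), pci$lower, pci$upper, x$n_boot))
  invisible(x)
}
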