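#' Single-model association fits used by the sequential screens
#'
#' Three model forms, each returning one `ScreenResult` row:
#'
#' * `fit_outcome_on_cpg()` — outcome on one CpG M-residual, adjusting for
#'   sex, ethnicity, and age at testing; Gaussian identity link for
#'   continuous outcomes, negative binomial log link (dispersion estimated
#'   by maximum likelihood) for count outcomes. The Step 2 model.
#' * `fit_cpg_on_exposure()` — CpG M-residual on one exposure by ordinary
#'   least squares, adjusting for sex and ethnicity only (no age: the
#'   exposure-methylation model has no testing occasion). The Step 3 model.
#' * `fit_outcome_on_exposure()` — outcome on one exposure with the same
#'   family and covariates as Step 2. The Step 4 model.
#'
#' Fits use complete cases only (listwise deletion across response,
#' predictor and covariates) and at least 20 of them. Degenerate inputs —
#' constant predictor, rank-deficient design (e.g. the exposure duplicated
#' as a covariate), or non-convergence — yield a flagged row with
#' `converged = FALSE` and `p_raw = 1`, so the fit still counts in its
#' multiple-testing family instead of silently vanishing. P-values are
#' Wald-type (coefficient / SE): t reference for Gaussian fits, normal for
#' count fits.
#'
#' @param y Outcome vector (numeric; counts for `family = "count"`).
#' @param cpg CpG M-residual vector.
#' @param x Exposure vector.
#' @param covs Data frame of covariates (e.g. `sex`, `ethnicity`, `age`);
#'   character/factor columns are expanded to indicators via
#'   `model.matrix()`, so `sex = "male"` and `ethnicity = "Dominican"`
#'   become the conventional indicator terms.
#' @param family `"continuous"` (Gaussian) or `"count"` (negative binomial).
#' @param response,predictor Labels carried into the result row.
#' @return One-row data frame: `response`, `predictor`, `estimate`, `se`,
#'   `statistic`, `p_raw`, `n`, `family`, `converged`, `note`.
#' @name screen_fits
NULL

flagged_row <- function(response, predictor, family, n, note) {
  data.frame(response = response, predictor = predictor,
             estimate = NA_real_, se = NA_real_, statistic = NA_real_,
             p_raw = 1, n = n, family = family, converged = FALSE,
             note = note, stringsAsFactors = FALSE)
}

# Core fit on complete-case arrays with a prebuilt covariate design
# (intercept in column 1). Rank deficiency is detected from the fit itself.
fit_core <- function(y, pred, Xc, family, response, predictor) {
  n <- length(y)
  if (stats::sd(pred) == 0)
    return(flagged_row(response, predictor, family, n, "constant_predictor"))
  X <- cbind(Xc[, 1, drop = FALSE], predictor = pred, Xc[, -1, drop = FALSE])

  if (family == "continuous") {
    fit <- tryCatch(gaussian_ols_fit(X, y), error = function(e) NULL)
    if (!is.null(fit) && fit$rank < ncol(X))
      return(flagged_row(response, predictor, family, n, "rank_deficient_design"))
    if (is.null(fit) || is.na(fit$se["predictor"]) || fit$se["predictor"] == 0)
      return(flagged_row(response, predictor, family, n, "fit_failed"))
    est <- fit$coef["predictor"]; se <- fit$se["predictor"]
    stat <- est / se
    p <- 2 * stats::pt(-abs(stat), df = fit$df)
    note <- ""
  } else {
    if (stats::sd(y) == 0)
      return(flagged_row(response, predictor, family, n, "constant_response"))
    fit <- tryCatch(nb_ml_fit(X, y), error = function(e) NULL)
    if (!is.null(fit) && anyNA(fit$coef))
      return(flagged_row(response, predictor, family, n, "rank_deficient_design"))
    if (is.null(fit) || !fit$converged || is.na(fit$se["predictor"]) ||
        fit$se["predictor"] == 0)
      return(flagged_row(response, predictor, family, n, "fit_failed"))
    est <- fit$coef["predictor"]; se <- fit$se["predictor"]
    stat <- est / se
    p <- 2 * stats::pnorm(-abs(stat))
    note <- if (fit$fallback) "poisson_fallback_robust_se" else ""
  }
  data.frame(response = response, predictor = predictor,
             estimate = unname(est), se = unname(se),
             statistic = unname(stat), p_raw = unname(p), n = n,
             family = family, converged = TRUE, note = note,
             stringsAsFactors = FALSE)
}

covariate_design <- function(covs) {
  tryCatch(stats::model.matrix(~ ., covs), error = function(e) NULL)
}

fit_screen_model <- function(y, pred, covs, family, response, predictor,
                             min_n = 20L) {
  stopifnot(family %in% c("continuous", "count"))
  covs <- as.data.frame(covs)
  cc <- !is.na(y) & !is.na(pred) & stats::complete.cases(covs)
  n <- sum(cc)
  if (n < min_n)
    return(flagged_row(response, predictor, family, n, "too_few_complete_cases"))
  Xc <- covariate_design(covs[cc, , drop = FALSE])
  if (is.null(Xc))
    return(flagged_row(response, predictor, family, n, "degenerate_covariates"))
  fit_core(y[cc], pred[cc], Xc, family, response, predictor)
}

#' @rdname screen_fits
#' @export
fit_outcome_on_cpg <- function(y, cpg, covs, family,
                               response = "outcome", predictor = "cpg") {
  fit_screen_model(y, cpg, covs, family, response, predictor)
}

#' @rdname screen_fits
#' @export
fit_cpg_on_exposure <- function(cpg, x, covs,
                                response = "cpg", predictor = "exposure") {
  fit_screen_model(cpg, x, covs, "continuous", response, predictor)
}

#' @rdname screen_fits
#' @export
fit_outcome_on_exposure <- function(y, x, covs, family,
                                    response = "outcome", predictor = "exposure") {
  fit_screen_model(y, x, covs, family, response, predictor)
}

#' Benjamini-Hochberg adjustment with an explicit family size
#'
#' Step-up FDR adjustment `adj_i = min_{j >= rank(i)} (p_(j) * m / j)` capped
#' at 1, where the family size `m` may exceed the number of p-values actually
#' supplied (untested members of the family then implicitly carry p = 1).
#' Each screening step defines its own family: Step 2 uses the outcome's CpG
#' universe, Step 3 uses exposures x Step-2-significant CpGs per outcome, and
#' Step 4 uses the exposure-outcome tests actually run.
#'
#' @param raw_ps Numeric vector of raw p-values in \[0, 1\].
#' @param m Family size, at least `length(raw_ps)` (default: the length).
#' @return Adjusted p-values, same order as input; always `>= raw_ps` and
#'   `<= 1`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(raw_ps, m = length(raw_ps)) {
  if (m < length(raw_ps))
    stop("family size `m` must be at least length(raw_ps)")
  if (!length(raw_ps)) return(numeric(0))
  if (any(raw_ps < 0 | raw_ps > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(raw_ps, method = "BH", n = m)
}

#' Run the sequential Step 2-4 association screens
#'
#' For each outcome: Step 2 regresses the outcome on every CpG in its
#' universe and keeps CpGs with FDR-adjusted p below `alpha` (family = all
#' attempted tests in the universe). For outcomes with at least one Step 2
#' hit, Step 3 regresses each surviving CpG on every exposure — restricted
#' to samples that have the outcome measured, methylation, and the exposure —
#' with FDR family = exposures x surviving CpGs per outcome. Step 4 then
#' tests each (outcome, exposure) pair that had at least one significant
#' exposure-CpG association, with FDR family = the number of Step 4 tests
#' actually run. Pairs significant at Step 4 become mediation candidates,
#' carrying the CpGs significant in both Step 2 and Step 3 as mediators.
#'
#' Flagged (non-converged/degenerate) fits stay in their family with
#' `p_raw = 1`; outcomes are processed independently, so outcome order never
#' changes any result.
#'
#' @param cohort Cohort data frame (`sample_id`, `sex`, `ethnicity`, age
#'   columns, exposures, outcomes).
#' @param meth `M_residual`-stage [meth_matrix]; rows are matched to
#'   `cohort$sample_id`.
#' @param universes Named list (by outcome id) of `cpg_universe` objects or
#'   plain CpG-id character vectors. Outcomes with an empty universe are
#'   skipped (Steps 2-5 all empty for them).
#' @param outcome_spec Data frame with columns `id`, `family`, `age_col`.
#' @param exposures Character vector of exposure column names.
#' @param alpha FDR threshold (default 0.05).
#' @return A list of class `screen_cascade`: data frames `step2`, `step3`,
#'   `step4` (each with `p_adj` and `selected` columns) and `triples`
#'   (columns `outcome`, `exposure`, `mediators` — semicolon-joined CpG ids —
#'   plus the Step 4 estimate and p-values).
#' @export
run_sequential_screen <- function(cohort, meth, universes, outcome_spec,
                                  exposures, alpha = 0.05) {
  stopifnot(is_meth_matrix(meth))
  if (meth$stage != "M_residual")
    stop("screens expect an M_residual-stage matrix")
  common <- intersect(cohort$sample_id, sample_ids(meth))
  if (!length(common)) stop("no samples shared between cohort and methylation")
  cohort <- cohort[match(common, cohort$sample_id), , drop = FALSE]
  V <- meth$values[common, , drop = FALSE]

  step2 <- list(); step3 <- list(); step4 <- list()
  sig2 <- list(); sig3 <- list()

  for (i in seq_len(nrow(outcome_spec))) {
    oid <- outcome_spec$id[i]
    fam <- outcome_spec$family[i]
    uni <- universes[[oid]]
    if (inherits(uni, "cpg_universe")) uni <- uni$cpg_ids
    uni <- intersect(uni, colnames(V))
    if (!length(uni)) next
    y <- cohort[[oid]]
    if (is.null(y)) stop("outcome column missing from cohort: ", oid)
    covs <- data.frame(sex = cohort$sex, ethnicity = cohort$ethnicity,
                       age = cohort[[outcome_spec$age_col[i]]],
                       stringsAsFactors = FALSE)
    # covariate design built once per outcome; per-CpG missingness handled
    # by row subsetting of the same design
    base <- !is.na(y) & stats::complete.cases(covs)
    Xc_full <- covariate_design(covs[base, , drop = FALSE])
    yb <- y[base]
    Vb <- V[base, uni, drop = FALSE]
    rows <- do.call(rbind, lapply(uni, function(k) {
      pk <- Vb[, k]
      ok <- !is.na(pk)
      n_ok <- sum(ok)
      if (n_ok < 20L)
        return(flagged_row(oid, k, fam, n_ok, "too_few_complete_cases"))
      if (is.null(Xc_full))
        return(flagged_row(oid, k, fam, n_ok, "degenerate_covariates"))
      if (all(ok)) fit_core(yb, pk, Xc_full, fam, oid, k)
      else fit_core(yb[ok], pk[ok], Xc_full[ok, , drop = FALSE], fam, oid, k)
    }))
    rows$p_adj <- bh_adjust(rows$p_raw, m = nrow(rows))
    rows$selected <- rows$p_adj < alpha
    step2[[oid]] <- rows
    sig2[[oid]] <- rows$predictor[rows$selected]
  }

  for (oid in names(sig2)) {
    cpgs <- sig2[[oid]]
    if (!length(cpgs)) next
    has_y <- !is.na(cohort[[oid]])
    covs3 <- data.frame(sex = cohort$sex[has_y],
                        ethnicity = cohort$ethnicity[has_y],
                        stringsAsFactors = FALSE)
    rows <- do.call(rbind, lapply(exposures, function(j) {
      xj <- cohort[[j]]
      if (is.null(xj)) stop("exposure column missing from cohort: ", j)
      do.call(rbind, lapply(cpgs, function(k)
        fit_cpg_on_exposure(V[has_y, k], xj[has_y], covs3,
                            response = k, predictor = j)))
    }))
    rows$outcome <- oid
    rows$p_adj <- bh_adjust(rows$p_raw, m = length(exposures) * length(cpgs))
    rows$selected <- rows$p_adj < alpha
    step3[[oid]] <- rows
    if (any(rows$selected))
      sig3[[oid]] <- rows[rows$selected, c("predictor", "response")]
  }

  pairs <- do.call(rbind, lapply(names(sig3), function(oid)
    data.frame(outcome = oid, exposure = unique(sig3[[oid]]$predictor),
               stringsAsFactors = FALSE)))
  if (!is.null(pairs) && nrow(pairs)) {
    rows <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
      oid <- pairs$outcome[r]; j <- pairs$exposure[r]
      i <- match(oid, outcome_spec$id)
      covs <- data.frame(sex = cohort$sex, ethnicity = cohort$ethnicity,
                         age = cohort[[outcome_spec$age_col[i]]],
                         stringsAsFactors = FALSE)
      fit_outcome_on_exposure(cohort[[oid]], cohort[[j]], covs,
                              outcome_spec$family[i],
                              response = oid, predictor = j)
    }))
    rows$p_adj <- bh_adjust(rows$p_raw, m = nrow(rows))
    rows$selected <- rows$p_adj < alpha
    step4 <- rows
  } else {
    step4 <- NULL
  }

  triples <- NULL
  if (!is.null(step4) && any(step4$selected)) {
    sel <- step4[step4$selected, , drop = FALSE]
    triples <- do.call(rbind, lapply(seq_len(nrow(sel)), function(r) {
      oid <- sel$response[r]; j <- sel$predictor[r]
      s3 <- sig3[[oid]]
      meds <- sort(unique(s3$response[s3$predictor == j]))
      data.frame(outcome = oid, exposure = j,
                 mediators = paste(meds, collapse = ";"),
                 step4_estimate = sel$estimate[r], step4_p_raw = sel$p_raw[r],
                 step4_p_adj = sel$p_adj[r], stringsAsFactors = FALSE)
    }))
  }

  empty2 <- flagged_row("", "", "continuous", 0L, "")[0, ]
  empty2$p_adj <- numeric(0); empty2$selected <- logical(0)
  structure(list(
    step2 = if (length(step2)) do.call(rbind, c(step2, make.row.names = FALSE)) else empty2,
    step3 = if (length(step3)) do.call(rbind, c(step3, make.row.names = FALSE)) else NULL,
    step4 = step4,
    triples = triples
  ), class = "screen_cascade")
}

#' @export
print.screen_cascade <- function(x, ...) {
  n2 <- if (is.null(x$step2)) 0L else sum(x$step2$selected)
  n3 <- if (is.null(x$step3)) 0L else sum(x$step3$selected)
  nt <- if (is.null(x$triples)) 0L else nrow(x$triples)
  cat(sprintf("<screen_cascade> %d Step-2 CpG hits, %d Step-3 pairs, %d candidate triple(s)\n",
              n2, n3, nt))
  invisible(x)
}
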