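#' Coverage QC and sex-chromosome filtering
#'
#' Applies the standard array QC sequence: drop samples with less than
#' `sample_cpg_coverage_min` non-missing CpGs, then CpGs with less than
#' `cpg_sample_coverage_min` non-missing samples (computed on the retained
#' samples), then CpGs annotated to sex chromosomes. The defaults are the
#' conventional 95% CpG coverage per sample and 70% sample coverage per CpG.
#'
#' @param m A [meth_matrix] (any stage).
#' @param manifest Manifest data frame (`cpg_id`, `chr`, `pos`, `gene`) used
#'   for the chromosome lookup.
#' @param sample_cpg_coverage_min Minimum fraction of non-missing CpGs a
#'   sample must have (default 0.95).
#' @param cpg_sample_coverage_min Minimum fraction of non-missing samples a
#'   CpG must have (default 0.70).
#' @param sex_chromosomes Chromosome labels treated as sex chromosomes.
#' @return A list: `matrix` (filtered [meth_matrix]) and `report` (data frame
#'   of drop counts per QC rule).
#' @export
qc_filter <- function(m, manifest,
                      sample_cpg_coverage_min = 0.95,
                      cpg_sample_coverage_min = 0.70,
                      sex_chromosomes = c("X", "Y", "chrX", "chrY")) {
  stopifnot(is_meth_matrix(m))
  v <- m$values
  ok <- !is.na(v)

  keep_s <- rowMeans(ok) >= sample_cpg_coverage_min
  if (!any(keep_s))
    stop(sprintf("all samples dropped: none reach %.0f%% CpG coverage",
                 100 * sample_cpg_coverage_min))
  v <- v[keep_s, , drop = FALSE]

  keep_c <- colMeans(!is.na(v)) >= cpg_sample_coverage_min
  v <- v[, keep_c, drop = FALSE]

  chr <- manifest$chr[match(colnames(v), manifest$cpg_id)]
  on_sex <- !is.na(chr) & chr %in% sex_chromosomes
  v <- v[, !on_sex, drop = FALSE]
  if (ncol(v) == 0) stop("all CpGs dropped by QC")

  report <- data.frame(
    rule = c("sample_cpg_coverage", "cpg_sample_coverage", "sex_chromosome"),
    threshold = c(sample_cpg_coverage_min, cpg_sample_coverage_min, NA),
    dropped = c(sum(!keep_s), sum(!keep_c), sum(on_sex)),
    kept = c(nrow(v), ncol(v) + sum(on_sex), ncol(v)),
    stringsAsFactors = FALSE
  )
  list(matrix = meth_matrix(v, m$stage), report = report)
}

#' Beta-value to M-value (logit2) transform and its inverse
#'
#' `M = log2(beta / (1 - beta))`. Beta-values at or beyond the machine
#' boundary are clamped to `[eps, 1 - eps]` first (with a warning giving the
#' count), since the logit is unbounded there.
#'
#' @param m A beta-stage [meth_matrix].
#' @param eps Boundary clamp (default 1e-6).
#' @return An M-stage [meth_matrix] (or beta-stage for [m_to_beta()]).
#' @examples
#' b <- meth_matrix(matrix(c(0.5, 0.8), 1, 2,
#'                  dimnames = list("s1", c("cg1", "cg2"))), "beta")
#' beta_to_m(b)$values  # 0 and 2
#' @export
beta_to_m <- function(m, eps = 1e-6) {
  stopifnot(is_meth_matrix(m))
  if (m$stage != "beta") stop("beta_to_m() needs a beta-stage matrix")
  v <- m$values
  n_clamp <- sum(v < eps | v > 1 - eps, na.rm = TRUE)
  if (n_clamp > 0) {
    warning(sprintf("%d boundary beta-value(s) clamped to [%g, %g]",
                    n_clamp, eps, 1 - eps))
    v <- pmin(pmax(v, eps), 1 - eps)
  }
  meth_matrix(log2(v / (1 - v)), "M")
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  stopifnot(is_meth_matrix(m))
  if (m$stage != "M") stop("m_to_beta() needs an M-stage matrix")
  meth_matrix(1 / (1 + 2^(-m$values)), "beta")
}

#' Regress cell-type composition out of M-values
#'
#' Per CpG, fits ordinary least squares of the M-values on the cell-type
#' proportion columns (with intercept; one cell column is dropped to avoid
#' the sum-to-one singularity) and returns the residuals. The residuals are
#' the mediator scale of all downstream screens.
#'
#' @param m An M-stage [meth_matrix].
#' @param cells Numeric matrix or data frame of cell-type proportions,
#'   samples x cell types; rows must align with `sample_ids(m)` (matched by
#'   rownames when present) and sum to 1 within 1e-6.
#' @param drop_col Cell column dropped from the design (default: the last).
#' @return An `M_residual`-stage [meth_matrix].
#' @export
residualize_cells <- function(m, cells, drop_col = ncol(cells)) {
  stopifnot(is_meth_matrix(m))
  if (m$stage != "M") stop("residualize_cells() needs an M-stage matrix")
  cells <- as.matrix(cells)
  if (!is.null(rownames(cells))) {
    if (!all(sample_ids(m) %in% rownames(cells)))
      stop("cell proportions missing for some samples")
    cells <- cells[sample_ids(m), , drop = FALSE]
  } else if (nrow(cells) != nrow(m$values)) {
    stop("cell proportion rows do not align with methylation samples")
  }
  if (any(abs(rowSums(cells) - 1) > 1e-6))
    stop("cell proportions must sum to 1 per sample (within 1e-6)")
  X <- cbind(`(Intercept)` = 1, cells[, -drop_col, drop = FALSE])
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("cell-proportion design is rank deficient beyond the dropped column")
  v <- m$values
  if (anyNA(v)) {
    res <- v
    for (k in seq_len(ncol(v))) {
      obs <- !is.na(v[, k])
      fit <- stats::lm.fit(X[obs, , drop = FALSE], v[obs, k])
      res[obs, k] <- fit$residuals
    }
  } else {
    res <- qr.resid(qx, v)
    dimnames(res) <- dimnames(v)
  }
  meth_matrix(res, "M_residual")
}

#' Remove extreme outliers from an exposure or outcome vector
#'
#' Single-pass rule: values farther than `n_sd` standard deviations from the
#' mean (both computed once from all non-missing values) are removed. With
#' zero SD nothing is removed. Applied independently per outcome and per
#' exposure, never to methylation.
#'
#' @param values Numeric vector, possibly named (names act as sample ids).
#' @param n_sd SD multiple defining "extreme" (default 4).
#' @return A list: `kept` (the vector with outliers dropped), `removed_ids`
#'   (names, or integer positions when unnamed), `n_removed`.
#' @export
trim_outliers <- function(values, n_sd = 4) {
  obs <- !is.na(values)
  if (sum(obs) < 3) stop("need at least 3 non-missing values")
  mu <- mean(values[obs])
  s <- stats::sd(values[obs])
  out <- obs & !is.na(values) & s > 0 & abs(values - mu) > n_sd * s
  out[is.na(out)] <- FALSE
  ids <- if (!is.null(names(values))) names(values)[out] else which(out)
  list(kept = values[!out], removed_ids = ids, n_removed = sum(out))
}

#' Split a cohort into discovery and validation sets
#'
#' Random, seed-reproducible partition. The discovery size follows the
#' printed-percentage convention of cohort reports: when the nominal
#' fraction is a whole percentage, the discovery set is the largest subset
#' whose share of the cohort still rounds to that percentage (so a split
#' reported as "70%" stays accurate while giving the discovery models the
#' most samples). A 341-sample cohort at fraction 0.70 therefore splits
#' 240 / 101 (240/341 = 70.4%, which rounds to 70%). For fractions that are
#' not whole percentages the size is simply `fraction * n` rounded to
#' nearest. Remainder goes to validation.
#'
#' @param ids Character vector of sample ids.
#' @param fraction Discovery fraction in (0, 1), default 0.70.
#' @param seed Integer seed.
#' @return A list: `discovery`, `validation` (disjoint, exhaustive, sorted).
#' @examples
#' s <- split_cohort(sprintf("S%03d", 1:341), 0.70, seed = 1)
#' lengths(s)  # 240 and 101
#' @export
split_cohort <- function(ids, fraction = 0.70, seed = 1L) {
  n <- length(ids)
  if (n < 2) stop("need at least 2 samples to split")
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must be in (0, 1)")
  pct <- 100 * fraction
  if (abs(pct - round(pct)) < 1e-8) {
    # largest k with floor(100 k / n + 0.5) == pct
    n_disc <- ceiling(n * (round(pct) + 0.5) / 100 - 1e-9) - 1
  } else {
    n_disc <- floor(fraction * n + 0.5)
  }
  n_disc <- min(max(n_disc, 1L), n - 1L)
  set.seed(seed)
  disc <- sort(sample(ids, n_disc))
  list(discovery = disc, validation = sort(setdiff(ids, disc)))
}
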