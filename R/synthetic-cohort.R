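#' Configuration for the synthetic-cohort generator
#'
#' Defines a birth-cohort simulation with the statistical structure the
#' five-step analysis assumes: log-normal exposures, cell-mixture methylation
#' with optional planted exposure effects on the M-value scale, one
#' continuous (IQ-like) and one over-dispersed count (CBCL-like) outcome
#' family, and planted exposure -> CpG -> outcome mediation triangles with
#' known effect sizes.
#'
#' Effect sizes have the units of the models fitted downstream: `a` is the
#' exposure -> CpG slope per unit exposure on the M-value scale, `b` the
#' CpG -> outcome slope per unit M-residual on the outcome's link scale
#' (identity for continuous, log for count), and `c_direct` the direct
#' exposure -> outcome slope on the link scale.
#'
#' @param n_samples Number of samples (default 341, a cohort-scale size).
#' @param n_cpgs Number of CpG sites.
#' @param n_exposures Number of exposure variables (`exp01`, `exp02`, ...).
#' @param outcomes Data frame with columns `id`, `family`
#'   (`"continuous"`/`"count"`) and `age_col` naming the age-at-testing
#'   column used as covariate for that outcome.
#' @param planted_paths `NULL` for an all-null cohort, else a data frame with
#'   columns `exposure`, `cpg`, `outcome`, `a`, `b`, `c_direct` (one row per
#'   planted mediation triangle).
#' @param sd_m Residual SD of CpG M-values around their cell/exposure signal.
#' @param sd_y Residual SD of continuous outcomes.
#' @param theta NB2 dispersion of count outcomes (variance = mu + mu^2/theta).
#' @param count_baseline Baseline mean of count outcomes.
#' @param continuous_baseline Baseline mean of continuous outcomes.
#' @param exposure_meanlog,exposure_sdlog Log-normal exposure parameters.
#' @param cell_alpha Named Dirichlet concentration vector for cell-type
#'   proportions (cord-blood-like, granulocyte dominant).
#' @param gamma_sd SD of per-CpG cell-type loadings (the cell-composition
#'   confounding injected on the M scale).
#' @param cell_confounding_strength If > 0, the first exposure gains a
#'   contribution from (standardized) granulocyte fraction, creating
#'   exposure-CpG association that flows only through cell composition.
#' @param sex_chromosome_fraction Fraction of (non-planted) CpGs annotated to
#'   chrX/chrY in the manifest (removed by QC downstream).
#' @param missing_rate Fraction of methylation entries set to NA.
#' @param seed Integer seed; identical seed + config gives bit-identical
#'   output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 341L,
                       n_cpgs = 200L,
                       n_exposures = 10L,
                       outcomes = default_outcome_spec(),
                       planted_paths = default_planted_paths(),
                       sd_m = 0.4,
                       sd_y = 12,
                       theta = 2,
                       count_baseline = 3,
                       continuous_baseline = 100,
                       exposure_meanlog = 0,
                       exposure_sdlog = 0.5,
                       cell_alpha = c(Gran = 45, CD4T = 12, CD8T = 8,
                                      Mono = 5, Bcell = 4, NK = 3),
                       gamma_sd = 2,
                       cell_confounding_strength = 0,
                       sex_chromosome_fraction = 0.05,
                       missing_rate = 0,
                       seed = 1L) {
  if (n_samples <= 0) stop("`n_samples` must be positive")
  if (n_cpgs <= 0) stop("`n_cpgs` must be positive")
  if (theta <= 0) stop("count dispersion `theta` must be > 0")
  stopifnot(all(c("id", "family", "age_col") %in% names(outcomes)),
            all(outcomes$family %in% c("continuous", "count")))
  if (!is.null(planted_paths) && nrow(planted_paths)) {
    need <- c("exposure", "cpg", "outcome", "a", "b", "c_direct")
    miss <- setdiff(need, names(planted_paths))
    if (length(miss)) stop("planted_paths missing column(s): ",
                           paste(miss, collapse = ", "))
    bad <- setdiff(planted_paths$outcome, outcomes$id)
    if (length(bad)) stop("planted outcome(s) not in outcome spec: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(
    n_samples = as.integer(n_samples), n_cpgs = as.integer(n_cpgs),
    n_exposures = as.integer(n_exposures), outcomes = outcomes,
    planted_paths = planted_paths, sd_m = sd_m, sd_y = sd_y, theta = theta,
    count_baseline = count_baseline, continuous_baseline = continuous_baseline,
    exposure_meanlog = exposure_meanlog, exposure_sdlog = exposure_sdlog,
    cell_alpha = cell_alpha, gamma_sd = gamma_sd,
    cell_confounding_strength = cell_confounding_strength,
    sex_chromosome_fraction = sex_chromosome_fraction,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_outcome_spec <- function() {
  data.frame(
    id = c("iq_age5", "iq_age7", "cbcl_social_age7", "cbcl_internal_age9"),
    family = c("continuous", "continuous", "count", "count"),
    age_col = c("age_testing5", "age_testing7", "age_testing7", "age_testing9"),
    stringsAsFactors = FALSE
  )
}

#' @rdname sim_config
#' @export
default_planted_paths <- function() {
  data.frame(exposure = "exp01", cpg = "cg00000001",
             outcome = "cbcl_social_age7",
             a = 0.8, b = 0.8, c_direct = 0.3, stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @param x Object to test or print.
#' @param ... Unused.
#' @export
print.sim_config <- function(x, ...) {
  np <- if (is.null(x$planted_paths)) 0L else nrow(x$planted_paths)
  cat(sprintf(paste0("<sim_config> n=%d, %d CpGs, %d exposures, %d outcomes, ",
                     "%d planted path(s), seed=%d\n"),
              x$n_samples, x$n_cpgs, x$n_exposures, nrow(x$outcomes), np, x$seed))
  invisible(x)
}

# Dirichlet sampler via normalized gammas (rows sum to 1 exactly).
rdirichlet_mat <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

inv_logit2 <- function(m) 1 / (1 + 2^(-m))

#' Generate a synthetic birth cohort with planted mediation triangles
#'
#' Draws covariates (sex, ethnicity, ages at testing), cord-blood-like
#' cell-type proportions, log-normal exposures, a methylation matrix, and
#' outcomes of both families, then records every planted effect in a
#' ground-truth ledger so downstream stages can be scored against it.
#'
#' Methylation is generated on the M-value scale as
#' baseline + cell-mixture shift + planted `a * exposure` + Gaussian noise,
#' then transformed to beta-values by inverse logit2, so that the
#' preprocessing pipeline's logit2 transform recovers the generative scale
#' exactly. Outcomes depend on the cell-free mediator signal
#' (`a * exposure + noise`), so cell-composition residualization is a real,
#' testable de-confounding step rather than a no-op.
#'
#' The ledger's `true_proportion` per planted path is the closed form
#' `|a*b| / (|a*b| + |c_direct|)`, which the mediation stage's
#' difference-of-coefficients estimator targets in the linear-Gaussian case
#' and, because the mediator is conditionally Gaussian, also under the NB
#' log link (the marginal log-mean stays linear in the exposure with slope
#' `c_direct + a*b`).
#'
#' @param config A [sim_config()].
#' @return A list with elements `cohort` (data frame: `sample_id`, `sex`,
#'   `ethnicity`, age columns, `cell_*` proportions, `exp*` exposures,
#'   outcome columns), `methylation` (a beta-stage [meth_matrix]),
#'   `manifest` (CpG annotation data frame) and `truth` (class
#'   `ground_truth`: `planted_paths` with `true_proportion`, plus
#'   `null_cpg_ids`).
#' @examples
#' cfg <- sim_config(n_samples = 60, n_cpgs = 20, seed = 7)
#' sim <- generate_cohort(cfg)
#' sim$truth$planted_paths
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  p <- config$n_cpgs

  ids <- sprintf("S%04d", seq_len(n))
  cpgs <- sprintf("cg%08d", seq_len(p))
  paths <- config$planted_paths
  if (is.null(paths)) paths <- default_planted_paths()[0, ]
  if (nrow(paths) && !all(paths$cpg %in% cpgs))
    stop("planted CpG ids must be among the generated CpGs (cg00000001 ...)")

  cohort <- data.frame(
    sample_id = ids,
    sex = sample(c("male", "female"), n, replace = TRUE),
    ethnicity = sample(c("Dominican", "AfricanAmerican"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  for (ac in unique(config$outcomes$age_col)) {
    mid <- as.numeric(sub("age_testing", "", ac))
    cohort[[ac]] <- stats::runif(n, mid - 0.5, mid + 0.5)
  }

  cells <- rdirichlet_mat(n, config$cell_alpha)
  colnames(cells) <- names(config$cell_alpha)
  cell_center <- config$cell_alpha / sum(config$cell_alpha)
  cells_c <- sweep(cells, 2, cell_center)
  for (ct in colnames(cells)) cohort[[paste0("cell_", ct)]] <- cells[, ct]

  expo <- matrix(stats::rlnorm(n * config$n_exposures,
                               config$exposure_meanlog, config$exposure_sdlog),
                 nrow = n)
  colnames(expo) <- sprintf("exp%02d", seq_len(config$n_exposures))
  if (config$cell_confounding_strength > 0) {
    g <- cells_c[, 1]
    expo[, 1] <- expo[, 1] + config$cell_confounding_strength * g / stats::sd(g)
  }
  for (j in colnames(expo)) cohort[[j]] <- expo[, j]

  # M-value model: baseline + cell loadings + planted a*X + noise
  mu <- stats::rnorm(p, 0, 2)
  gamma <- matrix(stats::rnorm(p * ncol(cells), 0, config$gamma_sd), nrow = p)
  eps <- matrix(stats::rnorm(n * p, 0, config$sd_m), nrow = n)
  signal <- matrix(0, n, p, dimnames = list(ids, cpgs))
  if (nrow(paths)) {
    for (r in seq_len(nrow(paths))) {
      k <- match(paths$cpg[r], cpgs)
      signal[, k] <- signal[, k] + paths$a[r] * expo[, paths$exposure[r]]
    }
  }
  M <- sweep(cells_c %*% t(gamma), 2, mu, `+`) + signal + eps
  dimnames(M) <- list(ids, cpgs)

  # mediator seen by outcomes: the cell-free part (survives residualization)
  med <- signal + eps

  sex_i <- as.numeric(cohort$sex == "male")
  eth_i <- as.numeric(cohort$ethnicity == "Dominican")
  for (o in seq_len(nrow(config$outcomes))) {
    oid <- config$outcomes$id[o]
    fam <- config$outcomes$family[o]
    age <- cohort[[config$outcomes$age_col[o]]]
    eta <- rep(0, n)
    rows <- which(paths$outcome == oid)
    for (r in rows) {
      k <- match(paths$cpg[r], cpgs)
      eta <- eta + paths$b[r] * med[, k] + paths$c_direct[r] * expo[, paths$exposure[r]]
    }
    if (fam == "continuous") {
      y <- config$continuous_baseline + eta - 2 * sex_i - 3 * eth_i +
        1 * (age - mean(age)) + stats::rnorm(n, 0, config$sd_y)
    } else {
      lin <- log(config$count_baseline) + eta + 0.2 * sex_i + 0.15 * eth_i +
        0.05 * (age - mean(age))
      y <- stats::rnbinom(n, size = config$theta, mu = exp(lin))
    }
    cohort[[oid]] <- y
  }

  beta <- inv_logit2(M)
  eps_b <- 1e-6
  n_clamp <- sum(beta < eps_b | beta > 1 - eps_b, na.rm = TRUE)
  if (n_clamp > 0) {
    warning(sprintf("%d beta-values outside (%g, %g) clamped", n_clamp,
                    eps_b, 1 - eps_b))
    beta <- pmin(pmax(beta, eps_b), 1 - eps_b)
  }
  if (config$missing_rate > 0) {
    drop <- stats::runif(n * p) < config$missing_rate
    beta[drop] <- NA_real_
  }

  # manifest: planted CpGs on autosomes with dedicated genes; a fixed-fraction
  # tail of null CpGs annotated to sex chromosomes
  genes <- sprintf("GENE%04d", ((seq_len(p) - 1L) %/% 3L) + 1L)
  if (nrow(paths)) {
    pk <- match(unique(paths$cpg), cpgs)
    genes[pk] <- sprintf("PLGENE%02d", seq_along(pk))
  }
  chr <- as.character(sample(1:22, p, replace = TRUE))
  n_sex <- round(config$sex_chromosome_fraction * p)
  if (n_sex > 0) {
    cand <- setdiff(seq_len(p), match(paths$cpg, cpgs))
    sx <- utils::tail(cand, n_sex)
    chr[sx] <- rep(c("X", "Y"), length.out = length(sx))
  }
  manifest <- data.frame(cpg_id = cpgs, chr = chr,
                         pos = sample.int(2e8, p), gene = genes,
                         stringsAsFactors = FALSE)

  truth <- structure(list(
    planted_paths = if (nrow(paths)) {
      transform(paths,
                true_proportion = abs(a * b) / (abs(a * b) + abs(c_direct)))
    } else cbind(paths, true_proportion = numeric(0)),
    null_cpg_ids = setdiff(cpgs, paths$cpg)
  ), class = "ground_truth")

  list(cohort = cohort, methylation = meth_matrix(beta, "beta"),
       manifest = manifest, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d planted path(s), %d null CpGs\n",
              nrow(x$planted_paths), length(x$null_cpg_ids)))
  invisible(x)
}
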