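# Shared fixtures and independent oracles, built in code at test time.

# Brute-force Benjamini-Hochberg step-up: for each p at sorted rank i,
# adj = min over ranks j >= i of p_(j) * m / j, capped at 1. Kept deliberately
# O(n^2) and independent of the implementation it checks.
bh_oracle <- function(p, m = length(p)) {
  o <- order(p)
  ps <- p[o]
  n <- length(p)
  adj_sorted <- numeric(n)
  for (i in seq_len(n))
    adj_sorted[i] <- min(1, min(ps[i:n] * m / (i:n)))
  adj <- numeric(n)
  adj[o] <- adj_sorted
  adj
}

# Small cohort config for fast unit tests.
small_config <- function(seed = 1L, ...) {
  sim_config(n_samples = 150L, n_cpgs = 30L, n_exposures = 4L,
             sex_chromosome_fraction = 0, seed = seed, ...)
}

# Preprocess a generated cohort to M-residuals (QC skipped when clean).
to_residuals <- function(sim) {
  cells <- as.matrix(sim$cohort[, grep("^cell_", names(sim$cohort))])
  rownames(cells) <- sim$cohort$sample_id
  residualize_cells(beta_to_m(sim$methylation), cells)
}

# Tiny hand-built methylation matrix.
toy_meth <- function(values, stage = "beta") {
  meth_matrix(values, stage = stage)
}

# Linear-Gaussian mediation dataset where the mediator residual is
# orthogonalized against exposure and covariates, making OLS estimates
# exactly equal to the generative slopes (noiseless in the estimation sense).
exact_mediation_data <- function(n = 80, a = 0.5, b = 0.5, c_dir = 0.25,
                                 seed = 5) {
  set.seed(seed)
  x <- rnorm(n)
  covs <- toy_covs(n, seed = seed + 1)
  Z <- model.matrix(~ x + sex + ethnicity + age, data = cbind(covs, x = x))
  e <- residuals(lm.fit(Z, rnorm(n)))     # orthogonal to x and all covariates
  med <- a * x + e
  y <- c_dir * x + b * med                # outcome noiseless given (x, med)
  list(y = y, x = x, med = med, covs = covs)
}

# Covariate frame of the kind the screens expect.
toy_covs <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(sex = sample(c("male", "female"), n, replace = TRUE),
             ethnicity = sample(c("Dominican", "AfricanAmerican"), n,
                                replace = TRUE),
             age = runif(n, 6.5, 7.5), stringsAsFactors = FALSE)
}
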