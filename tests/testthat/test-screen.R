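test_that("Gaussian screen fit is exact on a noise-free linear relation", {
  n <- 40
  covs <- toy_covs(n, seed = 2)
  cpg <- rnorm(n)
  y <- 2 * cpg
  r <- fit_outcome_on_cpg(y, cpg, covs, "continuous")
  expect_true(r$converged)
  expect_equal(r$estimate, 2, tolerance = 1e-10)
  expect_lt(r$p_raw, 1e-12)
})

test_that("degenerate predictors are flagged and carry p = 1", {
  n <- 40
  covs <- toy_covs(n, seed = 3)
  y <- rnorm(n)
  r <- fit_outcome_on_cpg(y, rep(0.3, n), covs, "continuous")
  expect_false(r$converged)
  expect_equal(r$p_raw, 1)
  expect_identical(r$note, "constant_predictor")

  # exposure duplicated as a covariate -> rank-deficient design, flagged
  x <- rnorm(n)
  covs2 <- cbind(covs, dup = x)
  r2 <- fit_cpg_on_exposure(rnorm(n), x, covs2)
  expect_false(r2$converged)
  expect_identical(r2$note, "rank_deficient_design")

  # too few complete cases
  y3 <- c(rnorm(10), rep(NA, 30))
  r3 <- fit_outcome_on_cpg(y3, rnorm(n), covs, "continuous")
  expect_identical(r3$note, "too_few_complete_cases")
})

test_that("negative binomial screen fit matches MASS::glm.nb to machine precision", {
  set.seed(101)
  n <- 240
  covs <- toy_covs(n, seed = 101)
  med <- rnorm(n, sd = 0.5)
  sexI <- as.numeric(covs$sex == "male")
  ethI <- as.numeric(covs$ethnicity == "Dominican")
  y <- rnbinom(n, size = 2, mu = exp(1 + 0.5807 * med + 0.2 * sexI))
  r <- fit_outcome_on_cpg(y, med, covs, "count")
  oracle <- MASS::glm.nb(y ~ med + sexI + ethI + covs$age)
  so <- summary(oracle)$coefficients
  expect_equal(r$estimate, unname(so["med", 1]), tolerance = 1e-7)
  expect_equal(r$se, unname(so["med", 2]), tolerance = 1e-7)
  expect_equal(r$p_raw, unname(so["med", 4]), tolerance = 1e-6)
})

test_that("planted effects are recovered within 3 SEs by every screen model", {
  # no direct effect, so each screen model's closed-form estimand is the
  # planted slope itself (Step 2: b, Step 3: a, Step 4: a*b)
  paths <- data.frame(exposure = "exp01", cpg = "cg00000001",
                      outcome = "cbcl_social_age7",
                      a = 0.2333, b = 0.5807, c_direct = 0)
  cfg <- sim_config(n_samples = 240, n_cpgs = 10, n_exposures = 2,
                    planted_paths = paths, sex_chromosome_fraction = 0,
                    exposure_sdlog = 1, seed = 77)
  sim <- generate_cohort(cfg)
  resid <- to_residuals(sim)
  med <- resid$values[, "cg00000001"]
  covs <- data.frame(sex = sim$cohort$sex, ethnicity = sim$cohort$ethnicity,
                     age = sim$cohort$age_testing7)
  covs_m <- covs[, c("sex", "ethnicity")]

  r2 <- fit_outcome_on_cpg(sim$cohort$cbcl_social_age7, med, covs, "count")
  expect_lt(abs(r2$estimate - 0.5807), 3 * r2$se)

  r3 <- fit_cpg_on_exposure(med, sim$cohort$exp01, covs_m)
  expect_lt(abs(r3$estimate - 0.2333), 3 * r3$se)

  total_truth <- 0.2333 * 0.5807
  r4 <- fit_outcome_on_exposure(sim$cohort$cbcl_social_age7, sim$cohort$exp01,
                                covs, "count")
  expect_lt(abs(r4$estimate - total_truth), 3 * r4$se)
})

test_that("null exposure-CpG p-values are uniform (KS over replicates)", {
  set.seed(500)
  ps <- vapply(1:400, function(i) {
    n <- 100
    covs <- data.frame(sex = sample(c("male", "female"), n, TRUE),
                       ethnicity = sample(c("Dominican", "AfricanAmerican"), n, TRUE))
    fit_cpg_on_exposure(rnorm(n), rlnorm(n, 0, 0.5), covs)$p_raw
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("null outcome-exposure rejections sit at the nominal 5% level", {
  set.seed(600)
  rej <- vapply(1:400, function(i) {
    n <- 120
    covs <- toy_covs(n, seed = 600 + i)
    y <- rnorm(n, 100, 12)
    fit_outcome_on_exposure(y, rlnorm(n, 0, 0.5), covs, "continuous")$p_raw < 0.05
  }, logical(1))
  # binomial 3-sigma band around 0.05 at 400 replicates
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("Poisson fallback engages without over-dispersion and matches sandwich HC0", {
  skip_if_not_installed("sandwich")
  set.seed(9)
  n <- 200
  x <- rnorm(n)
  sexI <- rbinom(n, 1, 0.5); ethI <- rbinom(n, 1, 0.5); age <- runif(n, 6.5, 7.5)
  y <- rpois(n, exp(1 + 0.2 * x))   # equidispersed: NB theta diverges
  covs <- data.frame(sex = sexI, ethnicity = ethI, age = age)
  r <- fit_outcome_on_cpg(y, x, covs, "count")
  expect_true(r$converged)
  expect_identical(r$note, "poisson_fallback_robust_se")
  g <- glm(y ~ x + sexI + ethI + age, family = poisson())
  se_sand <- sqrt(diag(sandwich::vcovHC(g, type = "HC0")))[["x"]]
  expect_equal(r$se, se_sand, tolerance = 1e-6)
  expect_equal(r$estimate, unname(coef(g)[["x"]]), tolerance = 1e-8)
})

test_that("bh_adjust reproduces the step-up oracle and its textbook cases", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03, m = 1), 0.03)
  expect_error(bh_adjust(c(0.1, 0.2), m = 1), "at least")
  expect_error(bh_adjust(c(-0.1, 0.5)), "0, 1")

  # padding the family beyond the observed tests preserves order and adj >= raw
  p <- c(0.0008, 0.0313)
  adj <- bh_adjust(p, m = 40)
  expect_true(all(adj >= p))
  expect_true(all(diff(order(adj)) == diff(order(p))))
  expect_equal(adj, bh_oracle(p, m = 40), tolerance = 1e-15)

  set.seed(77)
  for (i in 1:100) {
    len <- sample(1:50, 1)
    p <- runif(len)
    m <- len + sample(0:20, 1)
    expect_equal(bh_adjust(p, m), bh_oracle(p, m), tolerance = 1e-12)
  }
})

test_that("the cascade selects exactly one strong planted triple and nothing else", {
  cfg <- sim_config(n_samples = 240, n_cpgs = 60, n_exposures = 5,
                    sex_chromosome_fraction = 0, seed = 21)
  sim <- generate_cohort(cfg)
  resid <- to_residuals(sim)
  unis <- setNames(rep(list(cpg_ids(resid)), 4), cfg$outcomes$id)
  cas <- run_sequential_screen(sim$cohort, resid, unis, cfg$outcomes,
                               sprintf("exp%02d", 1:5))
  expect_equal(nrow(cas$triples), 1)
  expect_identical(cas$triples$outcome, "cbcl_social_age7")
  expect_identical(cas$triples$exposure, "exp01")
  expect_identical(cas$triples$mediators, "cg00000001")
})

test_that("an all-null cohort propagates emptiness down the cascade", {
  cfg <- sim_config(n_samples = 200, n_cpgs = 40, n_exposures = 4,
                    planted_paths = NULL, sex_chromosome_fraction = 0,
                    seed = 22)
  sim <- generate_cohort(cfg)
  resid <- to_residuals(sim)
  unis <- setNames(rep(list(cpg_ids(resid)), 4), cfg$outcomes$id)
  cas <- run_sequential_screen(sim$cohort, resid, unis, cfg$outcomes,
                               sprintf("exp%02d", 1:4))
  if (sum(cas$step2$selected) == 0) {
    expect_null(cas$step3)
    expect_null(cas$step4)
    expect_null(cas$triples)
  } else {
    succeed("a Step-2 false positive occurred; emptiness propagation not applicable")
  }
})

test_that("screening is per-outcome independent: outcome order never matters", {
  cfg <- sim_config(n_samples = 150, n_cpgs = 30, n_exposures = 3,
                    sex_chromosome_fraction = 0, seed = 23)
  sim <- generate_cohort(cfg)
  resid <- to_residuals(sim)
  unis <- setNames(rep(list(cpg_ids(resid)), 4), cfg$outcomes$id)
  cas1 <- run_sequential_screen(sim$cohort, resid, unis, cfg$outcomes,
                                sprintf("exp%02d", 1:3))
  spec_rev <- cfg$outcomes[rev(seq_len(nrow(cfg$outcomes))), ]
  cas2 <- run_sequential_screen(sim$cohort, resid, unis, spec_rev,
                                sprintf("exp%02d", 1:3))
  key <- function(d) d[order(d$response, d$predictor),
                       c("response", "predictor", "estimate", "p_raw", "p_adj")]
  expect_equal(key(cas1$step2), key(cas2$step2), ignore_attr = TRUE)
  expect_equal(cas1$triples, cas2$triples)
})

test_that("outcomes with empty universes are skipped without derailing the rest", {
  cfg <- sim_config(n_samples = 150, n_cpgs = 30, n_exposures = 3,
                    sex_chromosome_fraction = 0, seed = 24)
  sim <- generate_cohort(cfg)
  resid <- to_residuals(sim)
  unis <- list(iq_age5 = character(0), iq_age7 = cpg_ids(resid),
               cbcl_social_age7 = cpg_ids(resid),
               cbcl_internal_age9 = character(0))
  cas <- run_sequential_screen(sim$cohort, resid, unis, cfg$outcomes,
                               sprintf("exp%02d", 1:3))
  expect_false("iq_age5" %in% cas$step2$response)
  expect_false("cbcl_internal_age9" %in% cas$step2$response)
  expect_true("cbcl_social_age7" %in% cas$step2$response)
})
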