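make_qc_fixture <- function() {
  set.seed(42)
  v <- matrix(runif(10 * 20, 0.2, 0.8), 10, 20,
              dimnames = list(sprintf("s%02d", 1:10), sprintf("cg%03d", 1:20)))
  manifest <- data.frame(cpg_id = colnames(v),
                         chr = c(rep("1", 18), "X", "Y"),
                         pos = seq_len(20), gene = "G1",
                         stringsAsFactors = FALSE)
  list(v = v, manifest = manifest)
}

test_that("qc_filter drops low-coverage samples, low-coverage CpGs, and sex chromosomes", {
  fx <- make_qc_fixture()
  v <- fx$v
  v["s01", 1:2] <- NA                       # sample at 90% CpG coverage
  v[2:10, "cg003"] <- NA                    # CpG at 10% coverage (s01 gone)
  res <- qc_filter(meth_matrix(v, "beta"), fx$manifest)
  expect_false("s01" %in% sample_ids(res$matrix))
  expect_false("cg003" %in% cpg_ids(res$matrix))
  expect_false(any(c("cg019", "cg020") %in% cpg_ids(res$matrix)))
  expect_equal(res$report$dropped, c(1, 1, 2))
})

test_that("qc_filter is the identity on clean autosomal data, and idempotent", {
  fx <- make_qc_fixture()
  auto <- fx$v[, 1:18]
  res <- qc_filter(meth_matrix(auto, "beta"), fx$manifest)
  expect_identical(res$matrix$values, auto)
  twice <- qc_filter(res$matrix, fx$manifest)
  expect_identical(twice$matrix$values, res$matrix$values)
})

test_that("qc_filter fails loudly when every sample is dropped, naming the threshold", {
  fx <- make_qc_fixture()
  v <- fx$v
  v[, 1:2] <- NA  # every sample at 90% coverage
  expect_error(qc_filter(meth_matrix(v, "beta"), fx$manifest), "95%")
})

test_that("logit2 transform hits the textbook identities and round-trips", {
  b <- toy_meth(matrix(c(0.5, 0.8, 0.25), 1, 3,
                       dimnames = list("s1", c("cg1", "cg2", "cg3"))))
  m <- beta_to_m(b)
  expect_identical(m$stage, "M")
  expect_equal(unname(m$values[1, ]), c(0, 2, -log2(3)))

  set.seed(1)
  v <- matrix(runif(200, 1e-5, 1 - 1e-5), 10, 20,
              dimnames = list(sprintf("s%d", 1:10), sprintf("cg%d", 1:20)))
  back <- m_to_beta(beta_to_m(toy_meth(v)))
  expect_lt(max(abs(back$values - v)), 1e-9)
})

test_that("boundary beta-values are clamped with a warning before the logit", {
  v <- matrix(c(0, 1, 0.5, 0.5), 2, 2,
              dimnames = list(c("s1", "s2"), c("cg1", "cg2")))
  expect_warning(m <- beta_to_m(toy_meth(v)), "2 boundary")
  expect_true(all(is.finite(m$values)))
  expect_equal(m$values["s1", "cg1"], log2(1e-6 / (1 - 1e-6)))
})

test_that("residualize_cells annihilates exact cell-combinations and is orthogonal", {
  set.seed(7)
  n <- 50
  cells <- matrix(rgamma(n * 4, shape = rep(c(10, 5, 3, 2), each = n)), n, 4)
  cells <- cells / rowSums(cells)
  rownames(cells) <- sprintf("s%02d", 1:n)
  exact <- 2 + cells[, 1] * 3 - cells[, 2] * 1.5        # exact linear comb
  indep <- rnorm(n)                                     # independent of cells
  M <- cbind(cg1 = exact, cg2 = indep)
  rownames(M) <- rownames(cells)
  res <- residualize_cells(meth_matrix(M, "M"), cells)
  expect_identical(res$stage, "M_residual")
  expect_lt(max(abs(res$values[, "cg1"])), 1e-8)
  # OLS orthogonality against every retained column
  for (j in 1:3)
    expect_lt(abs(cor(res$values[, "cg2"], cells[, j])), 1e-8)
  # matches an independent lm() oracle on the same arrays
  oracle <- residuals(lm(indep ~ cells[, 1:3]))
  expect_equal(unname(res$values[, "cg2"]), unname(oracle), tolerance = 1e-10)
  # variance essentially preserved for cell-independent input
  expect_gt(var(res$values[, "cg2"]) / var(indep), 0.85)
})

test_that("residualize_cells rejects designs that stay singular after the drop", {
  n <- 30
  a <- runif(n, 0.1, 0.3); b <- runif(n, 0.1, 0.3)
  c1 <- (1 - a - b) / 2
  cells <- cbind(a = a, b = b, c1 = c1, c2 = c1)  # c1 duplicated; rows sum to 1
  rownames(cells) <- sprintf("s%02d", 1:n)
  M <- matrix(rnorm(n), n, 1, dimnames = list(rownames(cells), "cg1"))
  expect_error(residualize_cells(meth_matrix(M, "M"), cells), "rank deficient")
})

test_that("residualization removes a planted cell-composition confounder", {
  # exposure 1 is correlated with cell composition; CpGs load on cells but
  # carry no direct exposure effect, so pre-residual slopes are inflated and
  # post-residual ones are null-calibrated
  cfg <- sim_config(n_samples = 400, n_cpgs = 40, n_exposures = 2,
                    planted_paths = NULL, cell_confounding_strength = 3,
                    gamma_sd = 3, sex_chromosome_fraction = 0, seed = 31)
  sim <- generate_cohort(cfg)
  M <- beta_to_m(sim$methylation)
  resid <- to_residuals(sim)
  x <- sim$cohort$exp01
  z_pre <- apply(M$values, 2, function(m) {
    f <- summary(lm(m ~ x))$coefficients
    f[2, 3]
  })
  z_post <- apply(resid$values, 2, function(m) {
    f <- summary(lm(m ~ x))$coefficients
    f[2, 3]
  })
  expect_gt(mean(abs(z_pre)), 2)          # confounding visible before
  expect_lt(mean(z_post^2), 1.6)          # ~ chi-square(1) mean after
  expect_lt(abs(mean(z_post)), 3 / sqrt(length(z_post)) * 1.3)
})

test_that("4-SD trimming removes the planted outlier and spares constants", {
  set.seed(4)
  x <- stats::setNames(c(scale(rnorm(100))[, 1], 4.5), sprintf("s%03d", 1:101))
  tr <- trim_outliers(x)
  expect_true("s101" %in% tr$removed_ids)

  const <- rep(3.3, 50)
  tr2 <- trim_outliers(const)
  expect_equal(tr2$n_removed, 0)
  expect_equal(tr2$kept, const)

  expect_error(trim_outliers(c(1, 2)), "at least 3")
})

test_that("a standard normal sample of 240 loses fewer than two values to trimming", {
  set.seed(240)
  tr <- trim_outliers(rnorm(240))
  expect_lt(tr$n_removed, 2)
})

test_that("trimming is single-pass: mean and SD are not recomputed after removal", {
  # one huge outlier inflates the SD enough to shelter a 5-sigma point;
  # iterated trimming would remove both, single-pass removes only the huge one
  v <- c(rnorm(200, sd = 1), 5, 60)
  tr <- trim_outliers(v)
  expect_equal(tr$n_removed, 1)
  expect_false(60 %in% tr$kept)
  expect_true(5 %in% tr$kept)
})

test_that("split_cohort reproduces the 240/101 allocation and is seed-stable", {
  ids <- sprintf("S%04d", 1:341)
  s <- split_cohort(ids, 0.70, seed = 99)
  expect_length(s$discovery, 240)
  expect_length(s$validation, 101)
  expect_identical(s, split_cohort(ids, 0.70, seed = 99))
  expect_false(identical(s$discovery, split_cohort(ids, 0.70, seed = 100)$discovery))
  expect_setequal(c(s$discovery, s$validation), ids)
  expect_length(intersect(s$discovery, s$validation), 0)

  s2 <- split_cohort(sprintf("S%03d", 1:100), 0.70, seed = 1)
  expect_length(s2$discovery, 70)
  expect_error(split_cohort("only_one", 0.5), "at least 2")
  expect_error(split_cohort(ids, 1.2), "in \\(0, 1\\)")
})
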