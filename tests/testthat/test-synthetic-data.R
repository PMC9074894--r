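test_that("identical seed and config give bit-identical cohorts", {
  cfg <- small_config(seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$methylation$values, b$methylation$values)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$truth, b$truth)
})

test_that("all-null config yields an empty planted ledger and all-null CpGs", {
  cfg <- small_config(seed = 2, planted_paths = NULL)
  sim <- generate_cohort(cfg)
  expect_equal(nrow(sim$truth$planted_paths), 0)
  expect_setequal(sim$truth$null_cpg_ids, cpg_ids(sim$methylation))
})

test_that("ground-truth proportion follows the closed form |ab|/(|ab|+|c|)", {
  paths <- data.frame(exposure = "exp01", cpg = "cg00000001",
                      outcome = "cbcl_social_age7",
                      a = 0.5, b = 0.5, c_direct = 0.25)
  sim <- generate_cohort(small_config(seed = 3, planted_paths = paths))
  expect_equal(sim$truth$planted_paths$true_proportion, 0.5)
  # opposite-sign path: absolute values in the closed form
  paths2 <- transform(paths, a = -0.5)
  sim2 <- generate_cohort(small_config(seed = 3, planted_paths = paths2))
  expect_equal(sim2$truth$planted_paths$true_proportion, 0.5)
  # planted CpGs exist in matrix and manifest
  expect_true(paths$cpg %in% cpg_ids(sim$methylation))
  expect_true(paths$cpg %in% sim$manifest$cpg_id)
})

test_that("OLS on the generated arrays recovers the planted exposure-CpG slope", {
  paths <- data.frame(exposure = "exp01", cpg = "cg00000001",
                      outcome = "cbcl_social_age7",
                      a = 0.5, b = 0.5, c_direct = 0.25)
  cfg <- sim_config(n_samples = 300, n_cpgs = 20, n_exposures = 4,
                    planted_paths = paths, sex_chromosome_fraction = 0,
                    seed = 1)
  sim <- generate_cohort(cfg)
  resid <- to_residuals(sim)
  fit <- summary(lm(resid$values[, "cg00000001"] ~ sim$cohort$exp01))
  est <- fit$coefficients[2, 1]
  se <- fit$coefficients[2, 2]
  expect_lt(abs(est - 0.5), 3 * se)
})

test_that("count outcomes are NB2: ML dispersion and Pearson stat agree at n=10000", {
  cfg <- sim_config(n_samples = 10000, n_cpgs = 3, n_exposures = 2,
                    planted_paths = NULL, sex_chromosome_fraction = 0,
                    seed = 5)
  sim <- generate_cohort(cfg)
  y <- sim$cohort$cbcl_social_age7
  sexI <- as.numeric(sim$cohort$sex == "male")
  ethI <- as.numeric(sim$cohort$ethnicity == "Dominican")
  fit <- MASS::glm.nb(y ~ sexI + ethI + sim$cohort$age_testing7)
  expect_lt(abs(fit$theta - 2) / 2, 0.15)
  pearson <- sum(residuals(fit, type = "pearson")^2) / fit$df.residual
  expect_lt(abs(pearson - 1), 0.1)
  # empirical variance consistent with mu + mu^2/theta
  mu <- fitted(fit)
  expect_lt(abs(var(y) / mean(mu + mu^2 / 2) - 1), 0.1)
})

test_that("with all effects zero, exposure-CpG residual correlations center at 0", {
  rs <- vapply(1:40, function(s) {
    sim <- generate_cohort(sim_config(n_samples = 150, n_cpgs = 5,
                                      n_exposures = 2, planted_paths = NULL,
                                      sex_chromosome_fraction = 0, seed = s))
    resid <- to_residuals(sim)
    cor(sim$cohort$exp01, resid$values[, 1])
  }, numeric(1))
  # Fisher-scale SE of a mean of 40 null correlations at n=150
  expect_lt(abs(mean(rs)), 3 / sqrt(147 * 40))
})

test_that("generator rejects invalid configurations", {
  expect_error(sim_config(n_samples = 0), "positive")
  expect_error(sim_config(theta = 0), "dispersion")
  expect_error(sim_config(planted_paths = data.frame(exposure = "exp01")),
               "missing column")
  bad <- default_planted_paths()
  bad$outcome <- "not_an_outcome"
  expect_error(sim_config(planted_paths = bad), "not in outcome spec")
})

test_that("cell proportions sum to one and betas stay inside (0,1)", {
  sim <- generate_cohort(small_config(seed = 9))
  cells <- as.matrix(sim$cohort[, grep("^cell_", names(sim$cohort))])
  expect_true(all(abs(rowSums(cells) - 1) < 1e-12))
  v <- sim$methylation$values
  expect_true(all(v > 0 & v < 1))
})

test_that("pathway fixture links planted genes to matching keywords, decoys to none", {
  cfg <- small_config(seed = 4)
  sim <- generate_cohort(cfg)
  fx <- generate_pathway_fixture(cfg, sim$manifest)
  ps <- fx$pathways
  expect_gte(length(ps$genes), 20)

  # every configured keyword is carried by at least one pathway
  kws <- unique(unlist(fx$profiles))
  for (kw in kws) {
    hits <- vapply(seq_len(nrow(ps$meta)),
                   function(i) match_keyword(ps$meta[i, ], kw), TRUE)
    expect_true(any(hits), label = sprintf("keyword '%s' has a pathway", kw))
  }

  # decoy pathways match no configured keyword
  decoys <- grep("^decoy", ps$meta$id)
  for (i in decoys) {
    hits <- vapply(kws, function(k) match_keyword(ps$meta[i, ], k), TRUE)
    expect_false(any(hits), label = sprintf("decoy %s matches no keyword",
                                            ps$meta$id[i]))
  }

  # planted gene is a member of a pathway matching the planted outcome profile
  planted_gene <- sim$manifest$gene[sim$manifest$cpg_id == "cg00000001"]
  target_kws <- fx$profiles[["cbcl_social_age7"]]
  carrier <- vapply(seq_len(nrow(ps$meta)), function(i) {
    any(vapply(target_kws, function(k) match_keyword(ps$meta[i, ], k), TRUE)) &&
      planted_gene %in% ps$genes[[ps$meta$id[i]]]
  }, TRUE)
  expect_true(any(carrier))
})

test_that("pathway fixture round-trips through the GMT writer/reader unchanged", {
  cfg <- small_config(seed = 6)
  fx <- generate_pathway_fixture(cfg)
  gmt <- withr::local_tempfile(fileext = ".gmt")
  meta <- withr::local_tempfile(fileext = ".tsv")
  write_gmt(fx$pathways, gmt)
  write_pathway_meta_tsv(fx$pathways, meta)
  back <- read_pathway_set(gmt, meta)
  expect_identical(back$genes, fx$pathways$genes)
  expect_identical(back$meta, fx$pathways$meta)
})

test_that("cohort, methylation, manifest and truth round-trip through their writers", {
  sim <- generate_cohort(small_config(seed = 8))
  d <- withr::local_tempdir()
  paths <- write_cohort_fixture(sim, out_dir = d)
  meth <- read_methylation_tsv(paths$methylation)
  expect_equal(meth$values, sim$methylation$values, tolerance = 1e-12)
  cohort <- read_cohort_tsv(paths$cohort)
  expect_equal(cohort$sample_id, sim$cohort$sample_id)
  expect_equal(cohort$exp01, sim$cohort$exp01, tolerance = 1e-12)
  manifest <- read_manifest_tsv(paths$manifest)
  expect_identical(manifest$cpg_id, sim$manifest$cpg_id)
  expect_identical(manifest$gene, sim$manifest$gene)
  truth <- read_ground_truth_json(paths$truth)
  expect_equal(truth$planted_paths$true_proportion,
               sim$truth$planted_paths$true_proportion)
  expect_identical(truth$null_cpg_ids, sim$truth$null_cpg_ids)
})
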