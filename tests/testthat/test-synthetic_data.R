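test_that("the generator is deterministic under a seed and leaves the RNG alone", {
  cfg <- sim_config(n_snps = 30, theta = 0.2, prop_invalid = 0.3,
                    alpha_mean = 0.01, alpha_sd = 0.004,
                    prop_palindromic = 0.1, seed = 12)
  set.seed(321)
  before <- .Random.seed
  a <- simulate_summary_pair(cfg)
  expect_identical(.Random.seed, before)
  b <- simulate_summary_pair(cfg)
  expect_identical(a, b)

  cat_a <- simulate_taxa_catalog(seed = 8)
  cat_b <- simulate_taxa_catalog(seed = 8)
  expect_identical(cat_a, cat_b)
})

test_that("truth bookkeeping matches the generating model", {
  cfg <- sim_config(n_snps = 40, theta = 0.3, prop_invalid = 0.25,
                    alpha_mean = 0.02, alpha_sd = 0.005, seed = 9)
  s <- simulate_summary_pair(cfg)
  expect_length(s$truth$gamma, 40)
  expect_length(s$truth$alpha, 40)
  expect_identical(s$truth$invalid_indices,
                   which(s$truth$alpha != 0))
  expect_length(s$truth$invalid_indices, 10)
  # reported SEs are the generating SEs: p-values reconstruct from beta/se
  expect_equal(s$exposure$pval,
               pmax(2 * pnorm(-abs(s$exposure$beta / s$exposure$se)),
                    .Machine$double.xmin))
  expect_true(all(s$exposure$eaf >= 0.05 & s$exposure$eaf <= 0.95))
  expect_identical(s$exposure$eaf, s$outcome$eaf)
})

test_that("the noiseless limit returns the true effects", {
  cfg <- sim_config(n_snps = 25, theta = 0.4, se_x_scale = 1e-10,
                    se_y_scale = 1e-10, seed = 3)
  s <- simulate_summary_pair(cfg)
  expect_equal(s$exposure$beta, s$truth$gamma, tolerance = 1e-6)
  expect_equal(s$outcome$beta, 0.4 * s$truth$gamma, tolerance = 1e-6)
})

test_that("standard errors follow the cohort calibration", {
  cfg <- sim_config(n_snps = 50, seed = 6)
  s <- simulate_summary_pair(cfg)
  eaf <- s$exposure$eaf
  expect_equal(s$exposure$se, 1 / sqrt(2 * eaf * (1 - eaf) * 18340))
  n_eff <- 4 / (1 / 1076 + 1 / 381977)
  expect_equal(s$outcome$se, 1 / sqrt(2 * eaf * (1 - eaf) * n_eff))
  # per-variant instrument strength lands in a plausible GWAS range
  f <- instrument_strength(s$exposure)$f_statistic
  expect_gt(mean(f), 30)
})

test_that("block LD structure drives clumping exactly as planned", {
  # no LD: every p-filtered variant survives
  cfg <- sim_config(n_snps = 30, theta = 0.3, ld_block_size = 1, seed = 44)
  s <- simulate_summary_pair(cfg)
  ld <- simulate_ld_table(s$exposure, cfg)
  expect_identical(nrow(clump(s$exposure, ld, 0.001, 10000)), 30L)

  # blocks of 5 at r2 = 0.8: exactly the smallest p per block survives
  cfg <- sim_config(n_snps = 30, theta = 0.3, ld_block_size = 5,
                    ld_within_r2 = 0.8, seed = 45)
  s <- simulate_summary_pair(cfg)
  ld <- simulate_ld_table(s$exposure, cfg)
  got <- clump(s$exposure, ld, 0.001, 10000)
  block <- ceiling(seq_len(30) / 5)
  expected <- vapply(split(seq_len(30), block), function(idx) {
    s$exposure$SNP[idx[which.min(s$exposure$pval[idx])]]
  }, character(1))
  expect_setequal(got$SNP, expected)

  # within-block r2 below the ceiling: nothing pruned
  cfg <- sim_config(n_snps = 30, theta = 0.3, ld_block_size = 5,
                    ld_within_r2 = 0.0005, seed = 46)
  s <- simulate_summary_pair(cfg)
  ld <- simulate_ld_table(s$exposure, cfg)
  expect_identical(nrow(clump(s$exposure, ld, 0.001, 10000)), 30L)
})

test_that("catalog generation respects the requested composition", {
  cat <- simulate_taxa_catalog(n_total = 211, n_unnamed = 15, seed = 2)
  expect_identical(nrow(cat), 211L)
  expect_identical(sum(!cat$is_named), 15L)
  expect_identical(nrow(filter_unnamed_taxa(cat)), 196L)

  cat0 <- simulate_taxa_catalog(n_total = 10, n_unnamed = 0,
                                level_counts = c(phylum = 2, class = 2,
                                                 order = 2, family = 2,
                                                 genus = 2), seed = 1)
  expect_identical(filter_unnamed_taxa(cat0), cat0)

  expect_error(simulate_taxa_catalog(n_total = 10, n_unnamed = 2,
                                     level_counts = c(phylum = 2, class = 2,
                                                      order = 2, family = 2,
                                                      genus = 2), seed = 1),
               "must sum to")
})

test_that("InSIDE violation induces the configured strength-pleiotropy link", {
  cfg <- sim_config(n_snps = 4000, prop_invalid = 1, alpha_mean = 0,
                    alpha_sd = 0.01, inside_correlation = 0.7, seed = 10)
  s <- simulate_summary_pair(cfg)
  expect_gt(cor(s$truth$gamma, s$truth$alpha), 0.6)
  cfg0 <- sim_config(n_snps = 4000, prop_invalid = 1, alpha_mean = 0,
                     alpha_sd = 0.01, inside_correlation = 0, seed = 10)
  s0 <- simulate_summary_pair(cfg0)
  expect_lt(abs(cor(s0$truth$gamma, s0$truth$alpha)), 0.1)
})
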