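test_that("p-value selection is strict and order preserving", {
  df <- tiny_sumstats()[c(1, 1, 1), ]
  df$SNP <- c("a", "b", "c")
  df$pval <- c(1e-6, 1e-5, 1e-4)
  got <- filter_by_pvalue(df, 1e-5)
  expect_identical(got$SNP, "a")  # boundary value excluded

  expect_identical(nrow(filter_by_pvalue(df[0, ], 0.5)), 0L)

  set.seed(31)
  big <- df[rep(1, 100), ]
  big$SNP <- paste0("rs", 1:100)
  big$pval <- runif(100)
  got <- filter_by_pvalue(big, 0.3)
  expect_identical(nrow(got), sum(big$pval < 0.3))  # brute-force count
  expect_identical(got$SNP, big$SNP[big$pval < 0.3])
})

test_that("greedy clumping follows the hand-run of the rule", {
  df <- data.frame(SNP = c("A", "B", "C"), chr = "1",
                   pos = c(100000L, 105000L, 110000L),
                   effect_allele = "A", other_allele = "G", eaf = 0.3,
                   beta = 0.1, se = 0.02,
                   pval = c(1e-8, 1e-6, 1e-7), n = 18340L,
                   stringsAsFactors = FALSE)
  ld <- ld_table(data.frame(variant_id_1 = c("A", "A"),
                            variant_id_2 = c("B", "C"),
                            r_squared = c(0.5, 0.0005)))
  got <- clump(df, ld, r2_max = 0.001, window_kb = 10000)
  expect_setequal(got$SNP, c("A", "C"))

  # independent variants survive untouched
  got <- clump(df, ld_table(), r2_max = 0.001, window_kb = 10000)
  expect_identical(got$SNP, df$SNP)

  # high LD but outside the window: both retained
  far <- df[1:2, ]
  far$pos <- c(1L, 20000001L)  # 20,000 kb apart
  ld2 <- ld_table(data.frame(variant_id_1 = "A", variant_id_2 = "B",
                             r_squared = 0.9))
  expect_identical(nrow(clump(far, ld2, 0.001, 10000)), 2L)
})

test_that("clumping is invariant to input order and leaves no correlated pair", {
  cfg <- sim_config(n_snps = 60, theta = 0.3, ld_block_size = 5,
                    ld_within_r2 = 0.8, seed = 91)
  s <- simulate_summary_pair(cfg)
  ld <- simulate_ld_table(s$exposure, cfg)
  ref <- clump(s$exposure, ld, 0.001, 10000)
  for (rep_seed in 1:5) {
    set.seed(rep_seed)
    shuffled <- s$exposure[sample.int(nrow(s$exposure)), ]
    got <- clump(shuffled, ld, 0.001, 10000)
    expect_setequal(got$SNP, ref$SNP)
  }
  # exhaustive pair scan of the retained set
  for (i in seq_len(nrow(ref))) {
    for (j in seq_len(nrow(ref))) {
      if (i >= j) next
      if (ref$chr[i] == ref$chr[j] &&
          abs(ref$pos[i] - ref$pos[j]) <= 1e7) {
        expect_lte(ld_lookup(ld, ref$SNP[i], ref$SNP[j]), 0.001)
      }
    }
  }
})

test_that("instrument strength matches hand evaluation of the printed formula", {
  df <- tiny_sumstats()[1, ]
  df$eaf <- 0.5; df$beta <- 0.1; df$n <- 18340L
  got <- instrument_strength(df, k = 1)
  expect_equal(got$r_squared, 0.005)
  expect_equal(got$f_statistic, 92.150754, tolerance = 1e-6)

  df$beta <- 0
  got <- instrument_strength(df)
  expect_equal(got$r_squared, 0)
  expect_equal(got$f_statistic, 0)

  df$eaf <- 0.9; df$beta <- 0.2
  got <- instrument_strength(df)
  expect_equal(got$maf, 0.1)
  expect_equal(got$r_squared, 2 * 0.1 * 0.9 * 0.04)

  df$eaf <- 1
  expect_error(instrument_strength(df), "degenerate allele frequency")
  df$eaf <- 0.5; df$n <- 2L
  expect_error(instrument_strength(df), "sample size")
})

test_that("F agrees with a direct reimplementation on random inputs", {
  set.seed(77)
  n_cases <- 1e4
  df <- data.frame(SNP = paste0("rs", 1:n_cases), chr = "1", pos = 1L,
                   effect_allele = "A", other_allele = "G",
                   eaf = runif(n_cases, 0.01, 0.99),
                   beta = rnorm(n_cases, 0, 0.3),
                   se = 0.01, pval = 0.5,
                   n = sample(100:500000, n_cases, replace = TRUE),
                   stringsAsFactors = FALSE)
  k <- 1
  got <- instrument_strength(df, k = k)
  maf <- ifelse(df$eaf < 0.5, df$eaf, 1 - df$eaf)
  r2 <- 2 * maf * (1 - maf) * df$beta * df$beta
  f <- r2 * (df$n - k - 1) / (k * (1 - r2))
  expect_lt(max(abs(got$f_statistic - f) / pmax(f, 1e-300)), 1e-12)
})

test_that("weak-instrument screening is strict at the threshold", {
  st <- data.frame(variant_id = c("a", "b", "c"), maf = 0.3,
                   r_squared = 0.001, f_statistic = c(9.9, 10, 10.1),
                   n = 18340L, k = 1)
  expect_identical(weak_instrument_filter(st, 10)$variant_id, "c")
  expect_identical(nrow(weak_instrument_filter(st, 0)), 3L)
})

test_that("aggregate strength uses the instrument count as k", {
  df <- tiny_sumstats()
  agg <- instrument_strength_aggregate(df)
  per <- instrument_strength(df, k = 1)
  r2 <- sum(per$r_squared)
  expect_equal(agg$f_statistic,
               r2 * (18340 - 2 - 1) / (2 * (1 - r2)))
})

test_that("the unnamed-taxon filter reproduces the catalog arithmetic", {
  cat <- simulate_taxa_catalog(n_total = 211, n_unnamed = 15, seed = 4)
  named <- filter_unnamed_taxa(cat)
  expect_identical(nrow(named), 196L)
  counts <- table(named$level)
  expect_identical(as.integer(counts[c("phylum", "class", "order",
                                       "family", "genus")]),
                   c(9L, 16L, 20L, 32L, 119L))

  all_named <- cat[cat$is_named, ]
  expect_identical(filter_unnamed_taxa(all_named), all_named)
})
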