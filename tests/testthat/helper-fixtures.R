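# Shared fixture builders for the suite. Everything is generated in code;
# no files ship with the tests.

# A harmonized set straight from aligned effect vectors.
make_hs <- function(bx, sx, by, sy, ids = NULL) {
  harmonized_set(bx, sx, by, sy, variant_ids = ids)
}

# A harmonized set from a simulated pair, ignoring allele bookkeeping
# (effects are aligned by construction).
sim_hs <- function(config) {
  s <- simulate_summary_pair(config)
  list(hs = make_hs(s$exposure$beta, s$exposure$se,
                    s$outcome$beta, s$outcome$se),
       truth = s$truth, exposure = s$exposure, outcome = s$outcome)
}

# Canonical two-row summary-statistics data.frame.
tiny_sumstats <- function() {
  data.frame(SNP = c("rs1", "rs2"), chr = c("1", "2"),
             pos = c(1000L, 2000L),
             effect_allele = c("A", "C"), other_allele = c("G", "T"),
             eaf = c(0.25, 0.6), beta = c(0.12, -0.34),
             se = c(0.05, 0.07), pval = c(1e-6, 2e-3),
             n = c(18340L, 18340L), stringsAsFactors = FALSE)
}

write_tsv_raw <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
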