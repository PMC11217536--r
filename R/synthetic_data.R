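#' Simulation configuration
#'
#' Collects the generating parameters for a synthetic exposure/outcome
#' summary-statistics pair. Defaults emulate the study design the package
#' targets: a microbiome-abundance exposure GWAS of 18,340 participants and
#' a binary-disease outcome GWAS with 1,076 cases and 381,977 controls.
#' Per-variant standard errors follow the standard GWAS approximations
#' `se_x = se_x_scale / sqrt(2 p (1 - p) n)` for a standardized
#' quantitative trait and
#' `se_y = se_y_scale / sqrt(2 p (1 - p) n_eff)` for a binary trait with
#' effective sample size `n_eff = 4 / (1/cases + 1/controls)`, where `p` is
#' the effect-allele frequency. The default instrument-effect distribution
#' `N(0.1, 0.02^2)` yields per-variant F-statistics spanning roughly 20-140
#' at these cohort sizes, the range typical of suggestive-threshold
#' microbiome instruments.
#'
#' @param n_snps Number of variants J.
#' @param theta True causal effect of the exposure on the outcome
#'   (log-odds per exposure unit).
#' @param gamma_mean,gamma_sd Distribution of the true instrument effects.
#' @param n_exposure Exposure GWAS sample size.
#' @param n_cases,n_controls Outcome GWAS case/control counts.
#' @param se_x_scale,se_y_scale Multipliers on the calibrated standard
#'   errors (1 = the cohort calibration above).
#' @param prop_invalid Fraction of variants given a horizontal pleiotropic
#'   effect on the outcome.
#' @param alpha_mean,alpha_sd Pleiotropic-effect distribution for invalid
#'   variants; a nonzero mean makes the pleiotropy directional.
#' @param inside_correlation Correlation between instrument strength and
#'   pleiotropic effect; 0 means the InSIDE assumption holds.
#' @param prop_palindromic Fraction of variants assigned palindromic
#'   (A/T or C/G) allele pairs.
#' @param ld_block_size Variants per LD block (1 = no LD).
#' @param ld_within_r2 Pairwise r-squared within a block.
#' @param seed RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 20, theta = 0, gamma_mean = 0.1,
                       gamma_sd = 0.02, n_exposure = 18340,
                       n_cases = 1076, n_controls = 381977,
                       se_x_scale = 1, se_y_scale = 1,
                       prop_invalid = 0, alpha_mean = 0, alpha_sd = 0,
                       inside_correlation = 0, prop_palindromic = 0,
                       ld_block_size = 1, ld_within_r2 = 0, seed = 1) {
  stopifnot(n_snps >= 1,
            prop_invalid >= 0, prop_invalid <= 1,
            prop_palindromic >= 0, prop_palindromic <= 1,
            se_x_scale > 0, se_y_scale > 0,
            abs(inside_correlation) <= 1,
            ld_block_size >= 1,
            ld_within_r2 >= 0, ld_within_r2 <= 1)
  structure(as.list(environment()), class = "sim_config")
}

NON_PALINDROMIC_PAIRS <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                                  "G", "A", "C", "A", "G", "T", "C", "T"),
                                ncol = 2, byrow = TRUE)
PALINDROMIC_PAIRS <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                            ncol = 2, byrow = TRUE)

#' Simulate an exposure/outcome summary-statistics pair with known truth
#'
#' Generates per-variant true instrument effects
#' `gamma_j ~ N(gamma_mean, gamma_sd^2)` and, for the configured fraction
#' of invalid variants, horizontal pleiotropic effects `alpha_j` with the
#' configured mean, spread, and correlation with instrument strength
#' (nonzero correlation violates InSIDE). Observed effects are
#' `bx_j = gamma_j + N(0, se_x_j^2)` and
#' `by_j = theta * gamma_j + alpha_j + N(0, se_y_j^2)`; reported standard
#' errors equal the generating ones, and p-values are two-sided normal.
#' Allele frequencies are Uniform(0.05, 0.95), shared between the two
#' datasets; allele pairs are palindromic for the configured fraction of
#' variants. Variants are laid out in LD blocks: consecutive blocks of
#' `ld_block_size` variants sit 1 kb apart within a block, with blocks 20
#' Mb apart on chromosomes cycling 1-22, so a block always falls inside a
#' standard 10 Mb clumping window and distinct blocks never do.
#'
#' @param config A [sim_config()].
#' @return A list with elements `exposure` and `outcome` (canonical
#'   summary-statistics data.frames) and `truth` (list with `theta`,
#'   `gamma`, `alpha`, `invalid_indices`, `palindromic_indices`).
#' @export
simulate_summary_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    J <- config$n_snps
    B <- config$ld_block_size
    block <- ceiling(seq_len(J) / B)
    n_block <- max(block)
    chr <- as.character((block - 1) %% 22 + 1)
    # blocks 20 Mb apart on their chromosome so distinct blocks never share
    # a 10 Mb clumping window; the ordinal wraps to stay inside integer
    # range for very large J (wrapped blocks carry no LD entries anyway)
    block_ordinal <- (ceiling(block / 22) - 1) %% 100 + 1
    pos <- as.integer(block_ordinal * 2e7 +
                        ((seq_len(J) - 1) %% B) * 1000)

    eaf <- stats::runif(J, 0.05, 0.95)
    se_x <- config$se_x_scale /
      sqrt(2 * eaf * (1 - eaf) * config$n_exposure)
    n_eff <- 4 / (1 / config$n_cases + 1 / config$n_controls)
    se_y <- config$se_y_scale / sqrt(2 * eaf * (1 - eaf) * n_eff)

    gamma <- stats::rnorm(J, config$gamma_mean, config$gamma_sd)
    n_invalid <- round(config$prop_invalid * J)
    invalid <- if (n_invalid > 0) sort(sample.int(J, n_invalid)) else integer(0)
    alpha <- numeric(J)
    if (n_invalid > 0 && (config$alpha_sd > 0 || config$alpha_mean != 0)) {
      rho <- config$inside_correlation
      z_gamma <- (gamma[invalid] - config$gamma_mean) /
        max(config$gamma_sd, .Machine$double.eps)
      z <- rho * z_gamma + sqrt(1 - rho^2) * stats::rnorm(n_invalid)
      alpha[invalid] <- config$alpha_mean + config$alpha_sd * z
      # a pleiotropic variant with alpha drawn exactly 0 is still invalid by
      # construction; nudge to keep the truth bookkeeping consistent
      zero <- alpha[invalid] == 0
      alpha[invalid][zero] <- .Machine$double.eps
    }

    bx <- gamma + stats::rnorm(J, 0, se_x)
    by <- config$theta * gamma + alpha + stats::rnorm(J, 0, se_y)

    n_pal <- round(config$prop_palindromic * J)
    pal <- if (n_pal > 0) sort(sample.int(J, n_pal)) else integer(0)
    alleles <- NON_PALINDROMIC_PAIRS[
      sample.int(nrow(NON_PALINDROMIC_PAIRS), J, replace = TRUE), ,
      drop = FALSE]
    if (n_pal > 0) {
      alleles[pal, ] <- PALINDROMIC_PAIRS[
        sample.int(nrow(PALINDROMIC_PAIRS), n_pal, replace = TRUE), ,
        drop = FALSE]
    }

    make_df <- function(beta, se, n) {
      data.frame(SNP = paste0("rs", seq_len(J)), chr = chr, pos = pos,
                 effect_allele = alleles[, 1], other_allele = alleles[, 2],
                 eaf = eaf, beta = beta, se = se,
                 pval = pmax(2 * stats::pnorm(-abs(beta / se)),
                             .Machine$double.xmin),
                 n = as.integer(n), stringsAsFactors = FALSE)
    }
    list(exposure = make_df(bx, se_x, config$n_exposure),
         outcome = make_df(by, se_y,
                           config$n_cases + config$n_controls),
         truth = list(theta = config$theta, gamma = gamma, alpha = alpha,
                      invalid_indices = invalid,
                      palindromic_indices = pal))
  })
}

#' Simulate a block-structured LD table
#'
#' Consecutive blocks of `ld_block_size` variants (in the row order of
#' `exposure`) share pairwise r-squared `ld_within_r2`; pairs in different
#' blocks are absent from the table (r-squared 0 on lookup).
#'
#' @param exposure A summary-statistics data.frame (row order defines the
#'   blocks, matching [simulate_summary_pair()]).
#' @param config The [sim_config()] used to generate it.
#' @return An [ld_table()].
#' @export
simulate_ld_table <- function(exposure, config) {
  stopifnot(inherits(config, "sim_config"))
  J <- nrow(exposure)
  B <- config$ld_block_size
  if (B <= 1 || config$ld_within_r2 == 0 || J < 2) return(ld_table())
  block <- ceiling(seq_len(J) / B)
  rows <- do.call(rbind, lapply(unique(block), function(b) {
    idx <- which(block == b)
    if (length(idx) < 2) return(NULL)
    pairs <- utils::combn(idx, 2)
    data.frame(variant_id_1 = exposure$SNP[pairs[1, ]],
               variant_id_2 = exposure$SNP[pairs[2, ]],
               r_squared = config$ld_within_r2,
               stringsAsFactors = FALSE)
  }))
  ld_table(rows)
}

#' Simulate a taxonomy catalog of exposure traits
#'
#' Builds a catalog of `n_total` bacterial traits of which `n_unnamed`
#' carry labels denoting unknown/unclassified groups (so that
#' [filter_unnamed_taxa()] removes exactly those) and the remaining named
#' traits are distributed across taxonomic levels per `level_counts`.
#'
#' @param n_total Total number of traits (default 211).
#' @param n_unnamed Number of unnamed traits (default 15).
#' @param level_counts Named integer vector over phylum/class/order/
#'   family/genus summing to `n_total - n_unnamed` (defaults 9, 16, 20,
#'   32, 119).
#' @param seed RNG seed for label assignment.
#' @return A catalog data.frame with `trait_id`, `trait_name`, `level`,
#'   `is_named`.
#' @export
simulate_taxa_catalog <- function(n_total = 211, n_unnamed = 15,
                                  level_counts = c(phylum = 9, class = 16,
                                                   order = 20, family = 32,
                                                   genus = 119),
                                  seed = 1) {
  if (n_unnamed > n_total) stop("n_unnamed exceeds n_total")
  if (!setequal(names(level_counts), TAXONOMIC_LEVELS)) {
    stop("level_counts must name exactly the five taxonomic levels")
  }
  if (sum(level_counts) != n_total - n_unnamed) {
    stop("level_counts must sum to n_total - n_unnamed (",
         n_total - n_unnamed, "), got ", sum(level_counts))
  }
  with_seed(seed, {
    level <- c(rep(TAXONOMIC_LEVELS, level_counts[TAXONOMIC_LEVELS]),
               sample(TAXONOMIC_LEVELS, n_unnamed, replace = TRUE))
    name <- character(n_total)
    named_n <- n_total - n_unnamed
    name[seq_len(named_n)] <- paste0(level[seq_len(named_n)], " Taxon",
                                     seq_len(named_n))
    if (n_unnamed > 0) {
      stems <- sample(c("unknown", "unclassified", "Incertae Sedis"),
                      n_unnamed, replace = TRUE)
      name[named_n + seq_len(n_unnamed)] <-
        paste0(level[named_n + seq_len(n_unnamed)], " ", stems, ".id.",
               1000 + seq_len(n_unnamed))
    }
    ord <- sample.int(n_total)  # shuffle so unnamed traits are interleaved
    data.frame(trait_id = sprintf("trait%03d", seq_len(n_total)),
               trait_name = name[ord], level = level[ord],
               is_named = is_named_taxon(name[ord]),
               stringsAsFactors = FALSE)
  })
}

#' Write a taxonomy catalog in the TSV dialect read by [read_taxa_catalog()]
#'
#' @param catalog A catalog data.frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_taxa_catalog <- function(catalog, path) {
  utils::write.table(catalog[, c("trait_id", "trait_name", "level")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
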