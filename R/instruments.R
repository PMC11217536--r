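#' Select genome-wide suggestive instruments
#'
#' Keeps the records whose association p-value is strictly below
#' `threshold`. The default mirrors the locus-wide suggestive threshold
#' commonly used when genome-wide significant hits are too few, as with
#' microbiome-abundance exposures.
#'
#' @param dat Summary-statistics data.frame (canonical columns).
#' @param threshold Significance threshold in (0, 1]; comparison is strict
#'   (`pval < threshold`).
#' @return The filtered data.frame, input order preserved.
#' @export
filter_by_pvalue <- function(dat, threshold = 1e-5) {
  stopifnot(is.numeric(threshold), threshold > 0, threshold <= 1)
  dat[dat$pval < threshold, , drop = FALSE]
}

#' Greedy LD clumping
#'
#' Prunes correlated variants: records are visited in order of ascending
#' p-value (ties broken by chromosome, position, then variant id); each
#' retained record discards every not-yet-decided record on the same
#' chromosome within `window_kb` kilobases whose r-squared with it exceeds
#' `r2_max`. The retained set is returned in the input's row order, so no
#' two retained variants within a window are correlated above the threshold.
#'
#' @param dat Summary-statistics data.frame.
#' @param ld An [ld_table()]; pairs absent from it count as r-squared 0.
#' @param r2_max Maximum tolerated r-squared between retained variants
#'   within a window (default 0.001).
#' @param window_kb Window half-width in kilobases (default 10000, i.e.
#'   10 Mb); two variants are "within the window" when their positions
#'   differ by at most `window_kb * 1000` base pairs on the same chromosome.
#' @return The clumped data.frame.
#' @export
clump <- function(dat, ld, r2_max = 0.001, window_kb = 10000) {
  stopifnot(r2_max >= 0, r2_max <= 1, window_kb > 0)
  J <- nrow(dat)
  if (J <= 1) return(dat)
  ord <- order(dat$pval, dat$chr, dat$pos, dat$SNP)
  window_bp <- window_kb * 1000
  alive <- rep(TRUE, J)     # not yet discarded
  keep <- rep(FALSE, J)
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    near <- which(alive &
                    dat$chr == dat$chr[i] &
                    abs(dat$pos - dat$pos[i]) <= window_bp)
    if (length(near) > 0) {
      r2 <- ld_lookup(ld, dat$SNP[i], dat$SNP[near])
      alive[near[r2 > r2_max]] <- FALSE
    }
  }
  dat[keep, , drop = FALSE]
}

#' Instrument strength: variance explained and F-statistic
#'
#' For each variant, computes the minor-allele frequency
#' `maf = min(eaf, 1 - eaf)`, the fraction of exposure variance explained
#' `R2 = 2 * maf * (1 - maf) * beta^2`, and the F-statistic
#' `F = R2 * (n - k - 1) / (k * (1 - R2))`, where `n` is the exposure GWAS
#' sample size and `k` the number of instruments entering the model. With
#' the default `k = 1` each variant is assessed on its own, the usual
#' per-SNP weak-instrument screen; F > 10 is the conventional threshold
#' below which weak-instrument bias is a concern.
#'
#' @param dat Summary-statistics data.frame (uses `SNP`, `eaf`, `beta`, `n`).
#' @param k Number of instruments in the F formula (default 1).
#' @return A data.frame with columns `variant_id`, `maf`, `r_squared`,
#'   `f_statistic`, `n`, `k`.
#' @export
instrument_strength <- function(dat, k = 1) {
  stopifnot(k >= 1)
  if (any(is.na(dat$eaf) | dat$eaf <= 0 | dat$eaf >= 1)) {
    stop("degenerate allele frequency: eaf must lie strictly in (0, 1)")
  }
  if (any(dat$n <= k + 1)) {
    stop("sample size too small: need n > k + 1")
  }
  maf <- pmin(dat$eaf, 1 - dat$eaf)
  r2 <- 2 * maf * (1 - maf) * dat$beta^2
  f <- r2 * (dat$n - k - 1) / (k * (1 - r2))
  data.frame(variant_id = dat$SNP, maf = maf, r_squared = r2,
             f_statistic = f, n = dat$n, k = k,
             stringsAsFactors = FALSE)
}

#' Aggregate instrument strength for a set of instruments
#'
#' Evaluates the same F formula with `k` equal to the number of instruments
#' and `R2` the summed per-variant variance explained — the model-level
#' companion to the per-SNP screen of [instrument_strength()].
#'
#' @param dat Summary-statistics data.frame of the retained instruments.
#' @return A one-row data.frame with `r_squared_total`, `f_statistic`, `n`,
#'   `k`.
#' @export
instrument_strength_aggregate <- function(dat) {
  per_snp <- instrument_strength(dat, k = 1)
  k <- nrow(dat)
  n <- min(dat$n)
  r2 <- sum(per_snp$r_squared)
  if (n <= k + 1) stop("sample size too small: need n > k + 1")
  data.frame(r_squared_total = r2,
             f_statistic = r2 * (n - k - 1) / (k * (1 - r2)),
             n = n, k = k)
}

#' Screen out weak instruments
#'
#' @param strengths Output of [instrument_strength()].
#' @param f_min Minimum F; records with `f_statistic > f_min` are kept
#'   (default 10).
#' @return The filtered strength table.
#' @export
weak_instrument_filter <- function(strengths, f_min = 10) {
  stopifnot(f_min >= 0)
  strengths[strengths$f_statistic > f_min, , drop = FALSE]
}

#' Drop catalog entries without a specific taxon name
#'
#' Keeps only traits whose label names a specific group (see
#' [is_named_taxon()]); unknown/unclassified taxa cannot be interpreted
#' biologically and are excluded before screening.
#'
#' @param catalog A catalog data.frame (see [read_taxa_catalog()]).
#' @return The catalog restricted to named traits.
#' @export
filter_unnamed_taxa <- function(catalog) {
  if (!"is_named" %in% names(catalog)) {
    catalog$is_named <- is_named_taxon(catalog$trait_name)
  }
  catalog[catalog$is_named, , drop = FALSE]
}
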