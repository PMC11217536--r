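# Canonical summary-statistics schema. Every reader maps its dialect onto
# these names; everything downstream assumes them.
SUMSTATS_COLUMNS <- c("SNP", "chr", "pos", "effect_allele", "other_allele",
                      "eaf", "beta", "se", "pval", "n")

TAXONOMIC_LEVELS <- c("phylum", "class", "order", "family", "genus")

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-separated table of per-variant association statistics into the
#' canonical schema used throughout the package: `SNP`, `chr`, `pos`,
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' Files written by other tools (different column names) are adapted through
#' `column_map`.
#'
#' Validation is strict: a missing required column is a schema error; a
#' non-numeric value, a non-positive standard error, an allele frequency
#' outside \[0,1\], a position below 1, or identical effect/other alleles is a
#' validation error that names the offending row. Two repairs are applied
#' with a warning rather than an error: alleles are upper-cased and rows
#' whose alleles are not single A/C/G/T bases (indels, multi-allelic codes)
#' are dropped with a count, and p-values of exactly zero are floored to the
#' smallest positive double so that downstream log transforms are defined.
#'
#' @param path Path to a tab-separated file with a header row. Missing values
#'   may be encoded as `"."` or the empty string.
#' @param column_map Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(SNP = "rsid", beta = "b", pval = "p")`. Canonical names absent from
#'   the map are looked up under their own name.
#' @return A `data.frame` with the canonical columns, one row per retained
#'   variant, in file order.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' df <- data.frame(SNP = c("rs1", "rs2"), chr = "1", pos = c(100L, 200L),
#'                  effect_allele = "A", other_allele = "G", eaf = 0.3,
#'                  beta = c(0.1, -0.2), se = 0.05, pval = c(1e-6, 1e-4),
#'                  n = 18340L)
#' write_summary_stats(df, f)
#' stats <- read_summary_stats(f)
#' @export
read_summary_stats <- function(path, column_map = NULL) {
  if (!file.exists(path)) {
    stop("summary-statistics file not found: ", path)
  }
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           na.strings = c(".", "", "NA"),
                           check.names = FALSE, strip.white = TRUE)
  name_in_file <- stats::setNames(SUMSTATS_COLUMNS, SUMSTATS_COLUMNS)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), SUMSTATS_COLUMNS)
    if (length(bad) > 0) {
      stop("column_map refers to unknown canonical column(s): ",
           paste(bad, collapse = ", "))
    }
    name_in_file[names(column_map)] <- unname(column_map)
  }
  missing <- name_in_file[!name_in_file %in% names(raw)]
  if (length(missing) > 0) {
    stop("missing required column(s): ",
         paste(sprintf("%s (expected as '%s')", names(missing), missing),
               collapse = ", "))
  }
  dat <- data.frame(
    SNP           = raw[[name_in_file["SNP"]]],
    chr           = raw[[name_in_file["chr"]]],
    pos           = raw[[name_in_file["pos"]]],
    effect_allele = toupper(raw[[name_in_file["effect_allele"]]]),
    other_allele  = toupper(raw[[name_in_file["other_allele"]]]),
    eaf           = raw[[name_in_file["eaf"]]],
    beta          = raw[[name_in_file["beta"]]],
    se            = raw[[name_in_file["se"]]],
    pval          = raw[[name_in_file["pval"]]],
    n             = raw[[name_in_file["n"]]],
    stringsAsFactors = FALSE
  )
  validate_sumstats(dat)
}

# Coerce character columns to their types and enforce the per-row invariants.
# `dat` must already use canonical names; row numbers in messages refer to
# data rows (header excluded).
validate_sumstats <- function(dat) {
  numeric_cols <- c("pos", "eaf", "beta", "se", "pval", "n")
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(dat[[col]]))
    bad <- which(!is.na(dat[[col]]) & is.na(v))
    if (length(bad) > 0) {
      stop(sprintf("unparsable numeric in column '%s' at row(s) %s",
                   col, paste(utils::head(bad, 5), collapse = ", ")))
    }
    dat[[col]] <- v
  }
  dat$pos <- as.integer(round(dat$pos))
  dat$n <- as.integer(round(dat$n))

  # Non-SNV alleles (indels etc.) are outside the harmonization rules:
  # drop with a warning count rather than fail the whole file.
  snv <- dat$effect_allele %in% c("A", "C", "G", "T") &
    dat$other_allele %in% c("A", "C", "G", "T")
  if (any(!snv)) {
    warning(sprintf("dropped %d row(s) with non-ACGT alleles", sum(!snv)))
    dat <- dat[snv, , drop = FALSE]
  }

  fail <- function(cond, what) {
    bad <- which(cond)
    if (length(bad) > 0) {
      stop(sprintf("%s at row(s) %s", what,
                   paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  fail(is.na(dat$beta) | is.na(dat$se) | is.na(dat$pval),
       "missing beta/se/pval")
  fail(dat$se <= 0, "se must be > 0")
  fail(!is.na(dat$eaf) & (dat$eaf < 0 | dat$eaf > 1),
       "eaf outside [0, 1]")
  fail(!is.na(dat$pos) & dat$pos < 1, "position must be >= 1")
  fail(dat$effect_allele == dat$other_allele,
       "effect and other allele identical")
  fail(dat$pval < 0 | dat$pval > 1, "p-value outside [0, 1]")
  if (any(dat$pval == 0)) {
    warning(sprintf("floored %d zero p-value(s) to smallest positive double",
                    sum(dat$pval == 0)))
    dat$pval[dat$pval == 0] <- .Machine$double.xmin
  }
  rownames(dat) <- NULL
  dat
}

#' Write a GWAS summary-statistics table
#'
#' Writes the canonical tab-separated dialect read by
#' [read_summary_stats()]. Numeric values keep enough digits for a
#' write/read round trip to be exact to well beyond 6 significant digits.
#'
#' @param dat A data.frame with the canonical columns.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_summary_stats <- function(dat, path) {
  out <- dat[, SUMSTATS_COLUMNS, drop = FALSE]
  for (col in c("eaf", "beta", "se", "pval")) {
    out[[col]] <- formatC(out[[col]], digits = 15, format = "g")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Linkage-disequilibrium table
#'
#' Builds a symmetric lookup of pairwise r-squared values from a long-format
#' table. Absent pairs have r-squared 0; a variant with itself always has
#' r-squared 1 (self-pair rows in the input are ignored). Duplicate pairs
#' collapse to the last value seen.
#'
#' @param pairs A data.frame with columns `variant_id_1`, `variant_id_2`,
#'   `r_squared` (values in \[0,1\]).
#' @return An object of class `ld_table`.
#' @seealso [read_ld_table()], [ld_lookup()]
#' @export
ld_table <- function(pairs = NULL) {
  env <- new.env(parent = emptyenv())
  obj <- structure(list(map = env), class = "ld_table")
  if (!is.null(pairs) && nrow(pairs) > 0) {
    r2 <- as.numeric(pairs$r_squared)
    if (any(is.na(r2) | r2 < 0 | r2 > 1)) {
      stop("r_squared outside [0, 1] at row(s) ",
           paste(utils::head(which(is.na(r2) | r2 < 0 | r2 > 1), 5),
                 collapse = ", "))
    }
    a <- as.character(pairs$variant_id_1)
    b <- as.character(pairs$variant_id_2)
    keep <- a != b  # self pairs are 1 by construction
    a <- a[keep]; b <- b[keep]; r2 <- r2[keep]
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    keys <- paste(lo, hi, sep = "\r")
    for (i in seq_along(keys)) assign(keys[i], r2[i], envir = env)
  }
  obj
}

#' Read a long-format LD table
#'
#' Three-column tab-separated file: `variant_id_1`, `variant_id_2`,
#' `r_squared`.
#'
#' @param path Path to the file.
#' @return An [ld_table()] object.
#' @export
read_ld_table <- function(path) {
  if (!file.exists(path)) stop("LD table not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "character", "numeric"),
                           check.names = FALSE)
  names(raw) <- c("variant_id_1", "variant_id_2", "r_squared")
  ld_table(raw)
}

#' Look up pairwise r-squared
#'
#' Symmetric lookup: `ld_lookup(ld, a, b)` equals `ld_lookup(ld, b, a)`.
#' A variant with itself returns 1; pairs absent from the table return 0.
#' Vectorized over `a` and `b`.
#'
#' @param ld An [ld_table()] object.
#' @param a,b Variant identifiers (character vectors, recycled).
#' @return Numeric vector of r-squared values.
#' @export
ld_lookup <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_table"))
  a <- as.character(a); b <- as.character(b)
  nn <- max(length(a), length(b))
  a <- rep_len(a, nn); b <- rep_len(b, nn)
  out <- numeric(nn)
  self <- a == b
  out[self] <- 1
  if (any(!self)) {
    keys <- paste(pmin(a[!self], b[!self]), pmax(a[!self], b[!self]),
                  sep = "\r")
    out[!self] <- vapply(keys, function(k) {
      if (exists(k, envir = ld$map, inherits = FALSE)) {
        get(k, envir = ld$map, inherits = FALSE)
      } else 0
    }, numeric(1), USE.NAMES = FALSE)
  }
  out
}

#' @export
print.ld_table <- function(x, ...) {
  cat("<ld_table> with", length(ls(x$map)), "stored pair(s)\n")
  invisible(x)
}

#' Read a trait catalog
#'
#' Reads a tab-separated catalog of exposure traits with columns `trait_id`,
#' `trait_name`, `level` (one of phylum, class, order, family, genus) and
#' annotates each record with `is_named`: `FALSE` when the label denotes an
#' unknown or unclassified group (the label contains "unknown",
#' "unclassified" or "incertae", case-insensitively), `TRUE` otherwise.
#'
#' @param path Path to the catalog file.
#' @return A data.frame with columns `trait_id`, `trait_name`, `level`,
#'   `is_named`.
#' @export
read_taxa_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  need <- c("trait_id", "trait_name", "level")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("catalog missing column(s): ", paste(missing, collapse = ", "))
  }
  bad <- which(!raw$level %in% TAXONOMIC_LEVELS)
  if (length(bad) > 0) {
    stop("unknown taxonomic level at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  data.frame(trait_id = raw$trait_id, trait_name = raw$trait_name,
             level = raw$level, is_named = is_named_taxon(raw$trait_name),
             stringsAsFactors = FALSE)
}

#' Does a taxon label name a specific group?
#'
#' Labels containing "unknown", "unclassified" or "incertae"
#' (case-insensitive) are treated as unnamed groups, mirroring the labels
#' used for unspecified taxa in microbiome GWAS catalogs.
#'
#' @param trait_name Character vector of taxon labels.
#' @return Logical vector.
#' @export
is_named_taxon <- function(trait_name) {
  !grepl("unknown|unclassified|incertae", trait_name, ignore.case = TRUE)
}

#' Write an MR results table
#'
#' Serializes causal-effect estimates to a tab-separated table with columns
#' `exposure`, `method`, `n_snp`, `beta`, `se`, `or`, `ci_low`, `ci_high`,
#' `pvalue`. Numbers are written with enough digits that reading the file
#' back reproduces them to at least 6 significant digits; odds ratios always
#' carry at least two decimals.
#'
#' @param estimates A data.frame of estimate rows (see
#'   [as.data.frame.mr_estimate()]), or a list of `mr_estimate` objects.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_results_table <- function(estimates, path) {
  cols <- c("exposure", "method", "n_snp", "beta", "se", "or",
            "ci_low", "ci_high", "pvalue")
  if (is.list(estimates) && !is.data.frame(estimates)) {
    estimates <- do.call(rbind, lapply(estimates, as.data.frame))
  }
  if (is.null(estimates) || nrow(estimates) == 0) {
    estimates <- data.frame(exposure = character(), method = character(),
                            n_snp = integer(), beta = numeric(),
                            se = numeric(), or = numeric(),
                            ci_low = numeric(), ci_high = numeric(),
                            pvalue = numeric())
  }
  if (!"exposure" %in% names(estimates)) estimates$exposure <- ""
  out <- estimates[, cols, drop = FALSE]
  for (col in c("beta", "se", "or", "ci_low", "ci_high", "pvalue")) {
    out[[col]] <- vapply(out[[col]], function(v) {
      if (is.na(v)) return(NA_character_)
      # >= 2 decimals and >= 9 significant digits, whichever is longer
      s <- formatC(v, digits = 10, format = "g")
      if (!grepl("[.eE]", s)) s <- sprintf("%.2f", v)
      s
    }, character(1))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Read back an MR results table
#'
#' @param path Path to a file written by [write_results_table()].
#' @return A data.frame with the table's columns, numerics parsed.
#' @export
read_results_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, na.strings = ".",
                    stringsAsFactors = FALSE)
}
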