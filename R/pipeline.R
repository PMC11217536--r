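#' Pipeline configuration
#'
#' Analysis settings for [run_single()] and [run_screen()]. Defaults follow
#' the screening design the package implements: suggestive instrument
#' threshold `p < 1e-5`, clumping at r-squared 0.001 within 10,000 kb,
#' unconditional palindrome removal, IVW as the primary method with the
#' heterogeneity-driven fixed/random switch, per-trait significance at
#' nominal `p < 0.05`, and no multiple-testing correction (Bonferroni and
#' Benjamini-Hochberg are opt-in).
#'
#' @param pvalue_threshold Instrument selection threshold (default 1e-5).
#' @param clump_r2 Clumping r-squared ceiling (default 0.001).
#' @param clump_kb Clumping window in kb (default 10000).
#' @param palindrome_policy Only `"drop"` is implemented: palindromic
#'   variants are removed during harmonization.
#' @param methods Estimators to run per exposure; any of `"ivw"`,
#'   `"egger"`, `"weighted_median"`, `"max_likelihood"`.
#' @param ivw_model `"auto"`, `"fixed"`, or `"random"` (default `"auto"`).
#' @param presso_n_simulations,presso_significance MR-PRESSO settings
#'   (defaults 1000 and 0.05).
#' @param n_boot Weighted-median bootstrap replicates (default 1000).
#' @param significance Per-trait significance threshold on the IVW p-value
#'   (default 0.05).
#' @param multiple_testing `"none"` (default), `"bonferroni"`, or `"bh"`;
#'   applied to the IVW p-values across the screened exposures.
#' @param f_min Weak-instrument F threshold, reported per variant
#'   (default 10).
#' @param apply_f_filter Apply `f_min` as a hard exclusion rather than a
#'   report-only flag (default FALSE).
#' @param seed Seed for all stochastic components (default 42).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(pvalue_threshold = 1e-5, clump_r2 = 0.001,
                            clump_kb = 10000, palindrome_policy = "drop",
                            methods = c("ivw", "egger", "weighted_median",
                                        "max_likelihood"),
                            ivw_model = "auto",
                            presso_n_simulations = 1000,
                            presso_significance = 0.05,
                            n_boot = 1000, significance = 0.05,
                            multiple_testing = c("none", "bonferroni", "bh"),
                            f_min = 10, apply_f_filter = FALSE, seed = 42) {
  multiple_testing <- match.arg(multiple_testing)
  stopifnot(pvalue_threshold > 0, pvalue_threshold <= 1,
            clump_r2 >= 0, clump_r2 <= 1, clump_kb > 0,
            identical(palindrome_policy, "drop"),
            significance > 0, significance < 1)
  structure(as.list(environment()), class = "pipeline_config")
}

# Columns shared by every result row.
empty_screen_row <- function(exposure_name) {
  data.frame(exposure = exposure_name, method = NA_character_,
             n_snp = NA_integer_, beta = NA_real_, se = NA_real_,
             or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
             pvalue = NA_real_, n_snp_initial = NA_integer_,
             n_snp_after_clump = NA_integer_,
             n_snp_after_harmonize = NA_integer_,
             q_statistic = NA_real_, q_pvalue = NA_real_,
             ivw_model_selected = NA_character_,
             egger_intercept = NA_real_,
             egger_intercept_pvalue = NA_real_,
             presso_global_pvalue = NA_real_,
             presso_n_outliers = NA_integer_,
             presso_distortion_pvalue = NA_real_,
             min_f_statistic = NA_real_, significant = NA,
             skip_reason = NA_character_, error = NA_character_,
             stringsAsFactors = FALSE)
}

estimate_to_row <- function(est, exposure_name) {
  row <- empty_screen_row(exposure_name)
  row$method <- est$method
  row$n_snp <- est$n_snp
  row$beta <- est$beta
  row$se <- est$se
  row$or <- est$or
  row$ci_low <- est$ci_low
  row$ci_high <- est$ci_high
  row$pvalue <- est$pvalue
  row
}

#' Run the full analysis for one exposure
#'
#' Executes, in order: p-value instrument selection, greedy LD clumping,
#' instrument-strength assessment, exposure/outcome harmonization (with
#' palindrome removal), the configured estimators, Cochran's Q, the
#' MR-Egger intercept pleiotropy test, and MR-PRESSO. Per-method failures
#' (e.g. too few instruments for MR-Egger) are recorded in the `error`
#' column of that method's row and do not abort the run; an exposure with
#' no surviving instruments yields a single skip row with a reason.
#'
#' @param exposure Summary-statistics data.frame or path to one.
#' @param outcome Summary-statistics data.frame or path to one.
#' @param ld An [ld_table()] or path to a long-format LD file.
#' @param config A [pipeline_config()].
#' @param exposure_name Label carried into the result rows.
#' @return An object of class `mr_single`: list with `rows` (one
#'   data.frame row per method), and — when the analysis ran — `harmonized`
#'   (the `harmonized_set`), `estimates`, `heterogeneity`, `egger`,
#'   `presso`, `plot` (an `mr_plot_data`).
#' @export
run_single <- function(exposure, outcome, ld, config = pipeline_config(),
                       exposure_name = "exposure") {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(exposure)) exposure <- read_summary_stats(exposure)
  if (is.character(outcome)) outcome <- read_summary_stats(outcome)
  if (is.character(ld)) ld <- read_ld_table(ld)

  skip <- function(reason) {
    row <- empty_screen_row(exposure_name)
    row$skip_reason <- reason
    structure(list(rows = row), class = "mr_single")
  }

  sel <- filter_by_pvalue(exposure, config$pvalue_threshold)
  if (nrow(sel) == 0) return(skip("no instruments"))
  n_initial <- nrow(sel)

  clumped <- clump(sel, ld, config$clump_r2, config$clump_kb)
  n_clump <- nrow(clumped)

  strength <- tryCatch(instrument_strength(clumped, k = 1),
                       error = function(e) NULL)
  if (config$apply_f_filter && !is.null(strength)) {
    keep <- strength$f_statistic > config$f_min
    clumped <- clumped[keep, , drop = FALSE]
    strength <- strength[keep, , drop = FALSE]
    if (nrow(clumped) == 0) return(skip("no instruments above F threshold"))
  }

  hs <- harmonize_pair(clumped, outcome, exposure_name = exposure_name)
  J <- n_snps(hs)
  if (J == 0) return(skip("no instruments after harmonization"))

  het <- if (J >= 2) cochran_q(hs) else NULL
  egger_fit <- NULL
  presso_fit <- NULL
  estimates <- list()
  rows <- list()

  add_row <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      row <- empty_screen_row(exposure_name)
      row$method <- name
      row$error <- conditionMessage(res)
      rows[[length(rows) + 1]] <<- row
      NULL
    } else {
      res
    }
  }

  for (m in config$methods) {
    if (m == "ivw") {
      est <- add_row("ivw", function() {
        suppressWarnings(mr_ivw(hs, model = config$ivw_model))
      })
      if (!is.null(est)) {
        row <- estimate_to_row(est, exposure_name)
        row$ivw_model_selected <- attr(est, "model_selected")
        row$significant <- est$pvalue < config$significance
        rows[[length(rows) + 1]] <- row
        estimates <- c(estimates, list(est))
      }
    } else if (m == "egger") {
      egger_fit <- add_row("egger_slope", function() mr_egger(hs))
      if (!is.null(egger_fit)) {
        rows[[length(rows) + 1]] <- estimate_to_row(egger_fit$slope,
                                                    exposure_name)
        estimates <- c(estimates, list(egger_fit))
      }
    } else if (m == "weighted_median") {
      est <- add_row("weighted_median", function() {
        mr_weighted_median(hs, n_boot = config$n_boot, seed = config$seed)
      })
      if (!is.null(est)) {
        rows[[length(rows) + 1]] <- estimate_to_row(est, exposure_name)
        estimates <- c(estimates, list(est))
      }
    } else if (m == "max_likelihood") {
      est <- add_row("max_likelihood", function() mr_max_likelihood(hs))
      if (!is.null(est)) {
        rows[[length(rows) + 1]] <- estimate_to_row(est, exposure_name)
        estimates <- c(estimates, list(est))
      }
    } else {
      stop("unknown method in config: ", m)
    }
  }

  if (J >= 4) {
    presso_fit <- tryCatch(
      mr_presso(hs, n_simulations = config$presso_n_simulations,
                significance = config$presso_significance,
                seed = config$seed, model = config$ivw_model),
      error = function(e) NULL)
  }

  rows <- do.call(rbind, rows)
  rows$n_snp_initial <- n_initial
  rows$n_snp_after_clump <- n_clump
  rows$n_snp_after_harmonize <- J
  if (!is.null(het)) {
    rows$q_statistic <- het$q_statistic
    rows$q_pvalue <- het$pvalue
  }
  if (!is.null(egger_fit)) {
    rows$egger_intercept <- egger_fit$intercept$beta
    rows$egger_intercept_pvalue <- egger_fit$intercept$pvalue
  }
  if (!is.null(presso_fit)) {
    rows$presso_global_pvalue <- presso_fit$global_pvalue
    rows$presso_n_outliers <- length(presso_fit$outlier_indices)
    rows$presso_distortion_pvalue <- presso_fit$distortion_pvalue
  }
  if (!is.null(strength) && nrow(strength) > 0) {
    rows$min_f_statistic <- min(strength$f_statistic)
  }
  structure(list(rows = rows, harmonized = hs, estimates = estimates,
                 heterogeneity = het, egger = egger_fit,
                 presso = presso_fit, strength = strength,
                 plot = plot_data(hs, estimates)),
            class = "mr_single")
}

#' Screen many exposures against one outcome
#'
#' Applies [filter_unnamed_taxa()] to the catalog, then [run_single()] per
#' named trait. Traits whose exposure file is missing are recorded as skip
#' rows; the screen never aborts on a per-trait failure. The `significant`
#' subtable restricts the full table to exposures whose IVW p-value falls
#' below the configured threshold (after the configured multiple-testing
#' adjustment, if any) — exactly a post-hoc filter of the full table, with
#' no hidden criteria.
#'
#' @param catalog Catalog data.frame or path (see [read_taxa_catalog()]).
#' @param exposures Either a directory containing `<trait_id>.tsv` files,
#'   or a named list of summary-statistics data.frames keyed by trait id.
#' @param outcome Summary-statistics data.frame or path.
#' @param ld An [ld_table()] or path.
#' @param config A [pipeline_config()].
#' @return An object of class `screen_result`: list with `rows` (all
#'   result rows), `significant` (the subtable), `singles` (named list of
#'   `mr_single` objects), `config`.
#' @export
run_screen <- function(catalog, exposures, outcome, ld,
                       config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(catalog)) catalog <- read_taxa_catalog(catalog)
  if (is.character(outcome)) outcome <- read_summary_stats(outcome)
  if (is.character(ld)) ld <- read_ld_table(ld)
  named <- filter_unnamed_taxa(catalog)
  if (nrow(named) == 0) {
    warning("catalog is empty after removing unnamed taxa")
  }
  singles <- list()
  rows <- list()
  for (i in seq_len(nrow(named))) {
    id <- named$trait_id[i]
    label <- named$trait_name[i]
    exp_dat <- if (is.list(exposures) && !is.data.frame(exposures)) {
      exposures[[id]]
    } else {
      path <- file.path(exposures, paste0(id, ".tsv"))
      if (file.exists(path)) read_summary_stats(path) else NULL
    }
    if (is.null(exp_dat)) {
      row <- empty_screen_row(label)
      row$skip_reason <- "missing exposure file"
      rows[[length(rows) + 1]] <- row
      next
    }
    res <- run_single(exp_dat, outcome, ld, config, exposure_name = label)
    singles[[label]] <- res
    rows[[length(rows) + 1]] <- res$rows
  }
  rows <- if (length(rows) > 0) do.call(rbind, rows) else
    empty_screen_row("none")[0, , drop = FALSE]
  rownames(rows) <- NULL

  ivw <- rows$method %in% c("ivw_fixed", "ivw_random")
  if (config$multiple_testing != "none" && any(ivw)) {
    adj_method <- switch(config$multiple_testing,
                         bonferroni = "bonferroni", bh = "BH")
    rows$pvalue_adj <- NA_real_
    rows$pvalue_adj[ivw] <- stats::p.adjust(rows$pvalue[ivw], adj_method)
    rows$significant[ivw] <- rows$pvalue_adj[ivw] < config$significance
  }
  sig_exposures <- unique(rows$exposure[ivw & !is.na(rows$significant) &
                                          rows$significant])
  significant <- rows[rows$exposure %in% sig_exposures, , drop = FALSE]
  structure(list(rows = rows, significant = significant, singles = singles,
                 config = config), class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  n_exp <- length(unique(x$rows$exposure))
  cat(sprintf("<screen_result> %d exposure(s), %d significant at IVW p < %g\n",
              n_exp, length(unique(x$significant$exposure)),
              x$config$significance))
  invisible(x)
}

format_or_ci <- function(or, lo, hi) {
  ifelse(is.na(or), NA_character_,
         sprintf("%.2f (%.2f-%.2f)", or, lo, hi))
}

#' Write the report files for a screen
#'
#' Writes, under `out_dir`: `results.tsv` (every result row with estimate,
#' heterogeneity, pleiotropy, and MR-PRESSO columns), `forest.tsv` (one
#' row per exposure and method with the odds ratio formatted as
#' `OR (low-high)` at two decimals, the layout of a forest-plot table),
#' `scatter.tsv` and `funnel.tsv` (per-variant plot data across exposures),
#' and `run_log.txt` (configuration, seed, package version).
#'
#' @param result A `screen_result`.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the named vector of written paths.
#' @export
mr_report <- function(result, out_dir) {
  stopifnot(inherits(result, "screen_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(results = file.path(out_dir, "results.tsv"),
             forest = file.path(out_dir, "forest.tsv"),
             scatter = file.path(out_dir, "scatter.tsv"),
             funnel = file.path(out_dir, "funnel.tsv"),
             log = file.path(out_dir, "run_log.txt"))
  utils::write.table(result$rows, paths["results"], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = ".")
  forest_rows <- result$rows[!is.na(result$rows$method), , drop = FALSE]
  forest <- data.frame(
    exposure = forest_rows$exposure, method = forest_rows$method,
    n_snp = forest_rows$n_snp,
    or_ci = format_or_ci(forest_rows$or, forest_rows$ci_low,
                         forest_rows$ci_high),
    pvalue = signif(forest_rows$pvalue, 3), stringsAsFactors = FALSE)
  utils::write.table(forest, paths["forest"], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  scatter <- do.call(rbind, lapply(names(result$singles), function(nm) {
    pd <- result$singles[[nm]]$plot
    if (is.null(pd) || nrow(pd$scatter) == 0) return(NULL)
    cbind(exposure = nm, pd$scatter)
  }))
  funnel <- do.call(rbind, lapply(names(result$singles), function(nm) {
    pd <- result$singles[[nm]]$plot
    if (is.null(pd) || nrow(pd$funnel) == 0) return(NULL)
    cbind(exposure = nm, pd$funnel)
  }))
  if (is.null(scatter)) {
    scatter <- data.frame(exposure = character(), SNP = character(),
                          beta_exposure = numeric(), beta_outcome = numeric(),
                          se_exposure = numeric(), se_outcome = numeric())
  }
  if (is.null(funnel)) {
    funnel <- data.frame(exposure = character(), SNP = character(),
                         ratio = numeric(), precision = numeric(),
                         reference = numeric())
  }
  utils::write.table(scatter, paths["scatter"], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  utils::write.table(funnel, paths["funnel"], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  cfg <- result$config
  writeLines(c(
    paste0("mrscreen version: ",
           as.character(utils::packageVersion("mrscreen"))),
    paste0("R version: ", R.version.string),
    "configuration:",
    paste0("  ", names(cfg), " = ",
           vapply(cfg, function(v) paste(format(v), collapse = ","),
                  character(1)))
  ), paths["log"])
  invisible(paths)
}
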