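#' Cochran's Q heterogeneity test
#'
#' Measures excess dispersion of the per-variant Wald ratios around the
#' pooled IVW estimate: `Q = sum_j w_j (ratio_j - beta_IVW)^2` with IVW
#' weights `w_j = bx_j^2 / sy_j^2`. Under homogeneity Q follows a
#' chi-square distribution with `J - 1` degrees of freedom; a p-value below
#' `het_alpha` indicates heterogeneity and selects the random-effects IVW
#' model.
#'
#' @param set A `harmonized_set` with at least 2 variants.
#' @param het_alpha Significance level for the fixed/random switch
#'   (default 0.05).
#' @return An object of class `heterogeneity_result`: list with
#'   `q_statistic`, `df`, `pvalue`, `model_selected` (`"fixed"` or
#'   `"random"`).
#' @export
cochran_q <- function(set, het_alpha = 0.05) {
  p <- ivw_parts(set)
  J <- length(p$ratio)
  if (J < 2) stop("insufficient instruments: Cochran's Q needs at least 2")
  beta <- sum(p$w * p$ratio) / sum(p$w)
  q <- sum(p$w * (p$ratio - beta)^2)
  pv <- stats::pchisq(q, df = J - 1, lower.tail = FALSE)
  structure(list(q_statistic = q, df = J - 1L, pvalue = pv,
                 model_selected = if (pv < het_alpha) "random" else "fixed"),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f (df = %d), p = %.3g -> %s-effects model\n",
              x$q_statistic, x$df, x$pvalue, x$model_selected))
  invisible(x)
}

# Restrict a harmonized set to the given variant indices.
subset_harmonized <- function(set, idx) {
  out <- set
  out$data <- set$data[idx, , drop = FALSE]
  rownames(out$data) <- NULL
  out$log <- set$log[set$log$SNP %in% out$data$SNP, , drop = FALSE]
  out
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Detects and removes horizontally pleiotropic outlier variants.
#' \enumerate{
#'   \item \emph{Global test.} The observed residual sum of squares is
#'     `RSS = sum_j w_j (by_j - theta_(-j) * bx_j)^2`, where `theta_(-j)`
#'     is the leave-one-out IVW estimate and `w_j` the IVW weights. Its
#'     null distribution is simulated by redrawing each variant's effects
#'     (`bx* ~ N(bx_j, sx_j)`, `by* ~ N(theta_(-j) * bx_j, sy_j)`) and
#'     recomputing RSS; the global p-value is the Monte-Carlo tail
#'     probability with the add-one correction `(b + 1) / (m + 1)`.
#'   \item \emph{Outlier test.} Each variant's observed residual term is
#'     compared with its own simulated residuals; the per-variant tail
#'     probability is Bonferroni-multiplied by J and variants below
#'     `significance` are flagged.
#'   \item \emph{Distortion test.} The shift between the IVW estimate on
#'     all variants and on the non-flagged variants is compared with shifts
#'     from removing random subsets of the same size.
#' }
#'
#' @param set A `harmonized_set` with at least 4 variants.
#' @param n_simulations Monte-Carlo replicates for the global/outlier tests
#'   (default 1000; at least 100).
#' @param significance Outlier flagging threshold on the Bonferroni-adjusted
#'   p-value (default 0.05).
#' @param seed RNG seed (default 42); the caller's RNG state is preserved.
#' @param n_distortion_draws Random subsets for the distortion test
#'   (default 1000).
#' @param model IVW model for the raw and corrected estimates
#'   (default `"auto"`).
#' @return An object of class `presso_result`: list with
#'   `global_rss_observed`, `global_pvalue`, `outlier_indices`,
#'   `outlier_pvalues`, `distortion_pvalue` (`NA` when no outliers),
#'   `estimate_raw`, `estimate_corrected` (equal to the raw estimate when
#'   nothing is flagged), `n_simulations`, `seed`.
#' @export
mr_presso <- function(set, n_simulations = 1000, significance = 0.05,
                      seed = 42, n_distortion_draws = 1000,
                      model = "auto") {
  d <- set$data
  J <- nrow(d)
  if (J < 4) stop("insufficient instruments: MR-PRESSO needs at least 4")
  if (n_simulations < 100) stop("n_simulations must be at least 100")
  bx <- d$beta_exposure; sx <- d$se_exposure
  by <- d$beta_outcome; sy <- d$se_outcome
  w <- bx^2 / sy^2
  ratio <- by / bx
  sw <- sum(w); swr <- sum(w * ratio)
  theta_loo <- (swr - w * ratio) / (sw - w)
  expected <- theta_loo * bx
  res_obs <- w * (by - expected)^2
  rss_obs <- sum(res_obs)

  sim <- with_seed(seed, {
    m <- n_simulations
    BX <- matrix(stats::rnorm(J * m, mean = bx, sd = sx), nrow = J)
    BY <- matrix(stats::rnorm(J * m, mean = expected, sd = sy), nrow = J)
    W <- BX^2 / sy^2
    R <- BY / BX
    col_sw <- colSums(W)
    col_swr <- colSums(W * R)
    TL <- (rep(col_swr, each = J) - W * R) / (rep(col_sw, each = J) - W)
    RES <- W * (BY - TL * BX)^2
    list(rss = colSums(RES), res = RES)
  })
  global_p <- (sum(sim$rss >= rss_obs) + 1) / (n_simulations + 1)
  p_single <- (rowSums(sim$res >= res_obs) + 1) / (n_simulations + 1)
  p_adj <- pmin(1, p_single * J)
  outliers <- which(p_adj < significance)

  raw <- suppressWarnings(mr_ivw(set, model = model))
  if (length(outliers) == J) {
    stop("degenerate correction: every instrument flagged as an outlier")
  }
  corrected <- raw
  distortion_p <- NA_real_
  if (length(outliers) > 0) {
    corrected <- suppressWarnings(
      mr_ivw(subset_harmonized(set, setdiff(seq_len(J), outliers)),
             model = model))
    obs_shift <- corrected$beta - raw$beta
    shifts <- with_seed(seed + 1L, {
      vapply(seq_len(n_distortion_draws), function(i) {
        drop_idx <- sample.int(J, length(outliers))
        keep <- setdiff(seq_len(J), drop_idx)
        sum(w[keep] * ratio[keep]) / sum(w[keep]) - raw$beta
      }, numeric(1))
    })
    distortion_p <- (sum(abs(shifts) >= abs(obs_shift)) + 1) /
      (n_distortion_draws + 1)
  }
  structure(list(global_rss_observed = rss_obs, global_pvalue = global_p,
                 outlier_indices = outliers, outlier_pvalues = p_adj,
                 distortion_pvalue = distortion_p, estimate_raw = raw,
                 estimate_corrected = corrected,
                 n_simulations = n_simulations, seed = seed),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS = %.4f, global p = %.4g, %d outlier(s)\n",
              x$global_rss_observed, x$global_pvalue,
              length(x$outlier_indices)))
  if (length(x$outlier_indices) > 0) {
    cat("  outlier indices:", paste(x$outlier_indices, collapse = ", "),
        sprintf("; distortion p = %.4g\n", x$distortion_pvalue))
  }
  invisible(x)
}

#' Scatter- and funnel-plot data
#'
#' Tabulates per-variant effects for a scatter plot (exposure effect vs
#' outcome effect with per-method fitted lines) and a funnel plot (Wald
#' ratio vs its precision, with the pooled estimate as vertical
#' reference). Fitted lines pass through the origin for every method
#' except the MR-Egger slope, which uses its estimated intercept.
#'
#' @param set A `harmonized_set`.
#' @param estimates A list of `mr_estimate` and/or `mr_egger` objects.
#' @return An object of class `mr_plot_data`: list with data.frames
#'   `scatter` (per-variant effects and SEs), `lines` (method, slope,
#'   intercept), and `funnel` (per-variant ratio and precision plus a
#'   `reference` column holding the pooled IVW estimate where available).
#' @export
plot_data <- function(set, estimates = list()) {
  d <- set$data
  scatter <- data.frame(SNP = d$SNP, beta_exposure = d$beta_exposure,
                        beta_outcome = d$beta_outcome,
                        se_exposure = d$se_exposure,
                        se_outcome = d$se_outcome,
                        stringsAsFactors = FALSE)
  flat <- list()
  for (e in estimates) {
    if (inherits(e, "mr_egger")) {
      flat <- c(flat, list(e$slope), list(e$intercept))
    } else {
      flat <- c(flat, list(e))
    }
  }
  eg_int <- 0
  for (e in flat) {
    if (e$method == "egger_intercept") eg_int <- e$beta
  }
  line_methods <- vapply(flat, `[[`, character(1), "method")
  keep <- line_methods != "egger_intercept"
  lines <- data.frame(
    method = line_methods[keep],
    slope = vapply(flat[keep], `[[`, numeric(1), "beta"),
    intercept = ifelse(line_methods[keep] == "egger_slope", eg_int, 0),
    stringsAsFactors = FALSE
  )
  ref <- NA_real_
  for (e in flat) {
    if (e$method %in% c("ivw_fixed", "ivw_random") && is.na(ref)) {
      ref <- e$beta
    }
  }
  if (nrow(d) > 0) {
    ratio <- d$beta_outcome / d$beta_exposure
    precision <- abs(d$beta_exposure) / d$se_outcome
  } else {
    ratio <- numeric(0); precision <- numeric(0)
  }
  funnel <- data.frame(SNP = d$SNP, ratio = ratio, precision = precision,
                       reference = rep(ref, nrow(d)),
                       stringsAsFactors = FALSE)
  structure(list(scatter = scatter, lines = lines, funnel = funnel),
            class = "mr_plot_data")
}

#' Render a scatter plot of variant effects
#'
#' @param pd An `mr_plot_data` object.
#' @return A ggplot object.
#' @export
mr_scatter_plot <- function(pd) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for rendered plots")
  }
  ggplot2::ggplot(pd$scatter,
                  ggplot2::aes(x = .data$beta_exposure,
                               y = .data$beta_outcome)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$beta_outcome - .data$se_outcome,
      ymax = .data$beta_outcome + .data$se_outcome),
      width = 0, colour = "grey70") +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$beta_exposure - .data$se_exposure,
      xmax = .data$beta_exposure + .data$se_exposure),
      height = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(data = pd$lines,
                         ggplot2::aes(slope = .data$slope,
                                      intercept = .data$intercept,
                                      colour = .data$method)) +
    ggplot2::labs(x = "SNP effect on exposure",
                  y = "SNP effect on outcome (log-odds)")
}

#' Render a funnel plot of Wald ratios
#'
#' @param pd An `mr_plot_data` object.
#' @return A ggplot object.
#' @export
mr_funnel_plot <- function(pd) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for rendered plots")
  }
  gg <- ggplot2::ggplot(pd$funnel,
                        ggplot2::aes(x = .data$ratio,
                                     y = .data$precision)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Wald ratio", y = "Precision (1/SE)")
  if (nrow(pd$funnel) > 0 && !is.na(pd$funnel$reference[1])) {
    gg <- gg + ggplot2::geom_vline(xintercept = pd$funnel$reference[1],
                                   linetype = "dashed")
  }
  gg
}
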