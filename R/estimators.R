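#' Construct a causal-effect estimate
#'
#' Wraps an estimate on the log-odds scale with its odds-ratio conversion,
#' confidence interval, and two-sided normal p-value.
#'
#' @param method Method label, one of `wald`, `ivw_fixed`, `ivw_random`,
#'   `egger_slope`, `egger_intercept`, `weighted_median`, `max_likelihood`.
#' @param n_snp Number of instruments the estimate used.
#' @param beta Point estimate on the log-odds scale.
#' @param se Standard error of `beta` (> 0).
#' @param weights Per-variant weights used, where applicable.
#' @param level Confidence level (default 0.95).
#' @param pvalue Optional externally computed p-value; by default the
#'   two-sided normal p `2 * pnorm(-|beta/se|)`.
#' @return An object of class `mr_estimate`.
#' @export
mr_estimate <- function(method, n_snp, beta, se, weights = numeric(0),
                        level = 0.95, pvalue = NULL) {
  beta <- unname(beta); se <- unname(se)
  stopifnot(se > 0, level > 0, level < 1)
  orci <- to_odds_ratio(beta, se, level)
  if (is.null(pvalue)) pvalue <- 2 * stats::pnorm(-abs(beta / se))
  pvalue <- max(pvalue, .Machine$double.xmin)  # keep in (0, 1]
  structure(list(method = method, n_snp = as.integer(n_snp), beta = beta,
                 se = se, or = orci[["or"]], ci_low = orci[["ci_low"]],
                 ci_high = orci[["ci_high"]], pvalue = pvalue,
                 level = level, weights = weights),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s (J=%d): beta=%.4f se=%.4f OR=%.2f (%.2f-%.2f) p=%.3g\n",
              x$method, x$n_snp, x$beta, x$se, x$or, x$ci_low, x$ci_high,
              x$pvalue))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snp = x$n_snp, beta = x$beta, se = x$se,
             or = x$or, ci_low = x$ci_low, ci_high = x$ci_high,
             pvalue = x$pvalue, stringsAsFactors = FALSE)
}

#' Convert a log-odds estimate to an odds ratio with confidence interval
#'
#' @param beta Estimate on the log-odds scale.
#' @param se Standard error (> 0).
#' @param level Confidence level in (0, 1); default 0.95.
#' @return Named numeric vector `or`, `ci_low`, `ci_high` with
#'   `or = exp(beta)` and bounds `exp(beta -/+ z * se)` for the two-sided
#'   normal quantile `z`.
#' @export
to_odds_ratio <- function(beta, se, level = 0.95) {
  beta <- unname(beta); se <- unname(se)
  stopifnot(se > 0, level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(or = exp(beta), ci_low = exp(beta - z * se),
    ci_high = exp(beta + z * se))
}

#' Wald ratio for a single instrument
#'
#' The per-variant causal estimate: outcome effect divided by exposure
#' effect, `beta = by / bx`, with the first-order delta-method standard
#' error `se = |sy / bx|` that underlies inverse-variance weighting (the
#' exposure effect is treated as fixed). A second-order standard error that
#' propagates the exposure uncertainty,
#' `sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)`, is available via
#' `second_order = TRUE`.
#'
#' @param bx,sx Exposure effect and standard error.
#' @param by,sy Outcome effect and standard error.
#' @param second_order Use the second-order delta-method SE (default FALSE).
#' @return An `mr_estimate` with method `"wald"`.
#' @export
wald_ratio <- function(bx, sx, by, sy, second_order = FALSE) {
  if (bx == 0) stop("degenerate instrument: exposure effect is zero")
  stopifnot(sx > 0, sy > 0)
  beta <- by / bx
  se <- if (second_order) {
    sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  } else {
    abs(sy / bx)
  }
  mr_estimate("wald", 1L, beta, se)
}

# Internal: ratio estimates and IVW weights for a harmonized set.
ivw_parts <- function(set) {
  d <- set$data
  if (any(d$beta_exposure == 0)) {
    stop("degenerate instrument: zero exposure effect for ",
         paste(d$SNP[d$beta_exposure == 0], collapse = ", "))
  }
  list(ratio = d$beta_outcome / d$beta_exposure,
       w = d$beta_exposure^2 / d$se_outcome^2)
}

#' Inverse-variance weighted estimate
#'
#' Pools the per-variant Wald ratios with inverse-variance weights
#' `w_j = bx_j^2 / sy_j^2` (equivalently, weighted least squares of the
#' outcome effects on the exposure effects through the origin). The fixed
#' model uses `se = (sum w_j)^{-1/2}`; the multiplicative random-effects
#' model inflates it by `max(1, sqrt(Q / (J - 1)))` where `Q` is Cochran's
#' heterogeneity statistic; `model = "auto"` selects random effects exactly
#' when the heterogeneity p-value is below `het_alpha` and records which
#' branch fired in the `method` label and the `model_selected` attribute.
#'
#' A single instrument is accepted (the result is then the Wald ratio) with
#' a warning, so screening loops over many exposures do not hard-fail on
#' sparse instrument sets.
#'
#' @param set A `harmonized_set`.
#' @param model `"auto"` (default), `"fixed"`, or `"random"`.
#' @param het_alpha Heterogeneity significance level for the auto switch
#'   (default 0.05).
#' @return An `mr_estimate` with method `"ivw_fixed"` or `"ivw_random"`,
#'   carrying attributes `q`, `q_df`, `q_pvalue`, `model_selected`.
#' @export
mr_ivw <- function(set, model = c("auto", "fixed", "random"),
                   het_alpha = 0.05) {
  model <- match.arg(model)
  p <- ivw_parts(set)
  J <- length(p$ratio)
  if (J == 0) stop("empty harmonized set: no instruments for IVW")
  if (J == 1) {
    warning("single instrument: IVW reduces to the Wald ratio")
    d <- set$data
    est <- wald_ratio(d$beta_exposure, d$se_exposure, d$beta_outcome,
                      d$se_outcome)
    est$method <- "ivw_fixed"
    est$weights <- p$w
    attr(est, "q") <- NA_real_; attr(est, "q_df") <- 0L
    attr(est, "q_pvalue") <- NA_real_
    attr(est, "model_selected") <- "fixed"
    return(est)
  }
  beta <- sum(p$w * p$ratio) / sum(p$w)
  se_fixed <- 1 / sqrt(sum(p$w))
  q <- sum(p$w * (p$ratio - beta)^2)
  q_p <- stats::pchisq(q, df = J - 1, lower.tail = FALSE)
  use_random <- switch(model,
                       fixed = FALSE,
                       random = TRUE,
                       auto = q_p < het_alpha)
  se <- if (use_random) se_fixed * max(1, sqrt(q / (J - 1))) else se_fixed
  est <- mr_estimate(if (use_random) "ivw_random" else "ivw_fixed",
                     J, beta, se, weights = p$w)
  attr(est, "q") <- q
  attr(est, "q_df") <- J - 1L
  attr(est, "q_pvalue") <- q_p
  attr(est, "model_selected") <- if (use_random) "random" else "fixed"
  est
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with
#' an unconstrained intercept, weights `1 / sy_j^2`. Each variant is first
#' oriented so its exposure effect is non-negative (flipping both effect
#' signs together), which makes the fit invariant to arbitrary allele
#' orientation. The slope estimates the causal effect under the InSIDE
#' assumption; the intercept estimates the average directional pleiotropic
#' effect, and an intercept p-value below 0.05 is the conventional flag for
#' horizontal pleiotropy.
#'
#' Standard errors use multiplicative overdispersion: the residual variance
#' scale `RSS_w / (J - 2)` is floored at 1, so standard errors are never
#' deflated below the fixed-effect ones. P-values are two-sided normal by
#' default; `use_t = TRUE` switches to the t distribution with `J - 2`
#' degrees of freedom.
#'
#' @param set A `harmonized_set` with at least 3 variants.
#' @param use_t Use t-distribution p-values (default FALSE).
#' @return A list of class `mr_egger` with elements `slope` and `intercept`
#'   (both `mr_estimate`), plus `sigma` (the unfloored residual scale).
#' @export
mr_egger <- function(set, use_t = FALSE) {
  d <- set$data
  J <- nrow(d)
  if (J < 3) stop("insufficient instruments: MR-Egger needs at least 3")
  flip <- sign(d$beta_exposure)
  flip[flip == 0] <- 1
  bx <- d$beta_exposure * flip
  by <- d$beta_outcome * flip
  w <- 1 / d$se_outcome^2
  X <- cbind(intercept = 1, slope = bx)
  XtWX <- crossprod(X, w * X)
  coef <- solve(XtWX, crossprod(X, w * by))
  resid <- by - X %*% coef
  rss_w <- sum(w * resid^2)
  sigma2 <- rss_w / (J - 2)
  vc <- max(1, sigma2) * solve(XtWX)
  ses <- sqrt(diag(vc))
  pfun <- if (use_t) {
    function(b, s) 2 * stats::pt(-abs(b / s), df = J - 2)
  } else {
    function(b, s) 2 * stats::pnorm(-abs(b / s))
  }
  slope <- mr_estimate("egger_slope", J, coef["slope", 1], ses["slope"],
                       weights = w, pvalue = pfun(coef["slope", 1],
                                                  ses["slope"]))
  intercept <- mr_estimate("egger_intercept", J, coef["intercept", 1],
                           ses["intercept"], weights = w,
                           pvalue = pfun(coef["intercept", 1],
                                         ses["intercept"]))
  structure(list(slope = slope, intercept = intercept,
                 sigma = sqrt(sigma2)), class = "mr_egger")
}

#' @export
print.mr_egger <- function(x, ...) {
  cat("MR-Egger regression\n  slope:     ")
  print(x$slope)
  cat("  intercept: ")
  print(x$intercept)
  invisible(x)
}

# Internal: weighted-median point estimate of ratio estimates.
# Orders the ratios, forms cumulative midpoint percentiles
# p_j = (S_j - w_j / 2) / S_J, and linearly interpolates at 0.5.
weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  ratio <- ratio[ord]
  w <- w[ord]
  s <- cumsum(w)
  p <- (s - w / 2) / s[length(s)]
  stats::approx(p, ratio, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted median estimate
#'
#' The weighted median of the per-variant Wald ratios under IVW weights
#' normalized to sum to one. It is a consistent causal estimate as long as
#' more than half of the total weight comes from valid instruments, making
#' it robust to a minority of pleiotropic variants. The standard error is
#' the standard deviation of the estimate over `n_boot` parametric
#' bootstrap replicates in which each exposure and outcome effect is
#' redrawn from a normal distribution centred on its observed value with
#' its reported standard error.
#'
#' @param set A `harmonized_set` with at least 3 variants.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap (default 42); the caller's RNG
#'   state is left untouched.
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(set, n_boot = 1000, seed = 42) {
  d <- set$data
  J <- nrow(d)
  if (J < 3) stop("insufficient instruments: weighted median needs at least 3")
  p <- ivw_parts(set)
  wn <- p$w / sum(p$w)
  beta <- weighted_median_point(p$ratio, wn)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(J, d$beta_exposure, d$se_exposure)
      by <- stats::rnorm(J, d$beta_outcome, d$se_outcome)
      w <- bx^2 / d$se_outcome^2
      weighted_median_point(by / bx, w / sum(w))
    }, numeric(1))
  })
  se <- stats::sd(boots)
  if (se <= 0) se <- .Machine$double.eps
  mr_estimate("weighted_median", J, beta, se, weights = wn)
}

#' Maximum-likelihood estimate
#'
#' Joint normal-likelihood model for the causal effect that, unlike IVW,
#' accounts for measurement error in the exposure effects: the observed
#' exposure effect of variant `j` is `N(xi_j, sx_j^2)` and the observed
#' outcome effect is `N(theta * xi_j, sy_j^2)`, with the true instrument
#' effects `xi_j` profiled as nuisance parameters. The log-likelihood is
#' maximized by BFGS with an analytic gradient, initialized at the IVW
#' estimate and the observed exposure effects; the standard error comes
#' from the observed information (numeric Hessian) at the optimum.
#'
#' @param set A `harmonized_set`.
#' @param reltol Relative convergence tolerance for the optimizer
#'   (default 1e-10).
#' @return An `mr_estimate` with method `"max_likelihood"`.
#' @export
mr_max_likelihood <- function(set, reltol = 1e-10) {
  d <- set$data
  J <- nrow(d)
  if (J == 0) stop("empty harmonized set: no instruments")
  bx <- d$beta_exposure; sx <- d$se_exposure
  by <- d$beta_outcome; sy <- d$se_outcome
  theta0 <- if (J == 1) {
    by / bx
  } else {
    suppressWarnings(mr_ivw(set, model = "fixed")$beta)
  }
  nll <- function(par) {
    theta <- par[1]; xi <- par[-1]
    sum((bx - xi)^2 / (2 * sx^2) + (by - theta * xi)^2 / (2 * sy^2))
  }
  grad <- function(par) {
    theta <- par[1]; xi <- par[-1]
    ry <- (by - theta * xi) / sy^2
    c(-sum(ry * xi),
      -(bx - xi) / sx^2 - theta * ry)
  }
  fit <- stats::optim(c(theta0, bx), nll, grad, method = "BFGS",
                      control = list(reltol = reltol, maxit = 1000))
  if (fit$convergence != 0) {
    stop("maximum-likelihood optimizer did not converge (code ",
         fit$convergence, "): ", fit$message)
  }
  # Observed information at the optimum has an arrow structure: one theta
  # row/column bordering a diagonal xi block. The theta variance is the
  # inverse Schur complement, which stays well conditioned even when the
  # exposure standard errors are orders of magnitude below the outcome ones.
  theta <- fit$par[1]; xi <- fit$par[-1]
  h_tt <- sum(xi^2 / sy^2)
  h_tx <- -(by - 2 * theta * xi) / sy^2
  h_xx <- 1 / sx^2 + theta^2 / sy^2
  info_theta <- h_tt - sum(h_tx^2 / h_xx)
  if (!is.finite(info_theta) || info_theta <= 0) {
    stop("observed information is singular at the optimum")
  }
  mr_estimate("max_likelihood", J, theta, sqrt(1 / info_theta))
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
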