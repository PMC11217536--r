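test_that("Wald ratio follows hand arithmetic and propagates sign", {
  w <- wald_ratio(0.2, 0.01, 0, 0.02)
  expect_equal(w$beta, 0)
  expect_equal(w$or, 1)

  w <- wald_ratio(0.2, 0.01, 0.05, 0.02)
  expect_equal(w$beta, 0.25)
  expect_equal(w$se, 0.1)

  w <- wald_ratio(-0.2, 0.01, 0.05, 0.02)
  expect_equal(w$beta, -0.25)
  expect_equal(w$se, 0.1)

  expect_error(wald_ratio(0, 0.01, 0.05, 0.02), "degenerate instrument")

  # second-order SE adds the exposure-uncertainty term
  w2 <- wald_ratio(0.2, 0.01, 0.05, 0.02, second_order = TRUE)
  expect_equal(w2$se, sqrt(0.02^2 / 0.04 + 0.05^2 * 0.01^2 / 0.2^4))
})

test_that("IVW reduces to the Wald ratio on a single instrument", {
  h1 <- make_hs(0.2, 0.01, 0.05, 0.02)
  expect_warning(i1 <- mr_ivw(h1), "single instrument")
  w <- wald_ratio(0.2, 0.01, 0.05, 0.02)
  expect_identical(i1$beta, w$beta)
  expect_identical(i1$se, w$se)
})

test_that("IVW equals weighted least squares through the origin", {
  set.seed(101)
  for (r in 1:10) {
    J <- sample(3:20, 1)
    bx <- rnorm(J, 0.1, 0.03)
    by <- 0.4 * bx + rnorm(J, 0, 0.04)
    sy <- runif(J, 0.01, 0.06)
    hs <- make_hs(bx, rep(0.013, J), by, sy)
    est <- mr_ivw(hs, model = "fixed")
    fit <- lm(by ~ 0 + bx, weights = 1 / sy^2)
    expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-10)
    se_fixed <- sqrt(vcov(fit)[1, 1]) / summary(fit)$sigma
    expect_equal(est$se, unname(se_fixed), tolerance = 1e-10)
  }
})

test_that("the auto model switches to random effects exactly on heterogeneity", {
  set.seed(7)
  J <- 15
  bx <- rnorm(J, 0.1, 0.02)
  sy <- rep(0.03, J)
  # gross heterogeneity
  by <- 0.3 * bx + rnorm(J, 0, 5 * 0.03)
  hs <- make_hs(bx, rep(0.013, J), by, sy)
  q <- cochran_q(hs)
  auto <- mr_ivw(hs, model = "auto")
  expect_identical(attr(auto, "model_selected"), q$model_selected)
  expect_identical(q$model_selected, "random")
  fixed <- mr_ivw(hs, model = "fixed")
  expect_identical(auto$beta, fixed$beta)
  expect_equal(auto$se,
               fixed$se * max(1, sqrt(q$q_statistic / (J - 1))))

  # homogeneous data stay on the fixed branch
  by2 <- 0.3 * bx + rnorm(J, 0, 0.2 * 0.03)
  hs2 <- make_hs(bx, rep(0.013, J), by2, sy)
  expect_identical(attr(mr_ivw(hs2, model = "auto"), "model_selected"),
                   "fixed")
})

test_that("MR-Egger matches weighted least squares with intercept", {
  expect_error(mr_egger(make_hs(c(0.1, 0.2), c(0.01, 0.01),
                                c(0.05, 0.1), c(0.02, 0.02))),
               "insufficient instruments")

  # exactly collinear data: perfect fit
  bx <- c(0.05, 0.1, 0.2, 0.3)
  hs <- make_hs(bx, rep(0.01, 4), 0.5 * bx, rep(0.02, 4))
  eg <- mr_egger(hs)
  expect_equal(eg$slope$beta, 0.5, tolerance = 1e-12)
  expect_equal(eg$intercept$beta, 0, tolerance = 1e-12)

  set.seed(303)
  for (r in 1:10) {
    J <- sample(4:20, 1)
    bx <- abs(rnorm(J, 0.1, 0.03))
    by <- 0.02 + 0.4 * bx + rnorm(J, 0, 0.04)
    sy <- runif(J, 0.01, 0.06)
    hs <- make_hs(bx, rep(0.013, J), by, sy)
    eg <- mr_egger(hs)
    fit <- lm(by ~ bx, weights = 1 / sy^2)
    expect_equal(eg$slope$beta, unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(eg$intercept$beta, unname(coef(fit)[1]), tolerance = 1e-10)
  }
})

test_that("the Egger intercept recovers directional pleiotropy under InSIDE", {
  ints <- numeric(500)
  for (r in 1:500) {
    s <- sim_hs(sim_config(n_snps = 50, theta = 0, prop_invalid = 1,
                           alpha_mean = 0.02, alpha_sd = 0.005,
                           seed = 60000 + r))
    ints[r] <- mr_egger(s$hs)$intercept$beta
  }
  expect_lt(abs(mean(ints) - 0.02), 0.002)
})

test_that("the weighted median interpolates cumulative midpoint percentiles", {
  # equal weights, ratios 0.1/0.2/0.3 -> exactly the middle ratio
  hs <- make_hs(rep(1, 3), rep(0.01, 3), c(0.1, 0.2, 0.3), rep(1, 3))
  wm <- mr_weighted_median(hs, n_boot = 100, seed = 1)
  expect_equal(wm$beta, 0.2)

  # all ratios identical: estimate is that constant, bootstrap SE small
  hs <- make_hs(c(0.1, 0.2, 0.4), c(0.001, 0.001, 0.001),
                0.3 * c(0.1, 0.2, 0.4), c(0.001, 0.001, 0.001))
  wm <- mr_weighted_median(hs, n_boot = 200, seed = 2)
  expect_equal(wm$beta, 0.3, tolerance = 1e-10)
  expect_lt(wm$se, 0.05)

  expect_error(mr_weighted_median(make_hs(0.1, 0.01, 0.05, 0.02)),
               "insufficient instruments")

  # unequal weights: hand evaluation of the interpolation rule
  hs <- make_hs(c(1, 2, 1), rep(0.01, 3), c(0.1, 0.4, 0.3), rep(1, 3))
  # ratios 0.1, 0.2, 0.3 with weights 1/6, 4/6, 1/6:
  # percentiles 1/12, 1/2, 11/12 -> median = 0.2
  wm <- mr_weighted_median(hs, n_boot = 100, seed = 3)
  expect_equal(wm$beta, 0.2)
})

test_that("weighted-median bootstrap is seed-deterministic and leaves the RNG alone", {
  s <- sim_hs(sim_config(n_snps = 12, theta = 0.3, seed = 5))
  set.seed(99)
  before <- .Random.seed
  a <- mr_weighted_median(s$hs, n_boot = 100, seed = 7)
  expect_identical(.Random.seed, before)
  b <- mr_weighted_median(s$hs, n_boot = 100, seed = 7)
  expect_identical(a$se, b$se)
})

test_that("maximum likelihood matches its limiting oracles", {
  # single instrument: profile likelihood peaks at the Wald ratio
  h1 <- make_hs(0.2, 0.01, 0.05, 0.02)
  ml <- mr_max_likelihood(h1)
  expect_equal(ml$beta, 0.25, tolerance = 1e-6)

  # vanishing exposure error: agrees with IVW
  s <- sim_hs(sim_config(n_snps = 15, theta = 0.4, seed = 17))
  d <- s$hs$data
  hs0 <- make_hs(d$beta_exposure, 1e-8 * d$se_outcome,
                 d$beta_outcome, d$se_outcome)
  ml <- mr_max_likelihood(hs0)
  ivw <- mr_ivw(hs0, model = "fixed")
  expect_equal(ml$beta, ivw$beta, tolerance = 1e-4)

  # with real exposure error the ML estimate still recovers the truth
  ml2 <- mr_max_likelihood(s$hs)
  expect_lt(abs(ml2$beta - 0.4), 0.2)
  expect_gt(ml2$se, 0)
})

test_that("odds-ratio conversion matches hand arithmetic", {
  o <- to_odds_ratio(0, 0.1)
  expect_equal(unname(o["or"]), 1)
  expect_lt(o["ci_low"], 1)
  expect_gt(o["ci_high"], 1)
  expect_equal(unname(o["ci_low"] * o["ci_high"]), 1, tolerance = 1e-12)

  o <- to_odds_ratio(log(2), 1e-12)
  expect_equal(unname(o["or"]), 2)
  expect_equal(unname(o["ci_low"]), 2, tolerance = 1e-9)

  o <- to_odds_ratio(0.4574, 0.1938)
  expect_equal(unname(o["or"]), 1.5799607422, tolerance = 1e-9)
  expect_equal(unname(o["ci_low"]), 1.0806459669, tolerance = 1e-9)
  expect_equal(unname(o["ci_high"]), 2.3099849750, tolerance = 1e-9)
})

test_that("estimators are scale-equivariant and orientation-invariant", {
  s <- sim_hs(sim_config(n_snps = 14, theta = 0.3, seed = 23))
  d <- s$hs$data
  c_scale <- 2.7
  scaled <- make_hs(d$beta_exposure, d$se_exposure,
                    c_scale * d$beta_outcome, c_scale * d$se_outcome)
  flip <- rep(c(1, -1), length.out = nrow(d))
  flipped <- make_hs(flip * d$beta_exposure, d$se_exposure,
                     flip * d$beta_outcome, d$se_outcome)

  for (fits in list(
    list(function(h) mr_ivw(h, model = "fixed"), 1e-10, TRUE),
    # bootstrap SE is not draw-by-draw orientation invariant (the noise is
    # not sign-flipped with the effects), so only the point estimate is
    # checked for the weighted median
    list(function(h) mr_weighted_median(h, n_boot = 50, seed = 3), 1e-8,
         FALSE),
    list(function(h) mr_max_likelihood(h), 1e-5, TRUE),
    list(function(h) mr_egger(h)$slope, 1e-8, TRUE)
  )) {
    fit <- fits[[1]]; tol <- fits[[2]]; check_se <- fits[[3]]
    base <- fit(s$hs)
    sc <- fit(scaled)
    expect_equal(sc$beta, c_scale * base$beta, tolerance = tol)
    expect_equal(sc$se, c_scale * base$se, tolerance = tol)
    fl <- fit(flipped)
    expect_equal(fl$beta, base$beta, tolerance = tol)
    if (check_se) expect_equal(fl$se, base$se, tolerance = tol)
  }
})
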