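# Intraclass correlations and maximum-likelihood twin model fitting.

make_two_group <- function(a2, c2, n_mz, n_dz, seed, missing_rate = 0) {
  e2 <- 1 - a2 - c2
  simulate_twin_dataset(twin_sim_spec(
    a2_m = a2, c2_m = c2, e2_m = e2, a2_f = a2, c2_f = c2, e2_f = e2,
    n_pairs_by_group = c(MZm = ceiling(n_mz / 2), MZf = floor(n_mz / 2),
                         DZm = ceiling(n_dz / 2), DZf = floor(n_dz / 2),
                         DZos = 0),
    missing_rate = missing_rate, seed = seed))
}

test_that("intraclass correlation: identical, independent, calibrated", {
  x <- rnorm(100)
  icc <- intraclass_correlation(x, x)
  expect_equal(icc$r, 1, tolerance = 1e-12)

  set.seed(201)
  icc <- intraclass_correlation(rnorm(10000), rnorm(10000))
  expect_lt(abs(icc$r), 0.03)

  expect_error(intraclass_correlation(1:2, 1:2), "3 complete pairs")
  expect_error(intraclass_correlation(rep(1, 10), rep(1, 10)), "variance")

  # coverage calibration at the scale of a real MZ group
  set.seed(202)
  rho <- 0.35
  hits <- 0; rs <- numeric(300)
  for (i in 1:300) {
    x1 <- rnorm(730)
    x2 <- rho * x1 + sqrt(1 - rho^2) * rnorm(730)
    icc <- intraclass_correlation(x1, x2)
    rs[i] <- icc$r
    hits <- hits + (icc$ci_low <= rho && rho <= icc$ci_high)
  }
  expect_lt(abs(mean(rs) - rho), 0.01)
  expect_gt(hits / 300, 0.93)
  expect_lt(hits / 300, 0.98)
})

test_that("AE fit recovers a null world and a boundary world", {
  d <- make_two_group(0, 0, 2500, 2500, seed = 203)
  f <- fit_twin_model(d, "AE")
  expect_lt(f$estimates$a2, 0.05)

  # near-degenerate: all variance genetic plus tiny jitter
  d <- make_two_group(0.98, 0, 400, 400, seed = 204)
  f <- fit_twin_model(d, "AE")
  expect_gt(f$estimates$a2, 0.95)
})

test_that("ML estimates agree with the Falconer moment oracle at large n", {
  d <- make_two_group(0.4, 0.2, 25000, 25000, seed = 205)
  f <- fit_twin_model(d, "ACE")
  fal <- oracle_falconer(d)
  expect_lt(abs(f$estimates$a2 - fal[["a2"]]), 0.02)
  expect_lt(abs(f$estimates$c2 - fal[["c2"]]), 0.02)
  expect_equal(f$estimates$a2 + f$estimates$c2 + f$estimates$e2, 1,
               tolerance = 1e-6)
})

test_that("likelihood ordering holds across nested models", {
  for (seed in 206:208) {
    d <- make_two_group(0.32, 0.05, 700, 1100, seed = seed,
                        missing_rate = 0.13)
    m2 <- vapply(c("saturated", "ACE", "AE", "E"), function(m) {
      fit_twin_model(d, m)$minus2LL
    }, numeric(1))
    expect_true(all(diff(m2) > -1e-4))
  }
})

test_that("when c2 is estimated at zero, AE and ACE coincide", {
  d <- make_two_group(0.32, 0, 700, 1100, seed = 209)
  ace <- fit_twin_model(d, "ACE")
  ae <- fit_twin_model(d, "AE")
  if (ace$estimates$c2 < 1e-4) {
    expect_equal(ace$minus2LL, ae$minus2LL, tolerance = 1e-3)
  }
  cmp <- compare_models(ace, ae)
  expect_gte(cmp$p_value, 0)
  expect_false(cmp$inverted)
})

test_that("FIML with no missingness equals the complete-pairs likelihood", {
  d <- make_two_group(0.35, 0.1, 300, 300, seed = 210)
  f <- fit_twin_model(d, "ACE")
  # direct bivariate-normal evaluation at the fitted parameters
  p <- twin_pairs(d)
  est <- f$estimates
  mu <- est$mu; V <- est$V
  cmz <- est$V * (est$a2 + est$c2)
  cdz <- est$V * (0.5 * est$a2 + est$c2)
  dmvn <- function(x1, x2, cv) {
    S <- matrix(c(V, cv, cv, V), 2)
    -2 * sum(mapply(function(a, b) {
      d <- c(a, b) - mu
      -log(2 * pi) - 0.5 * log(det(S)) - 0.5 * drop(t(d) %*% solve(S) %*% d)
    }, x1, x2))
  }
  manual <- dmvn(p$MZ$x1, p$MZ$x2, cmz) + dmvn(p$DZ$x1, p$DZ$x2, cdz)
  expect_equal(f$minus2LL, manual, tolerance = 1e-6)
})

test_that("paper-scale AE recovery is unbiased over replicates", {
  a2 <- numeric(12)
  for (i in seq_along(a2)) {
    d <- make_two_group(0.32, 0, 700, 1140, seed = 300 + i)
    a2[i] <- fit_twin_model(d, "AE")$estimates$a2
  }
  expect_lt(abs(mean(a2) - 0.32), 0.025)
})

test_that("profile CIs bracket the estimate and tighten with n", {
  d_small <- make_two_group(0.35, 0, 60, 60, seed = 211)
  f_small <- fit_twin_model(d_small, "AE")
  ci_small <- profile_ci(f_small, "a2")
  expect_lte(ci_small$low, f_small$estimates$a2)
  expect_gte(ci_small$high, f_small$estimates$a2)

  d_big <- make_two_group(0.35, 0, 25000, 25000, seed = 212)
  f_big <- fit_twin_model(d_big, "AE")
  ci_big <- profile_ci(f_big, "a2")
  expect_lt(ci_big$high - ci_big$low, 0.03)
  expect_gt(ci_small$high - ci_small$low, ci_big$high - ci_big$low)

  # boundary component: lower bound at exactly 0
  d <- make_two_group(0.32, 0, 700, 1100, seed = 213)
  f <- fit_twin_model(d, "ACE")
  if (f$estimates$c2 < 1e-6) {
    ci <- profile_ci(f, "c2")
    expect_identical(ci$low, 0)
    expect_true(ci$one_sided)
  }
})

test_that("compare_models handles identity, nesting and inversion flags", {
  d <- make_two_group(0.3, 0, 200, 200, seed = 214)
  ace <- fit_twin_model(d, "ACE")
  e <- fit_twin_model(d, "E")
  expect_identical(compare_models(ace, ace)$p_value, 1)
  cmp <- compare_models(ace, e)
  expect_identical(cmp$delta_params, 3L)
  expect_lt(cmp$p_value, 0.05)
  expect_error(compare_models(e, ace), "more parameters")
})

test_that("LRT of a boundary-null component follows the 50:50 mixture", {
  # true c2 = 0: Delta(-2LL) for ACE vs AE is a mixture of a point mass
  # at 0 and chi2(1), so P(p > 0.5) ~ 0.75, not the naive 0.5
  set.seed(215)
  ps <- numeric(60)
  for (i in seq_along(ps)) {
    d <- make_two_group(0.3, 0, 250, 400, seed = 400 + i)
    ps[i] <- compare_models(fit_twin_model(d, "ACE"),
                            fit_twin_model(d, "AE"))$p_value
  }
  expect_lt(abs(mean(ps > 0.5) - 0.75), 0.15)
})

test_that("model selection prefers the generating model", {
  picks <- character(24)
  for (i in seq_along(picks)) {
    d <- make_two_group(0.35, 0, 836, 1422, seed = 500 + i,
                        missing_rate = 0.13)
    fits <- lapply(c("ACE", "AE", "E"), function(m) fit_twin_model(d, m))
    picks[i] <- select_best(fits)$best
  }
  expect_gte(mean(picks == "AE"), 0.8)

  picks_e <- character(12)
  for (i in seq_along(picks_e)) {
    d <- make_two_group(0, 0, 500, 800, seed = 600 + i)
    fits <- lapply(c("ACE", "AE", "E"), function(m) fit_twin_model(d, m))
    picks_e[i] <- select_best(fits)$best
  }
  expect_gt(mean(picks_e == "E"), 0.5)

  single <- fit_twin_model(make_two_group(0.3, 0, 100, 100, seed = 216), "AE")
  expect_identical(select_best(list(single))$best, "AE")
})
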