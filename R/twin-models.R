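# Classical twin variance-component analysis: intraclass correlations and
# maximum-likelihood fitting of the saturated, ACE, AE and E models on
# two zygosity groups, with profile-likelihood confidence intervals.
#
# The likelihood is full-information over individuals: a complete pair
# contributes a bivariate normal with common mean and zygosity-specific
# covariance (cov_MZ = a^2 + c^2, cov_DZ = a^2/2 + c^2, total variance
# V = a^2 + c^2 + e^2); a singleton contributes the univariate normal.

.LOG2PI <- log(2 * pi)
# large finite penalty for infeasible covariance structures: L-BFGS-B
# cannot digest Inf objective values
.M2LL_PENALTY <- 1e10

.bvn_m2ll <- function(x1, x2, m1, m2, v1, v2, cv) {
  det <- v1 * v2 - cv^2
  if (!is.finite(det) || det <= 0 || v1 <= 0 || v2 <= 0) {
    return(.M2LL_PENALTY)
  }
  d1 <- x1 - m1; d2 <- x2 - m2
  q <- (v2 * d1^2 - 2 * cv * d1 * d2 + v1 * d2^2) / det
  length(x1) * (2 * .LOG2PI + log(det)) + sum(q)
}

.uvn_m2ll <- function(x, m, v) {
  if (length(x) == 0) return(0)
  if (!is.finite(v) || v <= 0) return(.M2LL_PENALTY)
  length(x) * (.LOG2PI + log(v)) + sum((x - m)^2) / v
}

#' Arrange a twin dataset into complete pairs and singletons
#'
#' @param dataset Data frame with `family_id`, `twin`, `zygosity` and the
#'   phenotype column.
#' @param pheno Name of the phenotype column.
#' @return List with, per zygosity (`MZ`, `DZ`): `x1`, `x2` (complete-pair
#'   values) and `single` (phenotypes of individuals whose co-twin value
#'   is missing); plus `n_obs`, the total number of non-missing values.
#' @export
twin_pairs <- function(dataset, pheno = "pheno") {
  stopifnot(all(c("family_id", "twin", "zygosity") %in% names(dataset)),
            pheno %in% names(dataset))
  out <- list()
  for (z in c("MZ", "DZ")) {
    d <- dataset[dataset$zygosity == z, , drop = FALSE]
    y1 <- d[[pheno]][d$twin == 1][match(unique(d$family_id),
                                        d$family_id[d$twin == 1])]
    y2 <- d[[pheno]][d$twin == 2][match(unique(d$family_id),
                                        d$family_id[d$twin == 2])]
    both <- !is.na(y1) & !is.na(y2)
    s1 <- y1[!both & !is.na(y1)]
    s2 <- y2[!both & !is.na(y2)]
    out[[z]] <- list(x1 = y1[both], x2 = y2[both],
                     single1 = s1, single2 = s2, single = c(s1, s2))
  }
  out$n_obs <- sum(!is.na(dataset[[pheno]]))
  out
}

# -2 log-likelihood of the two-group model given structural quantities
.twin_m2ll_struct <- function(pairs, mu, V, covMZ, covDZ) {
  .bvn_m2ll(pairs$MZ$x1, pairs$MZ$x2, mu, mu, V, V, covMZ) +
    .bvn_m2ll(pairs$DZ$x1, pairs$DZ$x2, mu, mu, V, V, covDZ) +
    .uvn_m2ll(pairs$MZ$single, mu, V) +
    .uvn_m2ll(pairs$DZ$single, mu, V)
}

.fit_multistart <- function(obj, start, lower, upper, n_restarts = 5) {
  best <- NULL
  starts <- list(start)
  # deterministic jitter pattern: restarts must not consume (or depend
  # on) the caller's RNG stream, or seeded pipelines lose reproducibility
  scl <- c(0.6, 1.5, 0.85, 1.2)
  off <- c(0.05, -0.05, 0.15, -0.15)
  for (i in seq_len(min(n_restarts, 5) - 1)) {
    s <- start * scl[i] + off[i]
    starts[[i + 1]] <- pmin(pmax(s, lower + 1e-6), upper - 1e-6)
  }
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("optimisation failed in every restart")
  best
}

.saturated_group_m2ll <- function(par, g) {
  m1 <- par[1]; m2 <- par[2]
  v1 <- exp(par[3]); v2 <- exp(par[4])
  cv <- tanh(par[5]) * sqrt(v1 * v2)
  .bvn_m2ll(g$x1, g$x2, m1, m2, v1, v2, cv) +
    .uvn_m2ll(g$single1, m1, v1) + .uvn_m2ll(g$single2, m2, v2)
}

#' Fit a twin variance-component model by maximum likelihood
#'
#' Fits one of the standard univariate two-group models over individuals
#' (complete pairs plus singletons):
#' * `"saturated"`: per zygosity group two means, two variances and a
#'   covariance (10 parameters);
#' * `"ACE"`: common mean plus path coefficients a, c, e (4 parameters);
#' * `"AE"`: shared environment dropped (3 parameters);
#' * `"E"`: no familial resemblance; the mean is fixed at zero, as the
#'   model is intended for residualised (zero-mean) phenotypes
#'   (1 parameter).
#'
#' Paths are constrained non-negative; standardised components are the
#' squared paths divided by the total variance. Reports `-2LL`, the
#' classical `AIC = -2LL + 2p`, the legacy structural-equation convention
#' `AIC_mx = -2LL - 2 df` (with `df = n_obs - p`), and
#' `BIC = -2LL + p log(n_obs)`.
#'
#' @param dataset Twin data frame (see [simulate_twin_dataset()]) or the
#'   output of [twin_pairs()].
#' @param model One of `"saturated"`, `"ACE"`, `"AE"`, `"E"`.
#' @param pheno Phenotype column name.
#' @param n_restarts Optimiser restarts.
#' @return Object of class `twin_fit`.
#' @export
fit_twin_model <- function(dataset, model = c("ACE", "AE", "E", "saturated"),
                           pheno = "pheno", n_restarts = 5) {
  model <- match.arg(model)
  pairs <- if (is.data.frame(dataset)) twin_pairs(dataset, pheno) else dataset
  if (length(pairs$MZ$x1) + length(pairs$MZ$single) == 0 ||
      length(pairs$DZ$x1) + length(pairs$DZ$single) == 0) {
    stop("both zygosity groups must be represented")
  }
  n_obs <- pairs$n_obs
  allx <- c(pairs$MZ$x1, pairs$MZ$x2, pairs$MZ$single,
            pairs$DZ$x1, pairs$DZ$x2, pairs$DZ$single)
  v0 <- stats::var(allx)
  if (!is.finite(v0) || v0 <= 0) stop("phenotype variance is zero")

  if (model == "saturated") {
    m2ll <- 0; pars <- list()
    for (z in c("MZ", "DZ")) {
      g <- pairs[[z]]
      r0 <- if (length(g$x1) > 2) stats::cor(g$x1, g$x2) else 0
      start <- c(mean(c(g$x1, g$single)), mean(c(g$x2, g$single)),
                 log(v0), log(v0), atanh(min(max(r0, -0.95), 0.95)))
      fit <- .fit_multistart(function(p) .saturated_group_m2ll(p, g), start,
                             lower = c(-Inf, -Inf, -20, -20, -5),
                             upper = c(Inf, Inf, 20, 20, 5),
                             n_restarts = n_restarts)
      m2ll <- m2ll + fit$value
      pars[[z]] <- list(mean1 = fit$par[1], mean2 = fit$par[2],
                        var1 = exp(fit$par[3]), var2 = exp(fit$par[4]),
                        cov = tanh(fit$par[5]) *
                          sqrt(exp(fit$par[3]) * exp(fit$par[4])))
    }
    n_par <- 10L
    est <- list(saturated = pars)
  } else {
    # moment-based start from complete-pair correlations
    rMZ <- if (length(pairs$MZ$x1) > 2) stats::cor(pairs$MZ$x1, pairs$MZ$x2) else 0.3
    rDZ <- if (length(pairs$DZ$x1) > 2) stats::cor(pairs$DZ$x1, pairs$DZ$x2) else 0.15
    a2_0 <- min(max(2 * (rMZ - rDZ), 0.01), 0.95)
    c2_0 <- min(max(2 * rDZ - rMZ, 0.01), 0.95 - a2_0)
    e2_0 <- max(1 - a2_0 - c2_0, 0.02)
    mu0 <- mean(allx)
    if (model == "ACE") {
      obj <- function(p) {
        a <- p[2]; c <- p[3]; e <- p[4]
        V <- a^2 + c^2 + e^2
        .twin_m2ll_struct(pairs, p[1], V, a^2 + c^2, 0.5 * a^2 + c^2)
      }
      start <- c(mu0, sqrt(a2_0 * v0), sqrt(c2_0 * v0), sqrt(e2_0 * v0))
      lower <- c(-Inf, 0, 0, 1e-8); upper <- c(Inf, Inf, Inf, Inf)
    } else if (model == "AE") {
      obj <- function(p) {
        a <- p[2]; e <- p[3]
        .twin_m2ll_struct(pairs, p[1], a^2 + e^2, a^2, 0.5 * a^2)
      }
      start <- c(mu0, sqrt(max(a2_0 + c2_0, 0.02) * v0), sqrt(e2_0 * v0))
      lower <- c(-Inf, 0, 1e-8); upper <- c(Inf, Inf, Inf)
    } else { # E: mean fixed at 0 for residualised input
      obj <- function(p) {
        .twin_m2ll_struct(pairs, 0, p[1]^2, 0, 0)
      }
      start <- sqrt(v0); lower <- 1e-8; upper <- Inf
    }
    fit <- .fit_multistart(obj, start, lower, upper, n_restarts)
    p <- fit$par
    paths <- switch(model,
                    ACE = c(a = p[2], c = p[3], e = p[4]),
                    AE = c(a = p[2], c = 0, e = p[3]),
                    E = c(a = 0, c = 0, e = p[1]))
    V <- sum(paths^2)
    if (V <= 0) stop("degenerate variance in fitted model")
    est <- list(mu = if (model == "E") 0 else p[1],
                V = V, paths = paths,
                a2 = paths[["a"]]^2 / V, c2 = paths[["c"]]^2 / V,
                e2 = paths[["e"]]^2 / V)
    m2ll <- fit$value
    n_par <- switch(model, ACE = 4L, AE = 3L, E = 1L)
  }
  df <- n_obs - n_par
  structure(list(model = model, minus2LL = m2ll, n_obs = n_obs,
                 n_params = n_par, df = df,
                 aic = m2ll + 2 * n_par,
                 aic_mx = m2ll - 2 * df,
                 bic = m2ll + n_par * log(n_obs),
                 estimates = est, pairs = pairs, pheno = pheno),
            class = "twin_fit")
}

#' @export
print.twin_fit <- function(x, ...) {
  cat(sprintf("%s model: -2LL = %.2f, df = %d, AIC = %.2f, BIC = %.2f\n",
              x$model, x$minus2LL, x$df, x$aic, x$bic))
  if (!is.null(x$estimates$a2)) {
    cat(sprintf("  a2 = %.3f, c2 = %.3f, e2 = %.3f (V = %.3f)\n",
                x$estimates$a2, x$estimates$c2, x$estimates$e2,
                x$estimates$V))
  }
  invisible(x)
}

# profile -2LL with one standardised component fixed at t.
# Spherical split of the remaining variance keeps the simplex constraint
# exact: the two free proportions are (1-t) sin^2(phi), (1-t) cos^2(phi).
.twin_profile_m2ll <- function(pairs, model, component, t) {
  stopifnot(component %in% c("a2", "c2", "e2"))
  struct <- function(mu, V, pa, pc) {
    .twin_m2ll_struct(pairs, mu, V, V * (pa + pc), V * (0.5 * pa + pc))
  }
  if (model == "AE") {
    if (component == "c2") stop("AE model has no c2")
    obj <- function(p) {
      pa <- if (component == "a2") t else 1 - t
      struct(p[1], exp(p[2]), pa, 0)
    }
    start <- c(0, 0); lower <- c(-Inf, -20); upper <- c(Inf, 20)
  } else if (model == "ACE") {
    obj <- function(p) {
      s2 <- sin(p[3])^2
      rest <- (1 - t) * c(s2, 1 - s2)
      props <- switch(component,
                      a2 = c(t, rest[1]),        # (pa, pc); pe implied
                      c2 = c(rest[1], t),
                      e2 = c(rest[1], rest[2]))  # pa, pc from split
      struct(p[1], exp(p[2]), props[1], props[2])
    }
    start <- c(0, 0, pi / 4); lower <- c(-Inf, -20, 0)
    upper <- c(Inf, 20, pi / 2)
  } else stop("profile CIs are available for ACE and AE fits only")
  .fit_multistart(obj, start, lower, upper, n_restarts = 3)$value
}

#' Profile-likelihood confidence interval for a variance component
#'
#' Bounds are the values of the standardised component at which the
#' profiled `-2LL` exceeds its minimum by the chi-square(1) critical value
#' (3.84 at 95%), respecting the `[0, 1]` boundary. A component pinned at
#' a boundary yields a one-sided interval, flagged in the result.
#'
#' @param fit A `twin_fit` from [fit_twin_model()] (`ACE` or `AE`).
#' @param component One of `"a2"`, `"c2"`, `"e2"`.
#' @param level Confidence level (default 0.95).
#' @return List with `low`, `high`, `estimate`, `one_sided`.
#' @export
profile_ci <- function(fit, component = c("a2", "c2", "e2"), level = 0.95) {
  stopifnot(inherits(fit, "twin_fit"))
  component <- match.arg(component)
  if (!fit$model %in% c("ACE", "AE")) {
    stop("profile CIs are available for ACE and AE fits only")
  }
  crit <- fit$minus2LL + stats::qchisq(level, 1)
  est <- fit$estimates[[component]]
  prof <- function(t) .twin_profile_m2ll(fit$pairs, fit$model, component, t)
  f <- function(t) prof(t) - crit
  eps <- 1e-6
  low <- if (est <= eps) 0 else if (f(0) <= 0) 0 else {
    stats::uniroot(f, c(0, est), tol = 1e-4)$root
  }
  high <- if (est >= 1 - eps) 1 else if (f(1 - 1e-9) <= 0) 1 else {
    stats::uniroot(f, c(est, 1 - 1e-9), tol = 1e-4)$root
  }
  list(low = low, high = high, estimate = est,
       one_sided = est <= eps || est >= 1 - eps)
}

#' Likelihood-ratio comparison of nested twin models
#'
#' @param full,nested `twin_fit` objects on the same data, the nested one
#'   with fewer parameters.
#' @return List with `delta_minus2LL`, `delta_params`, `p_value` and
#'   `inverted` (TRUE when the nested model fits better than the full by
#'   more than numerical tolerance, signalling an optimiser failure).
#' @export
compare_models <- function(full, nested) {
  stopifnot(inherits(full, "twin_fit") || inherits(full, "sexlim_fit"),
            class(full) == class(nested))
  if (full$n_obs != nested$n_obs) stop("fits are not on the same data")
  d <- nested$minus2LL - full$minus2LL
  dp <- nested$df - full$df
  if (dp < 0) stop("`nested` must not have more parameters than `full`")
  inverted <- d < -1e-6
  p <- if (dp == 0) {
    if (abs(d) < 1e-6) 1 else NA_real_
  } else {
    stats::pchisq(max(d, 0), dp, lower.tail = FALSE)
  }
  list(delta_minus2LL = d, delta_params = dp, p_value = p,
       inverted = inverted)
}

#' Rank twin-model fits by information criteria and likelihood ratio
#'
#' Follows the usual selection logic: the preferred model is the most
#' parsimonious one, judged by (i) lowest AIC, (ii) lowest BIC, and
#' (iii) the most reduced nested model not significantly worse than the
#' full ACE model at `alpha`. Disagreements between the three criteria
#' are reported; the BIC choice breaks ties.
#'
#' @param fits List of `twin_fit` objects on the same data.
#' @param alpha LRT significance level.
#' @return List with `table` (one row per model), `best_aic`, `best_bic`,
#'   `best_lrt` (NA when no ACE fit is supplied) and `best`.
#' @export
select_best <- function(fits, alpha = 0.05) {
  stopifnot(length(fits) >= 1)
  if (length(fits) == 1) {
    return(list(table = NULL, best_aic = fits[[1]]$model,
                best_bic = fits[[1]]$model, best_lrt = fits[[1]]$model,
                best = fits[[1]]$model))
  }
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(model = f$model, minus2LL = f$minus2LL, n_params = f$n_params,
               df = f$df, aic = f$aic, aic_mx = f$aic_mx, bic = f$bic,
               stringsAsFactors = FALSE)
  }))
  names(fits) <- tab$model
  best_aic <- tab$model[which.min(tab$aic)]
  best_bic <- tab$model[which.min(tab$bic)]
  best_lrt <- NA_character_
  if ("ACE" %in% tab$model) {
    ace <- fits[["ACE"]]
    nested <- fits[tab$model %in% c("AE", "E")]
    keep <- ace$model
    if (length(nested)) {
      ps <- vapply(nested, function(f) compare_models(ace, f)$p_value,
                   numeric(1))
      ok <- names(nested)[!is.na(ps) & ps >= alpha]
      if (length(ok)) {
        np <- vapply(fits[ok], function(f) f$n_params, numeric(1))
        keep <- ok[which.min(np)]
      }
    }
    best_lrt <- keep
  }
  list(table = tab, best_aic = best_aic, best_bic = best_bic,
       best_lrt = best_lrt, best = best_bic)
}

#' Intraclass correlation for twin pairs
#'
#' Double-entry Pearson correlation (each pair entered both ways), the
#' one-way random-effects intraclass correlation for interchangeable
#' twins. The 95% interval uses the Fisher z transform with effective
#' sample size equal to the number of pairs.
#'
#' @param x1,x2 Co-twin phenotype values (complete pairs); alternatively
#'   `x1` may be a 2-column matrix.
#' @param level Confidence level.
#' @return Object of class `icc_result`: `r`, `n_pairs`, `ci_low`,
#'   `ci_high`.
#' @export
intraclass_correlation <- function(x1, x2 = NULL, level = 0.95) {
  if (is.null(x2)) { x2 <- x1[, 2]; x1 <- x1[, 1] }
  ok <- !is.na(x1) & !is.na(x2)
  x1 <- x1[ok]; x2 <- x2[ok]
  n <- length(x1)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::var(c(x1, x2)) == 0) stop("zero variance")
  r <- stats::cor(c(x1, x2), c(x2, x1))
  z <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12))
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(r = r, n_pairs = n, ci_low = tanh(z - q * se),
                 ci_high = tanh(z + q * se)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC r = %.3f (n = %d pairs, 95%% CI %.3f-%.3f)\n",
              x$r, x$n_pairs, x$ci_low, x$ci_high))
  invisible(x)
}

#' Intraclass correlations by zygosity
#'
#' @param dataset Twin data frame.
#' @param pheno Phenotype column name.
#' @return Data frame with one row per zygosity (`MZ`, `DZ`): `r`,
#'   `n_pairs`, `ci_low`, `ci_high`.
#' @export
icc_by_zygosity <- function(dataset, pheno = "pheno") {
  pairs <- twin_pairs(dataset, pheno)
  rows <- lapply(c("MZ", "DZ"), function(z) {
    g <- pairs[[z]]
    icc <- intraclass_correlation(g$x1, g$x2)
    data.frame(zygosity = z, r = icc$r, n_pairs = icc$n_pairs,
               ci_low = icc$ci_low, ci_high = icc$ci_high,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
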