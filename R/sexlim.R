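# Five-group sex-limitation twin models (Full, Common Effects, Scalar,
# Null), testing qualitative, quantitative and variance sex differences.
#
# Group structure: MZm, MZf, DZm, DZf (same-sex groups use that sex's
# paths) and DZos, whose pair covariance is rg * a_m * a_f + c_m * c_f
# with the shared-environment correlation fixed at 1. The genetic
# correlation rg is free in the Full model and fixed at 0.5 otherwise.
# A single grand mean is estimated in all four models (the phenotype is
# expected to be residualised, and the relative degrees of freedom of the
# four models then follow the conventional 8/7/5/4 parameter counts).

.SEXLIM_GROUPS <- c("MZm", "MZf", "DZm", "DZf", "DZos")

#' Arrange a twin dataset into the five sex-limitation groups
#'
#' @inheritParams twin_pairs
#' @return List with per-group complete pairs and singletons (for DZos,
#'   `x1`/`single1` is the male twin) plus `n_obs`.
#' @export
sexlim_groups <- function(dataset, pheno = "pheno") {
  stopifnot(all(c("family_id", "twin", "zygosity", "sex") %in% names(dataset)))
  d <- dataset
  fam <- unique(d$family_id)
  t1 <- d[d$twin == 1, ][match(fam, d$family_id[d$twin == 1]), ]
  t2 <- d[d$twin == 2, ][match(fam, d$family_id[d$twin == 2]), ]
  zyg <- t1$zygosity
  grp <- ifelse(zyg == "MZ", ifelse(t1$sex == "M", "MZm", "MZf"),
                ifelse(t1$sex == t2$sex,
                       ifelse(t1$sex == "M", "DZm", "DZf"), "DZos"))
  out <- list()
  for (g in .SEXLIM_GROUPS) {
    sel <- grp == g
    y1 <- t1[[pheno]][sel]; y2 <- t2[[pheno]][sel]
    if (g == "DZos") { # enforce twin 1 = male
      swap <- t1$sex[sel] == "F"
      tmp <- y1[swap]; y1[swap] <- y2[swap]; y2[swap] <- tmp
    }
    both <- !is.na(y1) & !is.na(y2)
    out[[g]] <- list(x1 = y1[both], x2 = y2[both],
                     single1 = y1[!both & !is.na(y1)],
                     single2 = y2[!both & !is.na(y2)])
  }
  out$n_obs <- sum(!is.na(d[[pheno]]))
  out
}

# -2LL given structural per-sex quantities
.sexlim_m2ll_struct <- function(gr, mu, Vm, Vf, covMZm, covDZm,
                                covMZf, covDZf, covOS) {
  .bvn_m2ll(gr$MZm$x1, gr$MZm$x2, mu, mu, Vm, Vm, covMZm) +
    .bvn_m2ll(gr$DZm$x1, gr$DZm$x2, mu, mu, Vm, Vm, covDZm) +
    .bvn_m2ll(gr$MZf$x1, gr$MZf$x2, mu, mu, Vf, Vf, covMZf) +
    .bvn_m2ll(gr$DZf$x1, gr$DZf$x2, mu, mu, Vf, Vf, covDZf) +
    .bvn_m2ll(gr$DZos$x1, gr$DZos$x2, mu, mu, Vm, Vf, covOS) +
    .uvn_m2ll(c(gr$MZm$single1, gr$MZm$single2,
                gr$DZm$single1, gr$DZm$single2, gr$DZos$single1), mu, Vm) +
    .uvn_m2ll(c(gr$MZf$single1, gr$MZf$single2,
                gr$DZf$single1, gr$DZf$single2, gr$DZos$single2), mu, Vf)
}

.sexlim_m2ll_paths <- function(gr, mu, am, cm, em, af, cf, ef, rg) {
  .sexlim_m2ll_struct(gr, mu,
                      Vm = am^2 + cm^2 + em^2, Vf = af^2 + cf^2 + ef^2,
                      covMZm = am^2 + cm^2, covDZm = 0.5 * am^2 + cm^2,
                      covMZf = af^2 + cf^2, covDZf = 0.5 * af^2 + cf^2,
                      covOS = rg * am * af + cm * cf)
}

#' Fit a sex-limitation twin model
#'
#' The four conventional five-group models:
#' * `"full"`: per-sex paths (a, c, e) and a free genetic correlation
#'   `rg` for opposite-sex pairs (qualitative + quantitative differences;
#'   8 parameters);
#' * `"common"`: per-sex paths, `rg = 0.5` (quantitative only;
#'   7 parameters);
#' * `"scalar"`: female paths are a single positive multiple `k` of the
#'   male paths, `rg = 0.5` (variance scaling only; 5 parameters);
#' * `"null"`: identical paths for both sexes (4 parameters).
#'
#' @param dataset Twin data frame with a `sex` column, or the output of
#'   [sexlim_groups()].
#' @param model One of `"full"`, `"common"`, `"scalar"`, `"null"`.
#' @param pheno Phenotype column name.
#' @param n_restarts Optimiser restarts.
#' @return Object of class `sexlim_fit` with per-sex standardised
#'   components, `rg` (full model), `k` (scalar model) and fit statistics.
#' @export
fit_sexlim <- function(dataset, model = c("full", "common", "scalar", "null"),
                       pheno = "pheno", n_restarts = 5) {
  model <- match.arg(model)
  gr <- if (is.data.frame(dataset)) sexlim_groups(dataset, pheno) else dataset
  for (g in .SEXLIM_GROUPS) {
    if (length(gr[[g]]$x1) + length(gr[[g]]$single1) +
        length(gr[[g]]$single2) == 0) {
      stop(sprintf("group %s is empty", g))
    }
  }
  allx <- unlist(lapply(gr[.SEXLIM_GROUPS],
                        function(g) c(g$x1, g$x2, g$single1, g$single2)))
  v0 <- stats::var(allx); mu0 <- mean(allx)
  s0 <- sqrt(v0)
  start_paths <- s0 * sqrt(c(0.3, 0.05, 0.65))

  if (model == "full") {
    obj <- function(p) .sexlim_m2ll_paths(gr, p[1], p[2], p[3], p[4],
                                          p[5], p[6], p[7], p[8])
    start <- c(mu0, start_paths, start_paths, 0.5)
    lower <- c(-Inf, rep(0, 3), rep(0, 3), 0)
    upper <- c(Inf, rep(Inf, 6), 1)
    n_par <- 8L
  } else if (model == "common") {
    obj <- function(p) .sexlim_m2ll_paths(gr, p[1], p[2], p[3], p[4],
                                          p[5], p[6], p[7], 0.5)
    start <- c(mu0, start_paths, start_paths)
    lower <- c(-Inf, rep(0, 6)); upper <- c(Inf, rep(Inf, 6))
    n_par <- 7L
  } else if (model == "scalar") {
    obj <- function(p) .sexlim_m2ll_paths(gr, p[1], p[2], p[3], p[4],
                                          p[5] * p[2], p[5] * p[3],
                                          p[5] * p[4], 0.5)
    start <- c(mu0, start_paths, 1)
    lower <- c(-Inf, rep(0, 3), 1e-6); upper <- c(Inf, rep(Inf, 3), Inf)
    n_par <- 5L
  } else {
    obj <- function(p) .sexlim_m2ll_paths(gr, p[1], p[2], p[3], p[4],
                                          p[2], p[3], p[4], 0.5)
    start <- c(mu0, start_paths)
    lower <- c(-Inf, rep(0, 3)); upper <- c(Inf, rep(Inf, 3))
    n_par <- 4L
  }
  fit <- .fit_multistart(obj, start, lower, upper, n_restarts)
  p <- fit$par
  paths_m <- switch(model,
                    full = p[2:4], common = p[2:4], scalar = p[2:4],
                    null = p[2:4])
  paths_f <- switch(model,
                    full = p[5:7], common = p[5:7],
                    scalar = p[5] * p[2:4], null = p[2:4])
  comp <- function(paths) {
    V <- sum(paths^2)
    list(V = V, a2 = paths[1]^2 / V, c2 = paths[2]^2 / V,
         e2 = paths[3]^2 / V)
  }
  n_obs <- gr$n_obs
  df <- n_obs - n_par
  m2ll <- fit$value
  structure(list(model = model, minus2LL = m2ll, n_obs = n_obs,
                 n_params = n_par, df = df,
                 aic = m2ll + 2 * n_par, aic_mx = m2ll - 2 * df,
                 bic = m2ll + n_par * log(n_obs),
                 mu = p[1],
                 male = comp(paths_m), female = comp(paths_f),
                 paths_m = paths_m, paths_f = paths_f,
                 rg = if (model == "full") p[8] else 0.5,
                 k = if (model == "scalar") p[5] else NA_real_,
                 groups = gr, pheno = pheno),
            class = "sexlim_fit")
}

#' @export
print.sexlim_fit <- function(x, ...) {
  cat(sprintf("%s sex-limitation model: -2LL = %.2f, df = %d, BIC = %.2f\n",
              x$model, x$minus2LL, x$df, x$bic))
  cat(sprintf("  males:   a2 = %.3f, c2 = %.3f, e2 = %.3f (V = %.3f)\n",
              x$male$a2, x$male$c2, x$male$e2, x$male$V))
  cat(sprintf("  females: a2 = %.3f, c2 = %.3f, e2 = %.3f (V = %.3f)\n",
              x$female$a2, x$female$c2, x$female$e2, x$female$V))
  if (x$model == "full") cat(sprintf("  rg (DZos) = %.3f\n", x$rg))
  invisible(x)
}

# profile -2LL for one sex-specific standardised component at value t,
# under the full model; the profiled sex uses the spherical split.
.sexlim_profile_m2ll <- function(gr, sex, component, t) {
  obj <- function(p) {
    V <- exp(p[1]); s2 <- sin(p[2])^2
    rest <- (1 - t) * c(s2, 1 - s2)
    props <- switch(component,
                    a2 = c(t, rest[1], rest[2]),
                    c2 = c(rest[1], t, rest[2]),
                    e2 = c(rest[1], rest[2], t))
    prof_paths <- sqrt(V * props)
    other <- p[5:7]
    mu <- p[3]; rg <- p[4]
    if (sex == "M") {
      .sexlim_m2ll_paths(gr, mu, prof_paths[1], prof_paths[2], prof_paths[3],
                         other[1], other[2], other[3], rg)
    } else {
      .sexlim_m2ll_paths(gr, mu, other[1], other[2], other[3],
                         prof_paths[1], prof_paths[2], prof_paths[3], rg)
    }
  }
  start <- c(0, pi / 4, 0, 0.5, sqrt(c(0.3, 0.05, 0.65)))
  lower <- c(-20, 0, -Inf, 0, rep(0, 3))
  upper <- c(20, pi / 2, Inf, 1, rep(Inf, 3))
  .fit_multistart(obj, start, lower, upper, n_restarts = 3)$value
}

#' Profile CI for a per-sex component of a full sex-limitation fit
#'
#' @param fit A `sexlim_fit` of the full model.
#' @param sex `"M"` or `"F"`.
#' @param component `"a2"`, `"c2"` or `"e2"`.
#' @param level Confidence level.
#' @return List with `low`, `high`, `estimate`.
#' @export
sexlim_profile_ci <- function(fit, sex = c("M", "F"),
                              component = c("a2", "c2", "e2"),
                              level = 0.95) {
  stopifnot(inherits(fit, "sexlim_fit"))
  if (fit$model != "full") stop("per-sex CIs are profiled on the full model")
  sex <- match.arg(sex); component <- match.arg(component)
  est <- if (sex == "M") fit$male[[component]] else fit$female[[component]]
  crit <- fit$minus2LL + stats::qchisq(level, 1)
  f <- function(t) .sexlim_profile_m2ll(fit$groups, sex, component, t) - crit
  eps <- 1e-6
  low <- if (est <= eps) 0 else if (f(0) <= 0) 0 else {
    stats::uniroot(f, c(0, est), tol = 1e-3)$root
  }
  high <- if (est >= 1 - eps) 1 else if (f(1 - 1e-9) <= 0) 1 else {
    stats::uniroot(f, c(est, 1 - 1e-9), tol = 1e-3)$root
  }
  list(low = low, high = high, estimate = est)
}

#' Fit and compare all four sex-limitation models
#'
#' Fits full, common-effects, scalar and null models, compares each
#' reduced model against the full model by likelihood ratio, ranks them
#' by AIC and BIC, and renders a verdict on sex differences.
#'
#' @param dataset Twin data frame with a `sex` column.
#' @param pheno Phenotype column name.
#' @param ci Also compute per-sex profile CIs from the full model
#'   (slower; default `FALSE`).
#' @param n_restarts Optimiser restarts per model.
#' @return List with `fits`, `table` (comparison in the usual layout),
#'   `selected` (lowest BIC) and `verdict`.
#' @export
sexlim_decision <- function(dataset, pheno = "pheno", ci = FALSE,
                            n_restarts = 5) {
  models <- c("full", "common", "scalar", "null")
  fits <- lapply(models, function(m) {
    fit_sexlim(dataset, m, pheno = pheno, n_restarts = n_restarts)
  })
  names(fits) <- models
  full <- fits$full
  tab <- do.call(rbind, lapply(fits, function(f) {
    cmp <- if (f$model == "full") list(delta_minus2LL = NA, p_value = NA)
           else compare_models(full, f)
    data.frame(model = f$model, minus2LL = f$minus2LL, df = f$df,
               delta_minus2LL = cmp$delta_minus2LL, p_value = cmp$p_value,
               aic = f$aic, bic = f$bic, n_params = f$n_params,
               stringsAsFactors = FALSE)
  }))
  selected <- tab$model[which.min(tab$bic)]
  verdict <- switch(selected,
    null = "no qualitative, quantitative or variance sex differences",
    scalar = "phenotypic variance differs by sex; same standardised etiology",
    common = "quantitative sex differences in variance components",
    full = "qualitative sex differences (rg for opposite-sex pairs below 0.5)")
  out <- list(fits = fits, table = tab, selected = selected,
              verdict = verdict)
  if (ci) {
    ci_tab <- do.call(rbind, lapply(c("M", "F"), function(s) {
      do.call(rbind, lapply(c("a2", "c2", "e2"), function(cc) {
        b <- sexlim_profile_ci(full, s, cc)
        data.frame(sex = s, component = cc, estimate = b$estimate,
                   ci_low = b$low, ci_high = b$high,
                   stringsAsFactors = FALSE)
      }))
    }))
    out$estimates <- ci_tab
  }
  out
}
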