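# SNP heritability for unrelated individuals: genetic relationship matrix,
# relatedness pruning, and variance-component estimation by REML
# (one EM step followed by average-information updates).

#' Compute the genetic relationship matrix
#'
#' `A_jk = (1 / M_jk) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`,
#' summing over SNPs non-missing in both individuals (`M_jk`). Allele
#' frequencies are estimated from the analysis sample; monomorphic SNPs
#' are excluded. With `mean_impute = TRUE`, missing dosages are replaced
#' by `2 p_i` and all SNPs count in every cell (the convention of common
#' GRM software).
#'
#' @param genotypes A [genotype_matrix()].
#' @param mean_impute Use mean imputation instead of per-pair SNP
#'   intersection for missing genotypes.
#' @return Object of class `grm`: `A` (symmetric N x N), `ids`,
#'   `n_snps` (matrix of per-cell SNP counts), `m` (SNPs used).
#' @export
compute_grm <- function(genotypes, mean_impute = FALSE) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  x <- genotypes$dosages
  p <- colMeans(x, na.rm = TRUE) / 2
  v <- colMeans(x^2, na.rm = TRUE) - colMeans(x, na.rm = TRUE)^2
  poly <- is.finite(p) & p > 0 & p < 1 & v > 0
  if (!any(poly)) stop("all SNPs are monomorphic or constant")
  x <- x[, poly, drop = FALSE]
  p <- p[poly]
  m <- ncol(x)
  z <- sweep(x, 2, 2 * p, "-")
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  miss <- is.na(z)
  if (any(miss)) {
    z[miss] <- 0 # zero contribution == mean imputation on the numerator
    if (mean_impute) {
      n_jk <- matrix(m, nrow(x), nrow(x))
    } else {
      obs <- 1 - miss
      n_jk <- tcrossprod(obs)
    }
  } else {
    n_jk <- matrix(m, nrow(x), nrow(x))
  }
  A <- tcrossprod(z) / n_jk
  dimnames(A) <- list(genotypes$ids, genotypes$ids)
  structure(list(A = A, ids = genotypes$ids, n_snps = n_jk, m = m),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  off <- x$A[upper.tri(x$A)]
  cat(sprintf(
    "grm: %d individuals, %d SNPs; diag mean %.3f, off-diag sd %.4f\n",
    length(x$ids), x$m, mean(diag(x$A)), stats::sd(off)))
  invisible(x)
}

#' Prune related individuals from a GRM
#'
#' Greedily removes one member of every pair whose relatedness exceeds
#' `cutoff` in absolute value (the default 0.025 corresponds to greater
#' relatedness than fourth-degree relatives) until no such pair remains.
#' At each step the individual involved in the most offending pairs is
#' removed; ties break by id order.
#'
#' @param grm A [compute_grm()] result.
#' @param cutoff Absolute relatedness threshold.
#' @return List with `kept` and `removed` id vectors.
#' @export
prune_related <- function(grm, cutoff = 0.025) {
  stopifnot(inherits(grm, "grm"))
  A <- abs(grm$A)
  diag(A) <- 0
  active <- rep(TRUE, nrow(A))
  removed <- character(0)
  repeat {
    off <- A > cutoff & outer(active, active, "&")
    counts <- rowSums(off)
    if (all(counts == 0)) break
    worst <- which(counts == max(counts))[1] # ties: first id in order
    active[worst] <- FALSE
    removed <- c(removed, grm$ids[worst])
  }
  list(kept = grm$ids[active], removed = removed)
}

#' Subset a GRM to a set of individuals
#'
#' @param grm A `grm` object.
#' @param ids Ids to keep, in the order given.
#' @return A `grm` restricted to `ids`.
#' @export
subset_grm <- function(grm, ids) {
  i <- match(ids, grm$ids)
  if (anyNA(i)) stop("unknown ids")
  structure(list(A = grm$A[i, i, drop = FALSE], ids = grm$ids[i],
                 n_snps = grm$n_snps[i, i, drop = FALSE], m = grm$m),
            class = "grm")
}

#' Estimate SNP heritability by REML
#'
#' Fits the random-effects model `y = X beta + g + e` with
#' `cov(g) = sigma_g^2 A` and `cov(e) = sigma_e^2 I` by restricted
#' maximum likelihood: one EM step from the starting values, then
#' average-information (AI) updates until successive restricted
#' log-likelihoods differ by less than `tol`. The heritability is
#' `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)`; its standard error comes
#' from the inverse AI matrix by the delta method. Components are
#' constrained non-negative by default (floored at 1e-6 of the
#' phenotypic variance, as GREML software does); `constrain = FALSE`
#' allows negative components.
#'
#' @param grm A `grm` (typically pruned; see [prune_related()]).
#' @param phenotype Numeric vector aligned with `grm$ids`.
#' @param covariates Optional numeric matrix of fixed covariates (an
#'   intercept is always included).
#' @param constrain Constrain variance components to be non-negative.
#' @param max_iter,tol Convergence controls.
#' @param algorithm `"ai"` (EM first step, AI thereafter) or `"em"`
#'   (EM throughout; slow, for cross-checking).
#' @return Object of class `greml_result`: `h2_snp`, `se`, `sigma_g2`,
#'   `sigma_e2`, `loglik`, `n_iterations`, `converged`, `n`.
#' @export
reml_h2 <- function(grm, phenotype, covariates = NULL, constrain = TRUE,
                    max_iter = 100, tol = 1e-8,
                    algorithm = c("ai", "em")) {
  stopifnot(inherits(grm, "grm"))
  algorithm <- match.arg(algorithm)
  y <- as.numeric(phenotype)
  n <- length(y)
  if (n != length(grm$ids)) stop("phenotype length does not match the GRM")
  if (n < 50) stop("refusing to run REML with fewer than 50 individuals")
  if (stats::var(y) == 0) stop("phenotype variance is zero")
  X <- cbind(`(intercept)` = rep(1, n), covariates)
  A <- grm$A
  vp <- stats::var(y)
  floor_v <- 1e-6 * vp
  theta <- c(g = vp / 2, e = vp / 2)

  reml_parts <- function(theta) {
    V <- theta[1] * A
    diag(V) <- diag(V) + theta[2]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vinv <- chol2inv(ch)
    VinvX <- Vinv %*% X
    XtVinvX <- crossprod(X, VinvX)
    chx <- tryCatch(chol(XtVinvX), error = function(e) NULL)
    if (is.null(chx)) return(NULL)
    P <- Vinv - VinvX %*% chol2inv(chx) %*% t(VinvX)
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                    sum(y * Py))
    list(P = P, Py = Py, ll = ll)
  }

  parts <- reml_parts(theta)
  if (is.null(parts)) stop("initial variance matrix is not positive definite")
  ll_old <- parts$ll
  trace <- data.frame(iter = 0L, sigma_g2 = theta[1], sigma_e2 = theta[2],
                      loglik = ll_old)
  converged <- FALSE
  AI <- NULL
  for (it in seq_len(max_iter)) {
    P <- parts$P; Py <- parts$Py
    APy <- A %*% Py
    if (it == 1 || algorithm == "em") {
      # EM update: theta_i + theta_i^2 (y'P V_i P y - tr(P V_i)) / n
      trPA <- sum(P * A) # tr(PA) for symmetric A
      trP <- sum(diag(P))
      theta_new <- c(
        theta[1] + theta[1]^2 * (sum(Py * APy) - trPA) / n,
        theta[2] + theta[2]^2 * (sum(Py * Py) - trP) / n
      )
    } else {
      trPA <- sum(P * A)
      trP <- sum(diag(P))
      score <- c(-0.5 * (trPA - sum(Py * APy)),
                 -0.5 * (trP - sum(Py * Py)))
      PAPy <- P %*% APy
      PPy <- P %*% Py
      AI <- 0.5 * matrix(c(sum(APy * PAPy), sum(APy * PPy),
                           sum(APy * PPy), sum(Py * PPy)), 2, 2)
      step <- tryCatch(solve(AI, score), error = function(e) NULL)
      if (is.null(step)) break
      theta_new <- theta + step
    }
    if (constrain) theta_new <- pmax(theta_new, floor_v)
    parts_new <- reml_parts(theta_new)
    if (is.null(parts_new)) { # halve the step until feasible
      for (h in 1:10) {
        theta_try <- theta + (theta_new - theta) / 2^h
        if (constrain) theta_try <- pmax(theta_try, floor_v)
        parts_new <- reml_parts(theta_try)
        if (!is.null(parts_new)) { theta_new <- theta_try; break }
      }
      if (is.null(parts_new)) break
    }
    theta <- theta_new
    parts <- parts_new
    trace <- rbind(trace, data.frame(iter = it, sigma_g2 = theta[1],
                                     sigma_e2 = theta[2],
                                     loglik = parts$ll))
    if (abs(parts$ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- parts$ll
  }
  if (!converged && nrow(trace) >= 2 &&
      abs(diff(utils::tail(trace$loglik, 2))) < sqrt(tol)) {
    converged <- TRUE # near-stationary: accept with loose tolerance
  }
  if (!converged) {
    stop("REML did not converge; trace:\n",
         paste(utils::capture.output(print(utils::tail(trace, 5))),
               collapse = "\n"))
  }
  # AI matrix at the optimum for standard errors
  P <- parts$P; Py <- parts$Py
  APy <- A %*% Py
  PAPy <- P %*% APy; PPy <- P %*% Py
  AI <- 0.5 * matrix(c(sum(APy * PAPy), sum(APy * PPy),
                       sum(APy * PPy), sum(Py * PPy)), 2, 2)
  Vcov <- tryCatch(solve(AI), error = function(e) matrix(NA, 2, 2))
  s <- sum(theta)
  grad <- c(theta[2], -theta[1]) / s^2
  se <- sqrt(max(drop(t(grad) %*% Vcov %*% grad), 0))
  structure(list(h2_snp = unname(theta[1] / s), se = se,
                 sigma_g2 = unname(theta[1]), sigma_e2 = unname(theta[2]),
                 var_components_se = sqrt(pmax(diag(Vcov), 0)),
                 loglik = parts$ll, n_iterations = max(trace$iter),
                 converged = converged, n = n, trace = trace),
            class = "greml_result")
}

#' @export
print.greml_result <- function(x, ...) {
  cat(sprintf(
    "GREML: h2_snp = %.3f (SE %.3f), sigma_g2 = %.4f, sigma_e2 = %.4f\n",
    x$h2_snp, x$se, x$sigma_g2, x$sigma_e2))
  cat(sprintf("  n = %d, logL = %.4f, %d iterations, converged = %s\n",
              x$n, x$loglik, x$n_iterations, x$converged))
  invisible(x)
}

#' One-call GREML analysis
#'
#' Builds the GRM, prunes relatives at `cutoff`, and runs [reml_h2()] on
#' the retained individuals.
#'
#' @param genotypes A [genotype_matrix()].
#' @param phenotype Numeric vector aligned with the genotype ids.
#' @param covariates Optional covariate matrix (same order).
#' @param cutoff Relatedness threshold for pruning.
#' @param ... Passed to [reml_h2()].
#' @return A `greml_result` with `n_removed` attached.
#' @export
greml_pipeline <- function(genotypes, phenotype, covariates = NULL,
                           cutoff = 0.025, ...) {
  grm <- compute_grm(genotypes)
  pr <- prune_related(grm, cutoff)
  keep <- match(pr$kept, grm$ids)
  res <- reml_h2(subset_grm(grm, pr$kept), phenotype[keep],
                 covariates = if (is.null(covariates)) NULL
                              else covariates[keep, , drop = FALSE], ...)
  res$n_removed <- length(pr$removed)
  res
}
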