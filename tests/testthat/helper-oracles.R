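# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths.

# Gaussian upper-tail probability by direct numerical integration,
# independent of pnorm/erfc: P(Z > z) for z >= 0.
gauss_tail_integrate <- function(z) {
  stats::integrate(function(t) exp(-t^2 / 2) / sqrt(2 * pi),
                   lower = z, upper = Inf, rel.tol = 1e-12)$value
}

# percent-correct oracle: 1 - tail(d) with d the discriminability
oracle_percent_correct <- function(n1, n2, w) {
  d <- abs(n1 - n2) / (w * sqrt(n1^2 + n2^2))
  1 - gauss_tail_integrate(d)
}

# exhaustive grid search for the Weber least-squares fit
oracle_weber_grid <- function(trials, w_lo = 0.01, w_hi = 2, step = 1e-3) {
  lo <- pmin(trials$n_yellow, trials$n_blue)
  hi <- pmax(trials$n_yellow, trials$n_blue)
  keep <- hi > lo
  key <- paste(lo[keep], hi[keep])
  obs <- tapply(as.numeric(trials$correct[keep]), key, mean)
  wt <- as.numeric(table(key)[names(obs)])
  nn <- do.call(rbind, strsplit(names(obs), " ", fixed = TRUE))
  n1 <- as.numeric(nn[, 1]); n2 <- as.numeric(nn[, 2])
  grid <- seq(w_lo, w_hi, by = step)
  sse <- vapply(grid, function(w) {
    p <- pnorm(abs(n1 - n2) / (w * sqrt(n1^2 + n2^2)))
    sum(wt * (obs - p)^2)
  }, numeric(1))
  grid[which.min(sse)]
}

# Falconer moment estimates from complete-pair correlations
oracle_falconer <- function(dataset, pheno = "pheno") {
  p <- twin_pairs(dataset, pheno)
  rmz <- cor(p$MZ$x1, p$MZ$x2)
  rdz <- cor(p$DZ$x1, p$DZ$x2)
  c(a2 = 2 * (rmz - rdz), c2 = 2 * rdz - rmz)
}

# profiled REML log-likelihood over a fixed h2, maximised over the total
# variance in closed form; independent of the AI-REML iteration
oracle_reml_grid <- function(A, y, h2_grid = seq(0.001, 0.999, by = 0.005)) {
  n <- length(y)
  X <- matrix(1, n, 1)
  ll <- vapply(h2_grid, function(h2) {
    V0 <- h2 * A + diag(1 - h2, n)
    ch <- chol(V0)
    V0inv <- chol2inv(ch)
    V0invX <- V0inv %*% X
    XtV0X <- crossprod(X, V0invX)
    P0 <- V0inv - V0invX %*% solve(XtV0X) %*% t(V0invX)
    yPy <- drop(t(y) %*% P0 %*% y)
    s <- yPy / (n - 1)
    -0.5 * (2 * sum(log(diag(ch))) + log(XtV0X[1, 1]) +
              (n - 1) * log(s) + (n - 1))
  }, numeric(1))
  h2_grid[which.max(ll)]
}

# brute-force minimal vertex cover of a small offense graph
oracle_min_vertex_cover <- function(adj) {
  n <- nrow(adj)
  pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (nrow(pairs) == 0) return(integer(0))
  for (k in 1:n) {
    combos <- utils::combn(n, k)
    for (j in seq_len(ncol(combos))) {
      s <- combos[, j]
      if (all(pairs[, 1] %in% s | pairs[, 2] %in% s)) return(s)
    }
  }
  seq_len(n)
}

# build a grm object directly (bypasses compute_grm)
make_grm <- function(A, ids = sprintf("I%03d", seq_len(nrow(A))), m = 1000) {
  dimnames(A) <- list(ids, ids)
  structure(list(A = A, ids = ids,
                 n_snps = matrix(m, nrow(A), nrow(A)), m = m),
            class = "grm")
}
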