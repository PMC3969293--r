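# GRM construction, relatedness pruning, REML heritability.

test_that("GRM formula: hand-evaluated single-SNP case", {
  # one SNP, dosages {0,2} at p = 0.5: z = (x-1)/sqrt(0.5), so products
  # are exactly +/- 2 ... but frequencies are estimated from the sample
  x <- matrix(c(0L, 2L, 0L, 2L), ncol = 1)
  g <- genotype_matrix(cbind(x, x)) # 2 SNPs so M >= 2 never an issue
  grm <- compute_grm(g)
  # p_hat = 0.5, z in {-sqrt(2), +sqrt(2)}; A_jk = +/-2 (mean over 2 SNPs)
  expect_equal(unname(diag(grm$A)), rep(2, 4))
  expect_equal(grm$A[1, 2], -2)
  expect_equal(grm$A[2, 4], 2)
})

test_that("identical genotype profiles share their diagonal relatedness", {
  set.seed(401)
  panel <- simulate_snp_panel(snp_sim_spec(60, 500, seed = 402))
  x <- panel$genotypes$dosages
  x[60, ] <- x[1, ] # duplicate individual
  grm <- compute_grm(genotype_matrix(x))
  expect_equal(grm$A[1, 60], grm$A[1, 1], tolerance = 1e-12)
  expect_equal(mean(diag(grm$A)), 1, tolerance = 0.02)
})

test_that("off-diagonal scale follows 1/sqrt(M) sampling theory", {
  panel <- simulate_snp_panel(snp_sim_spec(200, 10000, seed = 403))
  grm <- compute_grm(panel$genotypes)
  off <- grm$A[upper.tri(grm$A)]
  # in-sample frequency estimation forces row sums of A towards zero, so
  # the off-diagonal mean sits at ~ -1/(N-1), not at 0
  expect_lt(abs(mean(off) + 1 / 199), 0.002)
  expect_lt(abs(sd(off) - 1 / sqrt(10000)) / (1 / sqrt(10000)), 0.15)
})

test_that("monomorphic SNPs are excluded; all-monomorphic errors", {
  set.seed(400)
  x <- cbind(rep(1L, 10), rbinom(10, 2, 0.4))
  g <- genotype_matrix(x)
  expect_identical(compute_grm(g)$m, 1L)
  g0 <- genotype_matrix(cbind(rep(2L, 10), rep(0L, 10)))
  expect_error(compute_grm(g0), "monomorphic")
})

test_that("missing genotypes: pairwise intersection vs mean imputation", {
  set.seed(404)
  x <- matrix(rbinom(50 * 40, 2, 0.3), 50, 40)
  x[sample(length(x), 100)] <- NA
  g <- genotype_matrix(x)
  grm_int <- compute_grm(g)
  grm_imp <- compute_grm(g, mean_impute = TRUE)
  expect_true(all(grm_int$n_snps <= 40))
  expect_true(all(grm_imp$n_snps == grm_imp$m))
  # both agree where a pair has no missing genotypes at all
  full_pairs <- grm_int$n_snps == grm_int$m
  expect_equal(grm_int$A[full_pairs], grm_imp$A[full_pairs],
               tolerance = 1e-12)
})

test_that("GRM permutation invariance", {
  panel <- simulate_snp_panel(snp_sim_spec(40, 300, seed = 405))
  grm <- compute_grm(panel$genotypes)
  perm <- sample(40)
  x2 <- panel$genotypes$dosages[perm, ]
  grm2 <- compute_grm(genotype_matrix(x2, ids = panel$genotypes$ids[perm]))
  expect_equal(unname(grm2$A), unname(grm$A[perm, perm]), tolerance = 1e-12)
})

test_that("pruning removes a minimal set of relatives", {
  # clean panel: nobody removed
  n <- 30
  A <- diag(n) + matrix(rnorm(n * n, 0, 0.005), n, n)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  grm <- make_grm(A)
  pr <- prune_related(grm, 0.025)
  expect_length(pr$removed, 0)

  # one duplicated individual: exactly one of the two goes
  A2 <- A
  A2[1, 2] <- A2[2, 1] <- 0.98
  pr <- prune_related(make_grm(A2), 0.025)
  expect_length(pr$removed, 1)
  expect_true(pr$removed %in% c("I001", "I002"))

  # planted trio of mutual relatives at A ~ 0.5: minimal cover is 2
  A3 <- A
  for (i in 1:3) for (j in 1:3) if (i != j) A3[i, j] <- 0.5
  pr <- prune_related(make_grm(A3), 0.025)
  expect_length(pr$removed, 2)
  cover <- oracle_min_vertex_cover(abs(A3 - diag(diag(A3))) > 0.025)
  expect_length(pr$removed, length(cover))
})

test_that("REML recovers heritability and matches the grid oracle", {
  panel <- simulate_snp_panel(snp_sim_spec(800, 3000, h2_snp = 0.3,
                                           n_causal = 600, seed = 406))
  grm <- compute_grm(panel$genotypes)
  res <- reml_h2(grm, panel$phenotype)
  expect_true(res$converged)
  expect_lt(abs(res$h2_snp - 0.3), 0.12) # single replicate
  h2_grid <- oracle_reml_grid(grm$A, panel$phenotype)
  expect_lt(abs(res$h2_snp - h2_grid), 0.005)
})

test_that("REML limits: pure genetic signal and pure noise", {
  panel <- simulate_snp_panel(snp_sim_spec(400, 800, h2_snp = 1,
                                           n_causal = 800, seed = 407))
  res <- reml_h2(compute_grm(panel$genotypes), panel$phenotype)
  expect_gt(res$h2_snp, 0.95)

  panel <- simulate_snp_panel(snp_sim_spec(400, 800, h2_snp = 0,
                                           n_causal = 0, seed = 408))
  res0 <- reml_h2(compute_grm(panel$genotypes), panel$phenotype)
  expect_lt(res0$h2_snp, 2 * res0$se + 1e-9)
})

test_that("REML invariances and guards", {
  panel <- simulate_snp_panel(snp_sim_spec(300, 600, h2_snp = 0.4,
                                           n_causal = 200, seed = 409))
  grm <- compute_grm(panel$genotypes)
  r1 <- reml_h2(grm, panel$phenotype)
  r5 <- reml_h2(grm, 5 * panel$phenotype)
  expect_equal(r1$h2_snp, r5$h2_snp, tolerance = 1e-5)
  expect_equal(5^2 * r1$sigma_g2, r5$sigma_g2, tolerance = 1e-3)

  expect_error(reml_h2(grm, panel$phenotype[1:10]), "match")
  small <- subset_grm(grm, grm$ids[1:40])
  expect_error(reml_h2(small, panel$phenotype[1:40]), "fewer than 50")
  expect_error(reml_h2(grm, rep(1, 300)), "variance")
})

test_that("SE decreases with sample size at fixed marker count", {
  ses <- vapply(c(300, 600, 1200), function(n) {
    panel <- simulate_snp_panel(snp_sim_spec(n, 2000, h2_snp = 0.3,
                                             n_causal = 500,
                                             seed = 410 + n))
    reml_h2(compute_grm(panel$genotypes), panel$phenotype)$se
  }, numeric(1))
  expect_true(all(diff(ses) < 0))
})

test_that("EM-only and AI iterations reach the same optimum", {
  panel <- simulate_snp_panel(snp_sim_spec(150, 500, h2_snp = 0.5,
                                           n_causal = 100, seed = 411))
  grm <- compute_grm(panel$genotypes)
  ai <- reml_h2(grm, panel$phenotype, algorithm = "ai")
  em <- reml_h2(grm, panel$phenotype, algorithm = "em", max_iter = 5000,
                tol = 1e-10)
  expect_equal(ai$h2_snp, em$h2_snp, tolerance = 1e-4)
  expect_equal(ai$loglik, em$loglik, tolerance = 1e-6)
})

test_that("greml_pipeline prunes planted relatives before REML", {
  panel <- simulate_snp_panel(snp_sim_spec(120, 4000, h2_snp = 0,
                                           n_causal = 0, seed = 412))
  x <- panel$genotypes$dosages
  x[2, ] <- x[1, ] # plant a duplicate pair
  res <- greml_pipeline(genotype_matrix(x), panel$phenotype, cutoff = 0.2)
  expect_identical(res$n_removed, 1L)
  expect_identical(res$n, 119L)
})
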