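# Generators: twin phenotypes, task sessions, SNP panels.

test_that("twin spec validation names the offending field", {
  expect_error(twin_sim_spec(a2_m = 0.5, c2_m = 0.2, e2_m = 0.5),
               "a2_m \\+ c2_m \\+ e2_m")
  expect_error(twin_sim_spec(a2_m = -0.1, c2_m = 0.4, e2_m = 0.7), "a2_m")
  expect_error(twin_sim_spec(rg_os = 1.5), "rg_os")
  expect_error(twin_sim_spec(missing_rate = 1), "missing_rate")
})

test_that("twin generator is seed-deterministic", {
  spec <- twin_sim_spec(seed = 5)
  d1 <- simulate_twin_dataset(spec)
  d2 <- simulate_twin_dataset(spec)
  expect_identical(d1, d2)
  d3 <- simulate_twin_dataset(twin_sim_spec(seed = 6))
  expect_false(identical(d1$pheno, d3$pheno))
})

test_that("pure-A MZ co-twins are identical; pure-E twins are uncorrelated", {
  spec <- twin_sim_spec(a2_m = 1, c2_m = 0, e2_m = 0,
                        a2_f = 1, c2_f = 0, e2_f = 0,
                        n_pairs_by_group = c(MZm = 50, MZf = 50, DZm = 1,
                                             DZf = 1, DZos = 1),
                        missing_rate = 0, seed = 1)
  d <- simulate_twin_dataset(spec)
  p <- twin_pairs(d)
  expect_equal(p$MZ$x1, p$MZ$x2, tolerance = 1e-12)

  spec <- twin_sim_spec(a2_m = 0, c2_m = 0, e2_m = 1,
                        a2_f = 0, c2_f = 0, e2_f = 1,
                        n_pairs_by_group = c(MZm = 5000, MZf = 5000,
                                             DZm = 5000, DZf = 5000,
                                             DZos = 0),
                        missing_rate = 0, seed = 2)
  p <- twin_pairs(simulate_twin_dataset(spec))
  expect_lt(abs(cor(p$MZ$x1, p$MZ$x2)), 0.05)
  expect_lt(abs(cor(p$DZ$x1, p$DZ$x2)), 0.05)
})

test_that("empirical pair correlations converge to the implied ACE values", {
  spec <- twin_sim_spec(a2_m = 0.35, c2_m = 0, e2_m = 0.65,
                        a2_f = 0.35, c2_f = 0, e2_f = 0.65,
                        n_pairs_by_group = c(MZm = 5000, MZf = 5000,
                                             DZm = 5000, DZf = 5000,
                                             DZos = 0),
                        missing_rate = 0, seed = 3)
  p <- twin_pairs(simulate_twin_dataset(spec))
  expect_lt(abs(cor(p$MZ$x1, p$MZ$x2) - 0.35), 0.02)
  expect_lt(abs(cor(p$DZ$x1, p$DZ$x2) - 0.175), 0.02)

  # a C-loaded world, including opposite-sex pairs with reduced rg
  spec <- twin_sim_spec(a2_m = 0.4, c2_m = 0.3, e2_m = 0.3,
                        a2_f = 0.4, c2_f = 0.3, e2_f = 0.3,
                        rg_os = 0.2,
                        n_pairs_by_group = c(MZm = 10000, MZf = 10000,
                                             DZm = 10000, DZf = 10000,
                                             DZos = 20000),
                        missing_rate = 0, seed = 4)
  d <- simulate_twin_dataset(spec)
  implied <- implied_twin_correlations(spec)
  g <- sexlim_groups(d)
  for (nm in c("MZm", "DZf", "DZos")) {
    expect_lt(abs(cor(g[[nm]]$x1, g[[nm]]$x2) - implied[nm]), 0.02)
  }
})

test_that("missingness creates singletons at the requested rate", {
  spec <- twin_sim_spec(missing_rate = 0.13, seed = 9)
  d <- simulate_twin_dataset(spec)
  n_fam <- length(unique(d$family_id))
  n_single <- sum(tapply(!is.na(d$pheno), d$family_id, sum) == 1)
  expect_lt(abs(n_single / n_fam - 0.13), 0.03)
  # ages identical within pair, zygosity/sex structure intact
  expect_true(all(tapply(d$age, d$family_id, function(a) a[1] == a[2])))
  os <- d[d$group == "DZos", ]
  expect_true(all(os$sex[os$twin == 1] == "M"))
  expect_true(all(os$sex[os$twin == 2] == "F"))
})

test_that("session generator matches the analytic psychometric curve", {
  spec <- task_sim_spec(n_trials = 10000, seed = 12)
  tr <- simulate_session(0.25, spec)
  key <- paste(pmin(tr$n_yellow, tr$n_blue), pmax(tr$n_yellow, tr$n_blue))
  obs <- tapply(as.numeric(tr$correct), key, mean)
  n_b <- table(key)[names(obs)]
  for (b in names(obs)) {
    nn <- as.numeric(strsplit(b, " ")[[1]])
    p <- predict_percent_correct(nn[1], nn[2], 0.25)
    # 3.3 binomial SEs
    expect_lt(abs(obs[[b]] - p), 3.3 * sqrt(p * (1 - p) / n_b[[b]]) + 1e-9)
  }
})

test_that("session generator honours degenerate limits and determinism", {
  spec <- task_sim_spec(n_trials = 400, seed = 13)
  tr <- simulate_session(1e-9, spec)
  expect_true(all(tr$correct))

  ties <- task_sim_spec(n_trials = 10000,
                        ratio_schedule = data.frame(n_small = 8, n_large = 8),
                        seed = 14)
  tr <- simulate_session(0.3, ties)
  expect_equal(mean(tr$correct), 0.5, tolerance = 0.02)

  expect_error(simulate_session(-1, spec), "positive")

  spec <- task_sim_spec(seed = 15)
  expect_identical(simulate_session(0.3, spec), simulate_session(0.3, spec))
})

test_that("population Weber draws match the target moments", {
  spec <- task_sim_spec(n_trials = 1, seed = 16)
  pop <- simulate_population_sessions(spec, 2000)
  expect_lt(abs(mean(pop$truth$w_true) - 0.28), 0.02)
  expect_lt(abs(sd(pop$truth$w_true) - 0.13), 0.02)
  expect_true(all(pop$truth$w_true >= 0.10 & pop$truth$w_true <= 0.99))

  expect_identical(simulate_population_sessions(spec, 0)$trials,
                   data.frame())
  pop2 <- simulate_population_sessions(spec, 2000)
  expect_identical(pop$trials, pop2$trials)

  bad <- task_sim_spec(w_mean = 2, w_sd = 0.1, seed = 17)
  expect_error(simulate_population_sessions(bad, 5), "truncation")
})

test_that("SNP spec validation and degenerate heritabilities", {
  expect_error(snp_sim_spec(100, 50, h2_snp = 1.2), "h2_snp")
  expect_error(snp_sim_spec(100, 50, n_causal = 60), "n_causal")
  expect_error(snp_sim_spec(100, 50, maf_range = c(0, 0.5)), "maf_range")

  # h2 = 0: phenotype independent of any single SNP
  panel <- simulate_snp_panel(snp_sim_spec(2000, 50, h2_snp = 0,
                                           n_causal = 50, seed = 18))
  cors <- abs(cor(panel$phenotype, panel$genotypes$dosages))
  expect_lt(max(cors), 0.08)
  expect_equal(var(panel$phenotype), 1, tolerance = 0.05)

  # h2 = 1 with all SNPs causal: phenotype is exactly the genetic value
  panel <- simulate_snp_panel(snp_sim_spec(500, 100, h2_snp = 1,
                                           n_causal = 100, seed = 19))
  expect_identical(panel$phenotype, panel$genetic_value)
  expect_equal(var(panel$phenotype), 1, tolerance = 0.05)
})

test_that("SNP panel is deterministic and respects the MAF window", {
  spec <- snp_sim_spec(200, 300, maf_range = c(0.1, 0.3), h2_snp = 0.5,
                       n_causal = 30, seed = 20)
  p1 <- simulate_snp_panel(spec)
  p2 <- simulate_snp_panel(spec)
  expect_identical(p1$genotypes$dosages, p2$genotypes$dosages)
  expect_identical(p1$phenotype, p2$phenotype)
  expect_true(all(p1$genotypes$freq > 0.02 & p1$genotypes$freq < 0.42))
  expect_identical(sort(unique(as.vector(p1$genotypes$dosages))), c(0L, 1L, 2L))
})
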