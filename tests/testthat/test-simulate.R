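test_that("identical config and seed give bitwise-identical output", {
  cfg <- simConfig(n_cpg_clusters = 30L, n_true_dmrs = 3L,
                   samples_per_group = c(WT = 2L, `3aKO` = 2L), seed = 5L)
  s1 <- simulateMethylome(cfg)
  s2 <- simulateMethylome(cfg)
  expect_identical(methCounts(s1$methylome), methCounts(s2$methylome))
  expect_identical(readDepth(s1$methylome), readDepth(s2$methylome))
  expect_identical(as.data.frame(s1$truth$true_dmr_intervals),
                   as.data.frame(s2$truth$true_dmr_intervals))
  j1 <- simulateJunctionCounts(seed = 4L)
  j2 <- simulateJunctionCounts(seed = 4L)
  expect_identical(j1, j2)
  p1 <- simulatePSMTable(n_proteins = 10L, seed = 4L)
  p2 <- simulatePSMTable(n_proteins = 10L, seed = 4L)
  expect_identical(p1$psm, p2$psm)
})

test_that("null config: empty truth, group differences are noise only", {
  cfg <- simConfig(n_cpg_clusters = 60L, n_true_dmrs = 0L,
                   samples_per_group = c(WT = 3L, `3aKO` = 3L), seed = 2L)
  sim <- simulateMethylome(cfg)
  expect_length(sim$truth$true_dmr_intervals, 0L)
  sig <- groupMeanBetas(sim$methylome, "WT", "3aKO")
  expect_lt(abs(mean(sig$diff, na.rm = TRUE)), 0.01)
})

test_that("planted effect is recovered exactly at extreme depth (LLN)", {
  cfg <- simConfig(n_cpg_clusters = 12L, n_true_dmrs = 1L,
                   dmr_effect_by_genotype = c(`3aKO` = 0.4),
                   mean_depth = 1e6, depth_dispersion = 0,
                   beta_binomial_rho = 0,
                   samples_per_group = c(WT = 2L, `3aKO` = 2L), seed = 3L)
  sim <- simulateMethylome(cfg)
  sig <- groupMeanBetas(sim$methylome, "WT", "3aKO")
  in_dmr <- countOverlaps(rowRanges(sim$methylome),
                          sim$truth$true_dmr_intervals) > 0
  expect_equal(mean(sig$diff[in_dmr]), 0.4, tolerance = 1e-2)
  ## truth intervals are exactly the loci where group mu differs
  expect_identical(which(abs(sig$diff) > 0.2), which(in_dmr))
})

test_that("empirical mean depth is within 5% of the 18.6x target", {
  sim <- simulateMethylome(simConfig(n_cpg_clusters = 100L,
                                     n_true_dmrs = 10L, seed = 8L))
  expect_lt(abs(mean(readDepth(sim$methylome)) - 18.6) / 18.6, 0.05)
})

test_that("beta-binomial draws match theoretical mean and variance", {
  set.seed(10)
  d <- 20L; mu <- 0.3; rho <- 0.1; n <- 1e4
  x <- remethylome:::rbetabinom(n, d, mu, rho)
  v_theory <- d * mu * (1 - mu) * (1 + (d - 1) * rho)
  expect_equal(mean(x), d * mu, tolerance = 4 * sqrt(v_theory / n) / (d * mu))
  expect_equal(var(x), v_theory, tolerance = 0.1)
  ## rho = 0 reduces to binomial variance
  y <- remethylome:::rbetabinom(n, d, mu, 0)
  expect_equal(var(y), d * mu * (1 - mu), tolerance = 0.1)
})

test_that("addback endpoints and midpoint behave as designed", {
  cfg <- simConfig(n_cpg_clusters = 12L, n_true_dmrs = 2L,
                   dmr_effect_by_genotype = c(`3aKO` = 0.4),
                   mean_depth = 1e4, depth_dispersion = 0,
                   beta_binomial_rho = 0,
                   samples_per_group = c(WT = 2L, `3aKO` = 2L), seed = 6L)
  sim <- simulateMethylome(cfg)
  geno <- sampleGroups(sim$methylome)
  in_dmr <- countOverlaps(rowRanges(sim$methylome),
                          sim$truth$true_dmr_intervals) > 0
  beta <- betaValues(sim$methylome)
  wt <- mean(beta[in_dmr, geno == "WT"])
  ko <- mean(beta[in_dmr, geno == "3aKO"])
  for (lev in c(0, 0.5, 1)) {
    ab <- simulateAddback(sim$methylome, sim$truth, lev, "ab", seed = 9L)
    abm <- mean(betaValues(ab)[in_dmr, ])
    expect_equal(abm, ko + lev * (wt - ko), tolerance = 0.02)
  }
  expect_error(simulateAddback(sim$methylome, sim$truth, 1, "x", 1L,
                               ko_genotype = "nosuch"),
               "unknown genotype")
})

test_that("floxing dropout: efficiency 1 zeroes depth, 0 leaves it alone", {
  sim <- simulateMethylome(simConfig(n_cpg_clusters = 40L,
                                     n_true_dmrs = 4L, seed = 12L,
                                     samples_per_group = c(WT = 3L)))
  flox <- sim$truth$floxed_intervals
  idx <- countOverlaps(rowRanges(sim$methylome), flox) > 0
  full <- simulateFloxedCoverage(sim$methylome, flox, 1, seed = 2L)
  expect_true(all(readDepth(full)[idx, ] == 0))
  none <- simulateFloxedCoverage(sim$methylome, flox, 0, seed = 2L)
  expect_identical(readDepth(none), readDepth(sim$methylome))
  expect_error(simulateFloxedCoverage(
    sim$methylome, GRanges("chrS", IRanges(1e9, 1e9 + 10)), 0.5, 1L),
    "outside")
})

test_that("junction simulator hits the target usage at extreme depth", {
  m <- isoformModel("Dnmt3a1", "e6_e7", "utr_e7")
  jc <- simulateJunctionCounts(c(WT = 1, R878H = 1),
                               junction_depth = 100L,
                               n_samples = c(WT = 2L, R878H = 2L),
                               model = m, seed = 1L)
  inc <- jc$count[jc$junction_id == "e6_e7"]
  alt <- jc$count[jc$junction_id == "utr_e7"]
  expect_true(all(inc == 100L) && all(alt == 0L))
  jc2 <- simulateJunctionCounts(c(WT = 0.886, R878H = 0.886),
                                junction_depth = 1e6L,
                                n_samples = c(WT = 3L, R878H = 3L),
                                model = m, seed = 2L)
  u <- isoformPercentage(jc2, m)
  expect_equal(unname(mean(u)), 0.886, tolerance = 1e-3)
})
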