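test_that("passive methylation: forced means, missing DMRs, brute-force oracle", {
  me <- tiny_methylome()
  ## one DMR over the first two CpGs of sample B1 (betas 0.2, 0.2)
  d <- tiny_dmrs(starts = c(101, 3001), ends = c(160, 3100))
  pm <- passiveMethylation(d, me)
  bv <- betaValues(me)
  expect_equal(pm[1, "B1"], mean(bv[1:2, "B1"]))
  expect_true(all(is.na(pm[2, ])))         # DMR outside the methylome

  set.seed(11)
  sim <- simulateMethylome(simConfig(n_cpg_clusters = 40L, n_true_dmrs = 4L,
                                     samples_per_group = c(WT = 3L,
                                                           `3aKO` = 3L),
                                     seed = 14L))
  dd <- callDMRs(sim$methylome, "WT", "3aKO")
  pm <- passiveMethylation(dd, sim$methylome)
  bv <- betaValues(sim$methylome)
  pos <- GenomicRanges::start(rowRanges(sim$methylome))
  for (i in seq_along(dd)) {             # brute-force re-scan
    rows <- which(pos >= GenomicRanges::start(dd)[i] &
                    pos <= GenomicRanges::end(dd)[i])
    expect_equal(pm[i, ], colMeans(bv[rows, , drop = FALSE], na.rm = TRUE),
                 tolerance = 1e-12)
  }
  ## depth weighting equals pooled-count ratio
  pmd <- passiveMethylation(dd, sim$methylome, weighting = "depth")
  rows <- which(pos >= GenomicRanges::start(dd)[1] &
                  pos <= GenomicRanges::end(dd)[1])
  expect_equal(pmd[1, ],
               colSums(methCounts(sim$methylome)[rows, ]) /
                 colSums(readDepth(sim$methylome)[rows, ]),
               tolerance = 1e-12)
})

test_that("unified DMR set: identity, forced union, order invariance", {
  one <- tiny_dmrs()
  expect_identical(unifiedDMRSet(list(one)), one)

  s1 <- tiny_dmrs(starts = 101, ends = 200, direction = "hypo",
                  label = "c1")
  s2 <- tiny_dmrs(starts = 151, ends = 250, direction = "hypo",
                  label = "c2")
  u <- unifiedDMRSet(list(s1, s2))
  expect_length(u, 1L)
  expect_identical(GenomicRanges::start(u), 101L)
  expect_identical(GenomicRanges::end(u), 250L)
  expect_identical(mcols(u)$sources, "c1,c2")

  sets <- list(random_dmrs(8, 1, "a"), random_dmrs(8, 2, "b"),
               random_dmrs(8, 3, "c"))
  u1 <- unifiedDMRSet(sets)
  u2 <- unifiedDMRSet(sets[c(3, 1, 2)])
  expect_equal(as.data.frame(u1), as.data.frame(u2))
  expect_lte(length(u1), sum(lengths(sets)))
  expect_gte(sum(GenomicRanges::width(u1)),
             max(vapply(sets, function(s) sum(GenomicRanges::width(s)),
                        numeric(1))))
})

test_that("canyon profile: flat genome is flat, planted canyon dips by the effect", {
  sim <- simulateMethylome(simConfig(
    genome_length = 9e4, n_cpg_clusters = 60L, n_true_dmrs = 6L,
    baseline_beta_by_class = c(open_sea = 0.8),
    dmr_effect_by_genotype = c(`3aKO` = 0.4),
    mean_depth = 500, beta_binomial_rho = 0,
    samples_per_group = c(WT = 3L, `3aKO` = 3L),
    seed = 21L))
  d <- callDMRs(sim$methylome, "WT", "3aKO")
  cp <- canyonProfile(d, sim$methylome, flank = 1000L)
  wt <- cp[cp$genotype == "WT", ]
  ko <- cp[cp$genotype == "3aKO", ]
  expect_true(all(abs(wt$mean_beta - 0.8) < 0.05))
  body_bins <- ko$bin_type == "body"
  expect_true(all(abs(ko$mean_beta[body_bins] - 0.4) < 0.05))
  flank_bins <- ko$bin_type != "body"
  expect_true(mean(abs(ko$mean_beta[flank_bins] - 0.8) < 0.1) > 0.8)

  ## conservation: every CpG occurrence lands in exactly one bin
  win <- GenomicRanges::resize(granges(d), GenomicRanges::width(d) + 2000L,
                               fix = "center")
  n_occ <- sum(GenomicRanges::countOverlaps(rowRanges(sim$methylome), win))
  expect_identical(sum(wt$n) / 3L, as.numeric(n_occ))  # 3 WT samples
})

test_that("annotation summary matches global means and a brute-force scan", {
  me <- tiny_methylome()
  all_cls <- annotationTrack(GRanges("chr1", IRanges(1, 10000)), "everything")
  s <- annotationSummary(me, all_cls)
  expect_equal(s["everything", ], colMeans(betaValues(me)), tolerance = 1e-12)

  two <- annotationTrack(GRanges("chr1", IRanges(c(1, 900), c(400, 1200))),
                         c("cpg_island", "shore"))
  s2 <- annotationSummary(me, two)
  bv <- betaValues(me)
  expect_equal(s2["cpg_island", ], colMeans(bv[1:3, ]), tolerance = 1e-12)
  expect_equal(s2["shore", ], colMeans(bv[4:5, ]), tolerance = 1e-12)

  empty <- annotationTrack(GRanges("chr1", IRanges(9000, 9100)), "desert")
  expect_true(all(is.na(suppressMessages(
    annotationSummary(me, empty))["desert", ])))

  restricted <- annotationSummary(me, all_cls, restrict_to = tiny_dmrs(
    starts = 101, ends = 160, direction = "hypo"))
  expect_equal(restricted["everything", ], colMeans(bv[1:2, ]),
               tolerance = 1e-12)
})

test_that("floxing efficiency: exact endpoints and error on zero control", {
  me <- tiny_methylome()
  flox <- GRanges("chr1", IRanges(101, 210))      # first three CpGs
  d <- readDepth(me)
  d[1:3, ] <- 0L
  m <- methCounts(me); m[1:3, ] <- 0L
  gone <- CpGMethylome(rowRanges(me), m, d,
                       as.data.frame(SummarizedExperiment::colData(me)))
  ctrl <- GRanges("chr1", IRanges(900, 1200))
  expect_equal(unname(floxingEfficiency(gone, flox, ctrl)), rep(1, 4))
  expect_equal(unname(floxingEfficiency(me, flox, ctrl)), rep(0, 4))
  d[4:5, ] <- 0L
  zero_ctrl <- CpGMethylome(rowRanges(me), m, d,
                            as.data.frame(SummarizedExperiment::colData(me)))
  expect_error(floxingEfficiency(zero_ctrl, flox, ctrl), "zero control")
})

test_that("severity ordering is reproduced on the default simulation", {
  sim <- simulateMethylome(simConfig(n_cpg_clusters = 150L,
                                     n_true_dmrs = 20L, seed = 33L))
  d <- callDMRs(sim$methylome, "WT", "3aKO")
  pm <- passiveMethylation(d, sim$methylome)
  geno <- sampleGroups(sim$methylome)
  m <- vapply(c("WT", "3bKO", "R878H", "3aKO", "DKO"),
              function(g) mean(pm[, geno == g], na.rm = TRUE), numeric(1))
  expect_true(m["WT"] > m["3bKO"] && m["3bKO"] >= m["R878H"] &&
                m["R878H"] > m["3aKO"] && m["3aKO"] > m["DKO"])
  ## >= 99% of called DMRs are hypomethylated when only loss is planted
  expect_gte(mean(mcols(d)$direction == "hypo"), 0.99)
})
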