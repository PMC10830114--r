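## Helper: build a single-chromosome methylome from a beta matrix at
## fixed depth (exact counts, no noise).
beta_methylome <- function(beta, depth = 100L, spacing = 30L,
                           groups = rep(c("WT", "KO"), each = ncol(beta) / 2)) {
  n <- nrow(beta)
  gr <- GRanges("chr1", IRanges(start = seq(101, by = spacing, length.out = n),
                                width = 2))
  d <- matrix(depth, n, ncol(beta))
  m <- round(beta * d)
  storage.mode(m) <- "integer"
  ids <- sprintf("%s_%d", groups, ave(seq_along(groups), groups,
                                      FUN = seq_along))
  colnames(m) <- colnames(d) <- ids
  CpGMethylome(gr, m, d, data.frame(genotype = groups, group = groups,
                                    row.names = ids))
}

test_that("group mean betas match a brute-force recomputation", {
  set.seed(4)
  beta <- matrix(runif(6 * 30), 30, 6)
  me <- beta_methylome(beta, depth = 1000L,
                       groups = rep(c("WT", "KO"), each = 3))
  sig <- groupMeanBetas(me, "WT", "KO")
  bv <- betaValues(me)
  for (i in seq_len(nrow(beta))) {
    expect_equal(sig$mean_A[i], mean(bv[i, 1:3]), tolerance = 1e-12)
    expect_equal(sig$diff[i], mean(bv[i, 1:3]) - mean(bv[i, 4:6]),
                 tolerance = 1e-12)
  }
  expect_equal(groupMeanBetas(me, "WT", "KO")$mean_A[1],
               mean(c(beta[1, 1:3])), tolerance = 1e-3)
  expect_error(groupMeanBetas(me, character(0), "KO"), "empty|unknown")
})

test_that("CpGs uncovered in a whole group are flagged missing", {
  me <- tiny_methylome()
  d <- readDepth(me)
  d[2, c("B1", "B2")] <- 0L
  m <- methCounts(me); m[2, c("B1", "B2")] <- 0L
  me2 <- CpGMethylome(rowRanges(me), m, d,
                      as.data.frame(SummarizedExperiment::colData(me)))
  sig <- groupMeanBetas(me2, "WT", "KO")
  expect_true(sig$missing[2])
  expect_false(any(sig$missing[-2]))
})

test_that("segmentation: constant signal stays whole, planted block is cut out exactly", {
  sig <- data.frame(chrom = "chr1", pos = seq(101, by = 30, length.out = 30),
                    diff = rep(0.3, 30))
  cand <- segmentCandidates(sig, dmrParams())
  expect_identical(nrow(cand), 1L)
  expect_identical(c(cand$from, cand$to), c(1L, 30L))

  sig$diff <- c(rep(0, 10), rep(0.4, 10), rep(0, 10))
  cand <- segmentCandidates(sig, dmrParams())
  expect_true(any(cand$from == 11 & cand$to == 20))
  ## exhaustive-search oracle: the contiguous segment (>= 10 CpGs)
  ## maximizing |segment mean| is exactly 11..20
  best <- c(0, 0, -1)
  for (i in 1:21) for (j in (i + 9):30) {
    m <- abs(mean(sig$diff[i:j]))
    if (m > best[3]) best <- c(i, j, m)
  }
  expect_identical(best[1:2], c(11, 20))

  ## isolated CpGs (every gap > max_cpg_spacing) form runs below min_cpg
  sig2 <- data.frame(chrom = "chr1",
                     pos = seq(101, by = 500, length.out = 30),
                     diff = rep(0.4, 30))
  expect_identical(nrow(segmentCandidates(sig2, dmrParams())), 0L)
})

test_that("segment test matches an exact permutation oracle and handles ties", {
  expect_identical(testSegment(rep(0.5, 8), rep(0.5, 6)), 1)
  expect_lt(testSegment(rep(0.9, 20), rep(0.1, 20)), 1e-6)

  set.seed(7)
  a <- round(runif(4), 3); b <- round(runif(3), 3) + 1e-4  # distinct values
  p_obs <- testSegment(a, b)
  ## enumerate all assignments of the pooled values to group A
  pooled <- c(a, b)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  combos <- combn(7, 4)
  u_all <- apply(combos, 2, function(ii)
    u_stat(pooled[ii], pooled[-ii]))
  u0 <- u_stat(a, b)
  mu <- 4 * 3 / 2
  p_exact <- min(1, 2 * min(mean(u_all <= u0 + 1e-9),
                            mean(u_all >= u0 - 1e-9)))
  expect_equal(p_obs, p_exact, tolerance = 1e-9)
})

test_that("the minimum-CpG filter is enforced at the boundary", {
  ## one cluster with a huge effect: 9 CpGs -> rejected, 10 -> called
  for (n in c(9L, 10L)) {
    beta <- matrix(0.8, n, 8)
    beta[, 5:8] <- 0.2
    me <- beta_methylome(beta, depth = 50L,
                         groups = rep(c("WT", "KO"), each = 4))
    d <- callDMRs(me, "WT", "KO")
    expect_identical(length(d), as.integer(n == 10L))
    if (length(d)) {
      expect_identical(mcols(d)$n_cpg, 10L)
      expect_identical(mcols(d)$direction, "hypo")
      expect_equal(mcols(d)$diff, 0.6, tolerance = 1e-12)
    }
  }
})

test_that("every emitted DMR satisfies all filters; q >= p and monotone", {
  sim <- simulateMethylome(simConfig(n_cpg_clusters = 80L, n_true_dmrs = 8L,
                                     samples_per_group = c(WT = 4L,
                                                           `3aKO` = 4L),
                                     seed = 31L))
  params <- dmrParams()
  d <- callDMRs(sim$methylome, "WT", "3aKO", params)
  expect_gt(length(d), 0L)
  mc <- mcols(d)
  expect_true(all(mc$n_cpg >= params$min_cpg))
  expect_true(all(abs(mc$diff) >= params$min_diff))
  expect_true(all(mc$q_value < params$max_q))
  expect_true(all(mc$q_value >= mc$p_value))
  o <- order(mc$p_value)
  expect_true(all(diff(mc$q_value[o]) >= -1e-12))
})

test_that("calls are invariant under sample-order permutation within groups", {
  sim <- simulateMethylome(simConfig(n_cpg_clusters = 50L, n_true_dmrs = 5L,
                                     samples_per_group = c(WT = 4L,
                                                           `3aKO` = 3L),
                                     seed = 17L))
  ids <- colnames(sim$methylome)
  wt <- ids[startsWith(ids, "WT")]
  ko <- ids[startsWith(ids, "3aKO")]
  d1 <- callDMRs(sim$methylome, wt, ko)
  d2 <- callDMRs(sim$methylome, rev(wt), sample(ko))
  expect_equal(as.data.frame(d1), as.data.frame(d2))
})

test_that("adjacent same-direction DMRs merge by the 50-bp rule", {
  ## 0-based [100,200) and [240,300): gap 40 <= 50 -> one DMR [100,300)
  d <- tiny_dmrs(starts = c(101, 241), ends = c(200, 300))
  m <- mergeAdjacent(d, 50L)
  expect_length(m, 1L)
  expect_identical(GenomicRanges::start(m), 101L)
  expect_identical(GenomicRanges::end(m), 300L)
  expect_identical(mcols(m)$n_cpg, 24L)
  ## gap 51 -> untouched
  d2 <- tiny_dmrs(starts = c(101, 252), ends = c(200, 300))
  expect_length(mergeAdjacent(d2, 50L), 2L)
  ## opposite directions never merge
  d3 <- tiny_dmrs(starts = c(101, 241), ends = c(200, 300),
                  direction = c("hypo", "hyper"))
  expect_length(mergeAdjacent(d3, 50L), 2L)
})

test_that("merging is idempotent on random DMR sets", {
  for (seed in 1:5) {
    d <- random_dmrs(12L, seed = seed)
    m1 <- mergeAdjacent(d, 50L)
    m2 <- mergeAdjacent(m1, 50L)
    expect_equal(as.data.frame(m1), as.data.frame(m2))
  }
})
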