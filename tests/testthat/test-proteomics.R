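test_that("log2FC conversion matches forced arithmetic and a brute-force oracle", {
  psm <- data.frame(protein_id = "P1", peptide_id = "p1", psm_id = "s1",
                    sample_id = c("A", "B"), intensity = c(2, 8))
  r <- psmLog2FC(psm)
  expect_equal(r$log2fc, c(log2(2 / 5), log2(8 / 5)))

  eq <- psmLog2FC(data.frame(protein_id = "P1", peptide_id = "p1",
                             psm_id = "s1", sample_id = c("A", "B", "C"),
                             intensity = rep(4, 3)))
  expect_equal(eq$log2fc, rep(0, 3))

  set.seed(5)
  tab <- simulatePSMTable(n_proteins = 4L, psm_per_peptide = 3L, seed = 5L)$psm
  r <- psmLog2FC(tab)
  key <- paste(tab$protein_id, tab$peptide_id, tab$psm_id)
  for (k in sample(unique(key), 10)) {
    idx <- key == k
    expect_equal(r$log2fc[idx],
                 log2(tab$intensity[idx] / mean(tab$intensity[idx])),
                 tolerance = 1e-12)
  }
  ## geometric reference differs but preserves differences between samples
  g <- psmLog2FC(tab, mean_type = "geometric")
  expect_equal(diff(g$log2fc[key == k]), diff(r$log2fc[key == k]),
               tolerance = 1e-12)
  expect_error(psmLog2FC(transform(tab, intensity = -intensity)),
               "non-positive")
})

test_that("Dixon filter reproduces hand-evaluated decisions at published criticals", {
  ## tight triple: Q undefined threat is absent, nothing removed
  expect_length(dixonFilter(c(1.0, 1.02, 1.04))$removed, 0L)

  ## n = 4: Q = (5.0 - 0.12) / (5.0 - 0.1) = 0.9959 > 0.829 -> removed;
  ## the surviving triple has Q = 0.5 < 0.970 -> recursion stops
  r <- dixonFilter(c(0.1, 0.11, 0.12, 5.0))
  expect_equal(r$removed, 5.0)
  expect_equal(sort(r$kept), c(0.1, 0.11, 0.12))

  ## n = 5 stepwise under the classic one-sided Q95 table:
  ## (9-3)/9 = 0.667 > 0.642 -> drop 9; then (3-0.02)/3 = 0.993 > 0.765
  ## -> drop 3; then (0.01)/(0.02) = 0.5 < 0.941 -> stop
  r1 <- dixonFilter(c(0, 0.01, 0.02, 3, 9), table = "one_sided")
  expect_equal(r1$removed, c(9, 3))
  ## under the two-sided table the first step fails (0.667 < 0.710)
  r2 <- dixonFilter(c(0, 0.01, 0.02, 3, 9), table = "two_sided")
  expect_length(r2$removed, 0L)

  expect_error(dixonFilter(rnorm(31)), "allow_large")
  expect_silent(dixonFilter(rnorm(31), allow_large = TRUE))
})

test_that("Dixon filter removes at most n - 3 values, deterministically", {
  set.seed(6)
  for (i in 1:20) {
    v <- c(rnorm(sample(3:12, 1)), rnorm(sample(0:3, 1), 0, 50))
    r <- dixonFilter(v)
    expect_lte(length(r$removed), length(v) - 3L)
    expect_identical(r$removed, dixonFilter(v)$removed)
    expect_setequal(c(r$kept, r$removed), v)
  }
})

test_that("Dixon detection power on clean groups exceeds 80% at 8 SD", {
  set.seed(99)
  det <- vapply(1:400, function(i) {
    v <- rnorm(5, 0, 0.2)
    out <- sample(c(-1, 1), 1) * 8 * 0.2
    out %in% dixonFilter(c(v, out))$removed
  }, logical(1))
  expect_gte(mean(det), 0.8)
})

test_that("median roll-ups equal a brute-force nested median", {
  one <- data.frame(protein_id = "P1", peptide_id = c("p1", "p2"),
                    psm_id = c("m1", "m2"), sample_id = "A",
                    intensity = 1, log2fc = c(0.3, -0.1))
  r <- rollupMedians(one)
  expect_equal(r$peptide$log2fc, c(0.3, -0.1))
  expect_equal(r$protein$log2fc, median(c(0.3, -0.1)))

  tri <- data.frame(protein_id = "P1", peptide_id = "p1",
                    psm_id = c("m1", "m2", "m3"), sample_id = "A",
                    intensity = 1, log2fc = c(-1, 0, 4))
  expect_equal(rollupMedians(tri, dixon_alpha = NULL)$peptide$log2fc, 0)

  set.seed(8)
  tab <- psmLog2FC(simulatePSMTable(n_proteins = 6L, seed = 8L)$psm)
  r <- rollupMedians(tab, dixon_alpha = NULL)
  for (i in sample(nrow(r$protein), 5)) {
    s <- r$protein$sample_id[i]; p <- r$protein$protein_id[i]
    sub <- tab[tab$sample_id == s & tab$protein_id == p, ]
    pep_med <- tapply(sub$log2fc, sub$peptide_id, median)
    expect_equal(r$protein$log2fc[i], median(pep_med), tolerance = 1e-12)
  }
})

test_that("mixture alignment recovers shifts and dominant modes", {
  set.seed(12)
  x <- rnorm(500, 1, 0.3)
  al <- mixtureAlign(x)
  expect_equal(al$shift, -1, tolerance = 0.05)
  re <- mixtureAlign(al$aligned)
  expect_lt(abs(re$shift), 0.02)

  ## bimodal with dominant mode at 0, then displaced by +0.5
  y <- c(rnorm(800, 0, 0.1), rnorm(200, 2, 0.1)) + 0.5
  expect_equal(mixtureAlign(y)$shift, -0.5, tolerance = 0.05)

  expect_error(mixtureAlign(rnorm(5)), "at least")
  ## cross-check the EM against mclust on the same data
  fit <- remethylome:::.em2(y)
  suppressPackageStartupMessages(library(mclust))
  mc <- Mclust(y, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$mu), sort(unname(mc$parameters$mean)),
               tolerance = 0.02)
})

test_that("scale normalization standardizes spread and matches a percentile oracle", {
  set.seed(13)
  n <- 200
  base <- rnorm(n)
  aligned <- cbind(s1 = base, s2 = rnorm(n), s3 = 2 * base)
  ints <- 2 ^ rnorm(n, 20, 2)
  intensity <- cbind(s1 = ints, s2 = 2 ^ rnorm(n, 20, 2), s3 = ints)
  sc <- scaleNormalize(aligned, intensity)
  ## the doubled-spread sample is halved back to the reference spread
  expect_equal(unname(sc$scale["s3"]) * sc$trimmed_sd[["s3"]],
               median(sc$trimmed_sd), tolerance = 1e-12)
  expect_equal(unname(sc$scale["s3"] / sc$scale["s1"]), 0.5,
               tolerance = 1e-12)
  expect_equal(sc$scaled[, "s3"], sc$scaled[, "s1"], tolerance = 1e-12,
               ignore_attr = TRUE)

  ## brute-force trim membership
  for (j in colnames(aligned)) {
    qx <- quantile(aligned[, j], c(0.05, 0.95))
    qi <- quantile(intensity[, j], c(0.05, 0.95))
    keep <- aligned[, j] >= qx[1] & aligned[, j] <= qx[2] &
      intensity[, j] >= qi[1] & intensity[, j] <= qi[2]
    expect_identical(unname(sc$trimmed[, j]), unname(keep))
  }
  ## identical spreads -> identity scaling
  same <- cbind(a = rnorm(n), b = rnorm(n))
  sc2 <- scaleNormalize(same, matrix(1000, n, 2,
                                     dimnames = list(NULL, c("a", "b"))))
  expect_true(all(abs(sc2$scale - 1) < 0.1))
})

test_that("intensity calibration is the exact anti-log of the displacement", {
  I <- matrix(c(100, 200, 400, 800), 2, 2)
  expect_equal(calibrateIntensities(I, matrix(0, 2, 2)), I)
  expect_equal(calibrateIntensities(I, matrix(1, 2, 2)), 2 * I)
  set.seed(14)
  d <- matrix(rnorm(4), 2, 2)
  out <- calibrateIntensities(I, d)
  expect_equal(log2(out) - log2(I), d, tolerance = 1e-12)
})

test_that("pipeline is equivariant to a constant shift of one sample", {
  sim <- simulatePSMTable(n_proteins = 150L, frac_diff = 0,
                          sample_shifts = c(S1 = 0, S2 = 0, S3 = 0,
                                            S4 = 0),
                          seed = 15L)
  fit0 <- normalizePSM(sim$psm)
  shifted <- sim$psm
  idx <- shifted$sample_id == "S2"
  shifted$intensity[idx] <- shifted$intensity[idx] * 2 ^ 0.75
  fit1 <- normalizePSM(shifted)
  ## scaled outputs are unchanged; the recovered shift moves by
  ## -(c - delta), delta being the displacement of the average-precursor
  ## reference that the added constant itself causes
  expect_lt(max(abs(fit1$matrices$scaled - fit0$matrices$scaled)), 0.05)
  delta <- log2((3 + 2 ^ 0.75) / 4)
  expect_equal(unname(fit1$sample_shift["S2"] - fit0$sample_shift["S2"]),
               -(0.75 - delta), tolerance = 0.05)
})

test_that("stoichiometry ratios are length-normalized and reference-anchored", {
  ab <- c(bait = 1000, partner = 250)
  len <- c(bait = 1000, partner = 500)
  r <- stoichiometry(ab, len, "bait")
  expect_equal(unname(r["bait"]), 1)
  expect_equal(unname(r["partner"]), 0.5)
  expect_error(stoichiometry(ab, len, "nosuch"), "absent")
})
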