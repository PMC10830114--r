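## Shared fixtures, built in code.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
  library(SummarizedExperiment)
})

## A tiny hand-built methylome: 6 CpGs x 4 samples, two groups.
tiny_methylome <- function() {
  gr <- GRanges("chr1", IRanges(start = c(101, 151, 201, 1001, 1051, 5001),
                                width = 2))
  depth <- matrix(10L, 6, 4)
  meth <- matrix(c(8L, 8L, 8L, 9L, 9L, 9L,
                   8L, 9L, 8L, 9L, 8L, 9L,
                   2L, 2L, 2L, 9L, 9L, 9L,
                   3L, 2L, 2L, 8L, 9L, 9L), 6, 4)
  colnames(meth) <- colnames(depth) <- c("A1", "A2", "B1", "B2")
  si <- data.frame(genotype = c("WT", "WT", "KO", "KO"),
                   group = c("WT", "WT", "KO", "KO"),
                   row.names = colnames(meth))
  CpGMethylome(gr, meth, depth, si)
}

## A small DMRSet built by hand (1-based in memory).
tiny_dmrs <- function(starts = c(101, 241), ends = c(200, 300),
                      direction = c("hypo", "hypo"), label = "WT_vs_KO") {
  gr <- GRanges("chr1", IRanges(starts, ends))
  n <- length(gr)
  mcols(gr) <- DataFrame(n_cpg = rep(12L, n),
                         mean_beta_A = rep(0.8, n),
                         mean_beta_B = rep(0.3, n),
                         diff = ifelse(direction == "hypo", 0.5, -0.5),
                         p_value = rep(1e-4, n), q_value = rep(1e-3, n),
                         direction = direction)
  DMRSet(gr, label)
}

## Random valid DMRSet for property tests (non-overlapping, sorted).
random_dmrs <- function(n = 10L, seed = 1L, label = "rand") {
  set.seed(seed)
  gaps <- sample(10:200, n, replace = TRUE)
  widths <- sample(50:400, n, replace = TRUE)
  starts <- cumsum(gaps + widths) - widths
  gr <- GRanges("chr1", IRanges(starts, width = widths))
  dir <- sample(c("hypo", "hyper"), n, replace = TRUE)
  mcols(gr) <- DataFrame(n_cpg = sample(10:40, n, TRUE),
                         mean_beta_A = runif(n, 0.5, 0.9),
                         mean_beta_B = runif(n, 0.1, 0.5),
                         diff = ifelse(dir == "hypo", 1, -1) * runif(n, 0.2, 0.5),
                         p_value = runif(n, 0, 0.05),
                         q_value = runif(n, 0, 0.05),
                         direction = dir)
  mcols(gr)$q_value <- pmax(mcols(gr)$q_value, mcols(gr)$p_value)
  DMRSet(gr, label)
}

## Sensitivity of a called set against truth at >= 50% reciprocal overlap.
reciprocal_sensitivity <- function(truth, called, frac = 0.5) {
  if (!length(truth)) return(NA_real_)
  if (!length(called)) return(0)
  ov <- findOverlaps(truth, called)
  if (!length(ov)) return(0)
  w <- width(pintersect(truth[queryHits(ov)], called[subjectHits(ov)]))
  ok <- w >= frac * width(truth[queryHits(ov)]) &
    w >= frac * width(called[subjectHits(ov)])
  length(unique(queryHits(ov)[ok])) / length(truth)
}
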