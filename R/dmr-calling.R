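## Two-group DMR discovery: recursive binary segmentation of the per-CpG
## group-mean difference signal, Mann-Whitney testing of candidate
## segments, Benjamini-Hochberg control, and the published filter/merge
## criteria (>= 10 CpGs, mean difference >= 0.2, FDR < 0.05, 50-bp merge).

#' DMR calling parameters
#'
#' @param min_cpg minimum CpGs per DMR (default 10).
#' @param min_diff minimum absolute mean methylation difference
#'   (default 0.2).
#' @param max_q FDR threshold (default 0.05).
#' @param merge_gap maximum gap in bp for fusing adjacent DMRs
#'   (default 50).
#' @param min_samples_covered minimum covered samples per group for a CpG
#'   to enter the analysis (default NULL = all samples of the group).
#' @param max_cpg_spacing break a CpG run when neighbours are further
#'   apart than this (bp, default 300).
#' @param var_reduction_min minimum relative variance reduction for a
#'   segmentation split to be accepted (default 0.01).
#' @return validated list of class \code{"DmrParams"}.
#' @export
dmrParams <- function(min_cpg = 10L, min_diff = 0.2, max_q = 0.05,
                      merge_gap = 50L, min_samples_covered = NULL,
                      max_cpg_spacing = 300L, var_reduction_min = 0.01) {
  stopifnot(min_cpg >= 2, min_diff > 0, min_diff < 1,
            max_q > 0, max_q < 1, merge_gap >= 0, max_cpg_spacing > 0)
  structure(list(min_cpg = as.integer(min_cpg), min_diff = min_diff,
                 max_q = max_q, merge_gap = as.integer(merge_gap),
                 min_samples_covered = min_samples_covered,
                 max_cpg_spacing = as.integer(max_cpg_spacing),
                 var_reduction_min = var_reduction_min),
            class = "DmrParams")
}

## Resolve a group specification (group label or explicit sample ids)
## to column indices of the methylome.
.resolve_samples <- function(methylome, group) {
  grp <- sampleGroups(methylome)
  if (length(group) == 1 && group %in% grp) which(grp == group)
  else {
    idx <- match(group, colnames(methylome))
    if (anyNA(idx)) stop("unknown samples/group: ",
                         paste(group[is.na(idx)], collapse = ", "))
    idx
  }
}

#' Per-CpG group mean methylation and difference
#'
#' For each CpG, the mean beta over covered samples (depth >= 1) of each
#' group and their difference \code{mean_A - mean_B}. CpGs covered in
#' fewer than \code{min_samples_covered} samples of either group are
#' flagged missing.
#'
#' @param methylome a \linkS4class{CpGMethylome}.
#' @param group_A,group_B group label or vector of sample ids.
#' @param min_samples_covered per-group coverage requirement
#'   (default: all samples of the group).
#' @return data.frame with columns \code{chrom}, \code{pos} (1-based
#'   start), \code{mean_A}, \code{mean_B}, \code{diff}, \code{missing}.
#' @export
groupMeanBetas <- function(methylome, group_A, group_B,
                           min_samples_covered = NULL) {
  ia <- .resolve_samples(methylome, group_A)
  ib <- .resolve_samples(methylome, group_B)
  if (!length(ia) || !length(ib)) stop("empty group")
  beta <- betaValues(methylome)
  need_a <- if (is.null(min_samples_covered)) length(ia)
            else min(min_samples_covered, length(ia))
  need_b <- if (is.null(min_samples_covered)) length(ib)
            else min(min_samples_covered, length(ib))
  cov_a <- rowSums(!is.na(beta[, ia, drop = FALSE]))
  cov_b <- rowSums(!is.na(beta[, ib, drop = FALSE]))
  mean_a <- rowMeans(beta[, ia, drop = FALSE], na.rm = TRUE)
  mean_b <- rowMeans(beta[, ib, drop = FALSE], na.rm = TRUE)
  gr <- rowRanges(methylome)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             pos = GenomicRanges::start(gr),
             mean_A = mean_a, mean_B = mean_b,
             diff = mean_a - mean_b,
             missing = cov_a < need_a | cov_b < need_b)
}

## Recursive binary segmentation of one run of consecutive CpGs.
## Splits at the boundary maximizing |mean(left) - mean(right)| of the
## difference signal, subject to both children keeping >= min_cpg CpGs,
## and accepts the split while the relative variance reduction exceeds
## the threshold. Returns a matrix of (from, to) index pairs (leaves).
.segment_run <- function(diff, min_cpg, var_reduction_min) {
  n <- length(diff)
  if (n < min_cpg) return(NULL)
  if (n < 2L * min_cpg) return(matrix(c(1L, n), 1L))
  recurse <- function(from, to) {
    v <- diff[from:to]
    m <- length(v)
    cs <- cumsum(v)
    ks <- seq.int(min_cpg, m - min_cpg)     # left size
    mean_l <- cs[ks] / ks
    mean_r <- (cs[m] - cs[ks]) / (m - ks)
    k <- ks[which.max(abs(mean_l - mean_r))]
    ss <- function(x) sum((x - mean(x))^2)
    ss_tot <- ss(v)
    gain <- if (ss_tot <= 0) 0 else
      (ss_tot - ss(v[1:k]) - ss(v[(k + 1):m])) / ss_tot
    if (gain <= var_reduction_min) return(matrix(c(from, to), 1L))
    left <- if (k >= 2L * min_cpg) recurse(from, from + k - 1L)
            else matrix(c(from, from + k - 1L), 1L)
    right <- if (m - k >= 2L * min_cpg) recurse(from + k, to)
             else matrix(c(from + k, to), 1L)
    rbind(left, right)
  }
  recurse(1L, n)
}

#' Segment a per-CpG difference signal into candidate DMRs
#'
#' CpG runs are broken at gaps larger than \code{max_cpg_spacing}; each
#' run is recursively split at the boundary maximizing the difference of
#' segment means, while both children keep at least \code{min_cpg} CpGs
#' and the split achieves a relative variance reduction above
#' \code{var_reduction_min}. Leaves are returned as candidates.
#'
#' @param diff_signal data.frame from \code{\link{groupMeanBetas}} with
#'   missing CpGs already removed.
#' @param params a \code{\link{dmrParams}} list.
#' @return data.frame with columns \code{chrom}, \code{from}, \code{to}
#'   (row indices into \code{diff_signal}).
#' @export
segmentCandidates <- function(diff_signal, params = dmrParams()) {
  if (!nrow(diff_signal)) return(data.frame(chrom = character(),
                                            from = integer(),
                                            to = integer()))
  o <- order(diff_signal$chrom, diff_signal$pos)
  stopifnot(identical(o, seq_len(nrow(diff_signal))))
  gap_break <- c(TRUE, diff(diff_signal$pos) > params$max_cpg_spacing |
                   diff_signal$chrom[-1] != diff_signal$chrom[-nrow(diff_signal)])
  run_id <- cumsum(gap_break)
  out <- lapply(split(seq_len(nrow(diff_signal)), run_id), function(idx) {
    segs <- .segment_run(diff_signal$diff[idx], params$min_cpg,
                         params$var_reduction_min)
    if (is.null(segs)) return(NULL)
    data.frame(chrom = diff_signal$chrom[idx[1]],
               from = idx[segs[, 1]], to = idx[segs[, 2]])
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(data.frame(chrom = character(),
                                      from = integer(), to = integer()))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Mann-Whitney test of a candidate segment
#'
#' Two-sided Mann-Whitney U comparing the pooled per-sample per-CpG beta
#' values of the two groups within the segment. Exact when the pooled
#' sample size is at most 50 and no ties are present; otherwise the
#' normal approximation with mid-rank tie handling.
#'
#' @param betas_A,betas_B numeric vectors of pooled beta values
#'   (NA = uncovered, dropped).
#' @return two-sided p-value in [0,1]; 1 when all pooled values are tied.
#' @export
testSegment <- function(betas_A, betas_B) {
  a <- betas_A[!is.na(betas_A)]; b <- betas_B[!is.na(betas_B)]
  if (!length(a) || !length(b)) return(NA_real_)
  pooled <- c(a, b)
  if (max(pooled) == min(pooled)) return(1)
  exact <- length(pooled) <= 50 && !anyDuplicated(pooled)
  res <- suppressWarnings(wilcox.test(a, b, exact = exact,
                                      correct = !exact))
  min(1, res$p.value)
}

#' Call DMRs between two groups
#'
#' Computes the per-CpG group difference signal, segments it into
#' candidates, tests every candidate by Mann-Whitney on the pooled
#' per-sample per-CpG betas, applies Benjamini-Hochberg across all tested
#' candidates, retains candidates with \code{n_cpg >= min_cpg},
#' \code{|mean_A - mean_B| >= min_diff} and \code{q < max_q}, and fuses
#' retained same-direction DMRs within \code{merge_gap} bp.
#'
#' @param methylome a \linkS4class{CpGMethylome}.
#' @param group_A,group_B group label or sample id vector (A is the
#'   reference, typically WT).
#' @param params a \code{\link{dmrParams}} list.
#' @return a \linkS4class{DMRSet}; "hypo" means group B lost methylation
#'   relative to group A.
#' @examples
#' sim <- simulateMethylome(simConfig(n_cpg_clusters = 60L,
#'                                    n_true_dmrs = 6L,
#'                                    samples_per_group = c(WT = 4L,
#'                                                          `3aKO` = 4L),
#'                                    seed = 11L))
#' callDMRs(sim$methylome, "WT", "3aKO")
#' @export
callDMRs <- function(methylome, group_A, group_B, params = dmrParams()) {
  ia <- .resolve_samples(methylome, group_A)
  ib <- .resolve_samples(methylome, group_B)
  if (length(ia) + length(ib) < 2) stop("fewer than 2 samples in total")
  label <- paste0(if (length(group_A) == 1) group_A else "A", "_vs_",
                  if (length(group_B) == 1) group_B else "B")

  sig <- groupMeanBetas(methylome, group_A, group_B,
                        params$min_samples_covered)
  keep <- !sig$missing
  sig_idx <- which(keep)
  sig2 <- sig[keep, , drop = FALSE]
  rownames(sig2) <- NULL
  cand <- segmentCandidates(sig2, params)
  empty <- function() {
    gr <- GRanges()
    for (col in c("n_cpg", "mean_beta_A", "mean_beta_B", "diff",
                  "p_value", "q_value"))
      mcols(gr)[[col]] <- numeric()
    mcols(gr)$direction <- character()
    DMRSet(gr, label)
  }
  if (!nrow(cand)) return(empty())

  beta <- betaValues(methylome)
  p <- numeric(nrow(cand))
  mean_a <- numeric(nrow(cand)); mean_b <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    rows <- sig_idx[cand$from[i]:cand$to[i]]
    p[i] <- testSegment(as.vector(beta[rows, ia]),
                        as.vector(beta[rows, ib]))
    mean_a[i] <- mean(sig$mean_A[rows])
    mean_b[i] <- mean(sig$mean_B[rows])
  }
  q <- p.adjust(p, "BH")
  n_cpg <- cand$to - cand$from + 1L
  dff <- mean_a - mean_b
  keep_dmr <- n_cpg >= params$min_cpg & abs(dff) >= params$min_diff &
    q < params$max_q & !is.na(p)
  if (!any(keep_dmr)) return(empty())

  sel <- which(keep_dmr)
  pos <- rowRanges(methylome)
  starts <- GenomicRanges::start(pos)[sig_idx[cand$from[sel]]]
  ends <- GenomicRanges::end(pos)[sig_idx[cand$to[sel]]]
  gr <- GRanges(cand$chrom[sel], IRanges(starts, ends))
  mcols(gr) <- DataFrame(n_cpg = n_cpg[sel], mean_beta_A = mean_a[sel],
                         mean_beta_B = mean_b[sel], diff = dff[sel],
                         p_value = p[sel], q_value = q[sel],
                         direction = ifelse(dff[sel] > 0, "hypo", "hyper"))
  mergeAdjacent(DMRSet(gr, label), params$merge_gap)
}

#' Fuse adjacent same-direction DMRs
#'
#' Same-chromosome, same-direction DMRs whose gap is at most
#' \code{merge_gap} bp (and any overlapping ones) are combined: CpG counts
#' are summed, group means recomputed CpG-weighted, and the merged p/q is
#' the minimum of the parts. Idempotent.
#'
#' @param dmrs a \linkS4class{DMRSet}.
#' @param merge_gap maximum gap in bp (default 50).
#' @return a \linkS4class{DMRSet}.
#' @export
mergeAdjacent <- function(dmrs, merge_gap = 50L) {
  if (length(dmrs) < 2) return(dmrs)
  out <- lapply(c("hypo", "hyper"), function(dir) {
    sub <- dmrs[mcols(dmrs)$direction == dir]
    if (!length(sub)) return(NULL)
    red <- GenomicRanges::reduce(granges(sub),
                                 min.gapwidth = merge_gap + 1L,
                                 with.revmap = TRUE)
    mc <- mcols(sub)
    agg <- lapply(mcols(red)$revmap, function(ii) {
      w <- mc$n_cpg[ii]
      data.frame(n_cpg = sum(w),
                 mean_beta_A = sum(mc$mean_beta_A[ii] * w) / sum(w),
                 mean_beta_B = sum(mc$mean_beta_B[ii] * w) / sum(w),
                 p_value = min(mc$p_value[ii]),
                 q_value = min(mc$q_value[ii]))
    })
    agg <- do.call(rbind, agg)
    gr <- granges(red)
    mcols(gr) <- DataFrame(
      n_cpg = agg$n_cpg, mean_beta_A = agg$mean_beta_A,
      mean_beta_B = agg$mean_beta_B,
      diff = agg$mean_beta_A - agg$mean_beta_B,
      p_value = agg$p_value, q_value = agg$q_value,
      direction = dir)
    gr
  })
  gr <- do.call(c, out[!vapply(out, is.null, logical(1))])
  DMRSet(gr, comparisonLabel(dmrs))
}
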