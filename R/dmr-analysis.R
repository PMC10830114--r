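## DMR-centric summaries: passive methylation matrices, unified DMR sets,
## aggregate canyon profiles, annotation-class summaries, and floxing
## efficiency from coverage dropout.

#' Passive per-sample methylation over a fixed DMR set
#'
#' Evaluates every sample's mean methylation over the CpGs of each DMR
#' without re-calling DMRs ("passive plotting"). Unweighted across CpGs
#' by default (each covered CpG counts equally); depth weighting
#' (sum meth / sum depth) is available and never silent.
#'
#' @param dmrs a \linkS4class{DMRSet} (or \code{GRanges}).
#' @param methylome a \linkS4class{CpGMethylome}.
#' @param weighting \code{"cpg"} (default) or \code{"depth"}.
#' @return numeric matrix DMR x sample; \code{NA} where a DMR has no
#'   covered CpG in a sample (logged).
#' @export
passiveMethylation <- function(dmrs, methylome,
                               weighting = c("cpg", "depth")) {
  weighting <- match.arg(weighting)
  if (weighting == "depth") msg("passive means are depth-weighted")
  hits <- findOverlaps(rowRanges(methylome), dmrs)
  out <- matrix(NA_real_, length(dmrs), ncol(methylome),
                dimnames = list(sprintf("dmr_%05d", seq_along(dmrs)),
                                colnames(methylome)))
  if (!length(hits)) {
    msg("no CpGs overlap the DMR set")
    return(out)
  }
  by_dmr <- split(queryHits(hits), subjectHits(hits))
  meth <- methCounts(methylome); depth <- readDepth(methylome)
  beta <- betaValues(methylome)
  for (k in names(by_dmr)) {
    rows <- by_dmr[[k]]
    i <- as.integer(k)
    if (weighting == "cpg") {
      out[i, ] <- colMeans(beta[rows, , drop = FALSE], na.rm = TRUE)
    } else {
      d <- colSums(depth[rows, , drop = FALSE])
      out[i, ] <- ifelse(d > 0,
                         colSums(meth[rows, , drop = FALSE]) / d, NA_real_)
    }
  }
  out[is.nan(out)] <- NA_real_
  n_missing <- sum(is.na(out))
  if (n_missing) msg(n_missing, " DMR/sample cells without covered CpGs")
  out
}

#' Union of several DMR sets into a unified set
#'
#' Takes the interval union of the input sets, merging overlapping or
#' book-ended intervals only (not the 50-bp calling-time gap rule).
#' Provenance (which comparisons contributed) is recorded in the
#' \code{sources} metadata column. Summary columns are recombined
#' CpG-weighted from the contributing DMRs; \code{n_cpg} is recomputed
#' against \code{methylome} when one is supplied (otherwise summed over
#' members, which may double-count overlapping CpGs).
#'
#' @param sets list of \linkS4class{DMRSet} objects.
#' @param methylome optional \linkS4class{CpGMethylome} for exact CpG
#'   recounting.
#' @return a \linkS4class{DMRSet} labeled "unified".
#' @export
unifiedDMRSet <- function(sets, methylome = NULL) {
  stopifnot(length(sets) >= 1)
  if (length(sets) == 1) return(sets[[1]])
  labels <- vapply(sets, comparisonLabel, character(1))
  all_gr <- do.call(c, unname(lapply(sets, granges)))
  src <- rep(labels, vapply(sets, length, integer(1)))
  mc_all <- do.call(rbind, lapply(sets, function(s) as.data.frame(mcols(s))))
  red <- GenomicRanges::reduce(all_gr, min.gapwidth = 1L, with.revmap = TRUE)
  agg <- lapply(mcols(red)$revmap, function(ii) {
    w <- mc_all$n_cpg[ii]
    dominant <- names(sort(tapply(w, mc_all$direction[ii], sum),
                           decreasing = TRUE))[1]
    data.frame(n_cpg = sum(w),
               mean_beta_A = sum(mc_all$mean_beta_A[ii] * w) / sum(w),
               mean_beta_B = sum(mc_all$mean_beta_B[ii] * w) / sum(w),
               p_value = min(mc_all$p_value[ii]),
               q_value = min(mc_all$q_value[ii]),
               direction = dominant,
               sources = paste(sort(unique(src[ii])), collapse = ","))
  })
  agg <- do.call(rbind, agg)
  gr <- granges(red)
  if (!is.null(methylome)) {
    cnt <- GenomicRanges::countOverlaps(gr, rowRanges(methylome))
    agg$n_cpg <- pmax(cnt, 1L)
  }
  mcols(gr) <- DataFrame(n_cpg = agg$n_cpg,
                         mean_beta_A = agg$mean_beta_A,
                         mean_beta_B = agg$mean_beta_B,
                         diff = agg$mean_beta_A - agg$mean_beta_B,
                         p_value = agg$p_value, q_value = agg$q_value,
                         direction = agg$direction, sources = agg$sources)
  DMRSet(gr, "unified")
}

#' Aggregate methylation profile over scaled DMR bodies ("canyon plot")
#'
#' Each DMR body is scaled to \code{n_body_bins} bins; flanking sequence
#' of \code{flank} bp each side is binned absolutely into
#' \code{n_flank_bins} bins. Every CpG falling in a DMR window
#' contributes to exactly one bin of that window. Mean beta is reported
#' per bin per genotype (pooling CpGs and samples of the genotype).
#'
#' @param dmrs a \linkS4class{DMRSet}.
#' @param methylome a \linkS4class{CpGMethylome}.
#' @param flank flank size in bp (default 2000).
#' @param n_body_bins,n_flank_bins bin counts (defaults 20 and 10).
#' @return data.frame with \code{bin} (-n_flank_bins .. n_body_bins +
#'   n_flank_bins - 1; body bins are 0-based from 0), \code{bin_type}
#'   (upstream/body/downstream), \code{genotype}, \code{mean_beta},
#'   \code{n} (CpG-sample observations).
#' @export
canyonProfile <- function(dmrs, methylome, flank = 2000L,
                          n_body_bins = 20L, n_flank_bins = 10L) {
  stopifnot(flank >= 0)
  win <- suppressWarnings(GenomicRanges::trim(
    GenomicRanges::resize(granges(dmrs),
                          GenomicRanges::width(dmrs) + 2L * flank,
                          fix = "center")))
  hits <- findOverlaps(rowRanges(methylome), win)
  if (!length(hits)) stop("no CpGs fall inside the DMR windows")
  cpg_pos <- GenomicRanges::start(rowRanges(methylome))[queryHits(hits)]
  d_start <- GenomicRanges::start(dmrs)[subjectHits(hits)]
  d_end <- GenomicRanges::end(dmrs)[subjectHits(hits)]
  d_width <- d_end - d_start + 1L

  bin <- integer(length(hits))
  in_body <- cpg_pos >= d_start & cpg_pos <= d_end
  bin[in_body] <- pmin(n_body_bins - 1L,
                       floor((cpg_pos[in_body] - d_start[in_body]) /
                               d_width[in_body] * n_body_bins))
  up <- cpg_pos < d_start
  if (flank > 0) {
    bw <- flank / n_flank_bins
    bin[up] <- -1L - pmin(n_flank_bins - 1L,
                          floor((d_start[up] - cpg_pos[up] - 1) / bw))
    dn <- cpg_pos > d_end
    bin[dn] <- n_body_bins +
      pmin(n_flank_bins - 1L, floor((cpg_pos[dn] - d_end[dn] - 1) / bw))
  }
  keep <- in_body | flank > 0
  bin <- bin[keep]; rows <- queryHits(hits)[keep]

  beta <- betaValues(methylome)
  geno <- genotypes(methylome)
  res <- list()
  for (g in unique(geno)) {
    bg <- beta[rows, geno == g, drop = FALSE]
    v <- rowMeans(bg, na.rm = TRUE)
    n_obs <- rowSums(!is.na(bg))
    mean_b <- tapply(v * n_obs, bin, sum, na.rm = TRUE) /
      tapply(n_obs, bin, sum)
    n_bin <- tapply(n_obs, bin, sum)
    b <- as.integer(names(mean_b))
    res[[g]] <- data.frame(
      bin = b,
      bin_type = ifelse(b < 0, "upstream",
                        ifelse(b < n_body_bins, "body", "downstream")),
      genotype = g, mean_beta = as.numeric(mean_b),
      n = as.integer(n_bin))
  }
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  out[order(out$genotype, out$bin), ]
}

#' Mean methylation per annotation class per sample
#'
#' Mean beta over CpGs intersecting each annotation class; a CpG lying in
#' overlapping classes counts in each. Optionally restricted to CpGs
#' inside a DMR set.
#'
#' @param methylome a \linkS4class{CpGMethylome}.
#' @param annotation an \linkS4class{AnnotationTrack}.
#' @param restrict_to optional \linkS4class{DMRSet}; only CpGs inside it
#'   are summarised.
#' @return numeric matrix class x sample (NA for empty classes, logged).
#' @export
annotationSummary <- function(methylome, annotation, restrict_to = NULL) {
  beta <- betaValues(methylome)
  keep <- rep(TRUE, nrow(methylome))
  if (!is.null(restrict_to))
    keep <- GenomicRanges::countOverlaps(rowRanges(methylome),
                                         restrict_to) > 0
  classes <- unique(mcols(annotation)$class_label)
  out <- matrix(NA_real_, length(classes), ncol(methylome),
                dimnames = list(classes, colnames(methylome)))
  for (cl in classes) {
    idx <- GenomicRanges::countOverlaps(
      rowRanges(methylome), annotation[mcols(annotation)$class_label == cl]) > 0
    idx <- idx & keep
    if (!any(idx)) {
      msg("annotation class '", cl, "' covers no CpGs")
      next
    }
    out[cl, ] <- colMeans(beta[idx, , drop = FALSE], na.rm = TRUE)
  }
  out
}

#' Floxing efficiency from coverage dropout
#'
#' Estimates the excision fraction of loxP-flanked intervals from the
#' sequencing-depth dropout over those intervals:
#' \code{f = 1 - meanDepth(floxed) / meanDepth(control)}, clamped to
#' [0,1], per sample. The control is either user-supplied flanking
#' intervals, flanks of the same width generated on each side of every
#' floxed interval (default), or the same floxed intervals in a reference
#' (non-floxed) methylome.
#'
#' @param methylome a \linkS4class{CpGMethylome} (floxed samples).
#' @param floxed \code{GRanges} of excised intervals.
#' @param control_flanks optional \code{GRanges} of control intervals;
#'   default: same-width flanks on each side of each floxed interval.
#' @param reference optional \linkS4class{CpGMethylome} of non-floxed
#'   samples; when given, the control is the floxed intervals' depth in
#'   the reference, rescaled by the genome-wide depth ratio.
#' @param samples sample ids to estimate for (default all).
#' @return named numeric vector of per-sample efficiencies.
#' @export
floxingEfficiency <- function(methylome, floxed, control_flanks = NULL,
                              reference = NULL,
                              samples = colnames(methylome)) {
  if (!length(floxed)) stop("empty floxed interval set")
  depth <- readDepth(methylome)[, samples, drop = FALSE]
  in_flox <- GenomicRanges::countOverlaps(rowRanges(methylome), floxed) > 0
  if (!any(in_flox)) stop("no CpGs inside the floxed intervals")
  d_flox <- colMeans(depth[in_flox, , drop = FALSE])

  if (!is.null(reference)) {
    ref_depth <- readDepth(reference)
    ref_flox <- GenomicRanges::countOverlaps(rowRanges(reference), floxed) > 0
    ctrl <- mean(ref_depth[ref_flox, ]) *
      colMeans(depth) / mean(ref_depth)
  } else {
    if (is.null(control_flanks)) {
      w <- GenomicRanges::width(floxed)
      control_flanks <- c(
        GenomicRanges::flank(floxed, w, start = TRUE),
        GenomicRanges::flank(floxed, w, start = FALSE))
    }
    in_ctrl <- GenomicRanges::countOverlaps(rowRanges(methylome),
                                            control_flanks) > 0 & !in_flox
    if (!any(in_ctrl)) stop("no CpGs inside the control flanks")
    ctrl <- colMeans(depth[in_ctrl, , drop = FALSE])
  }
  if (any(ctrl <= 0)) stop("zero control depth")
  clamp01(1 - d_flox / ctrl)
}

#' Summary statistics of a DMRSet
#'
#' @param dmrs a \linkS4class{DMRSet}.
#' @return list with \code{n}, \code{n_hypo}, \code{n_hyper},
#'   \code{mean_width} (bp, half-open widths), \code{mean_cpg} and
#'   \code{total_bp}.
#' @export
summarizeDMRSet <- function(dmrs) {
  mc <- mcols(dmrs)
  list(n = length(dmrs),
       n_hypo = sum(mc$direction == "hypo"),
       n_hyper = sum(mc$direction == "hyper"),
       mean_width = if (length(dmrs)) mean(GenomicRanges::width(dmrs))
                    else NA_real_,
       mean_cpg = if (length(dmrs)) mean(mc$n_cpg) else NA_real_,
       total_bp = sum(GenomicRanges::width(dmrs)))
}
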