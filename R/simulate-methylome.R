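## Synthetic whole-genome bisulfite data with known ground truth.
##
## The generator emulates the statistical structure the downstream analysis
## assumes: CpGs clustered into annotation classes, negative-binomial read
## depth (mean 18.6x by default), beta-binomial methylation counts, a
## minority of regions carrying genotype-ordered focal hypomethylation
## (DKO > 3aKO > R878H > 3bKO), addback samples with a tunable correction
## level, and near-complete floxing as coverage dropout.

#' Simulate a multi-genotype CpG methylome with ground truth
#'
#' Lays out \code{n_cpg_clusters} CpG clusters over a single synthetic
#' chromosome ("chrS"), assigns each cluster an annotation class with a
#' class-specific baseline methylation level, plants genotype effects
#' (hypomethylation of depth \code{dmr_effect_by_genotype[g]}) in
#' \code{n_true_dmrs} clusters chosen among those with baseline >= 0.5,
#' then draws per-sample read depth from a negative binomial and methylated
#' counts from a beta-binomial. Two floxed intervals (class
#' \code{"floxed"}) are reserved in effect-free clusters for
#' floxing-efficiency simulations. Deterministic given
#' \code{config@seed}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with elements \code{methylome}
#'   (\linkS4class{CpGMethylome}; \code{rowData} keeps the baseline mu and
#'   class label, \code{metadata()$sim} the depth/overdispersion
#'   parameters), \code{annotation} (\linkS4class{AnnotationTrack} of
#'   cluster classes plus floxed intervals), and \code{truth} (list:
#'   \code{true_dmr_intervals} GRanges with per-genotype
#'   \code{delta_<genotype>} columns, \code{floxed_intervals},
#'   \code{true_floxing_efficiency}).
#' @examples
#' sim <- simulateMethylome(simConfig(n_cpg_clusters = 40L,
#'                                    n_true_dmrs = 4L, seed = 7L))
#' sim$methylome
#' @export
simulateMethylome <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  groups <- config@samples_per_group
  if (any(groups < 1)) stop("zero samples in a group")

  layout <- with_seed(child_seed(config@seed, "layout"), {
    ncl <- config@n_cpg_clusters
    classes <- sample(names(config@baseline_beta_by_class), ncl, replace = TRUE)
    sizes <- if (config@cluster_size_jitter)
      pmax(3L, rpois(ncl, config@cpg_per_cluster_mean))
    else rep(as.integer(round(config@cpg_per_cluster_mean)), ncl)
    slot_w <- floor(config@genome_length / ncl)
    ## intra-cluster CpG spacing 10-60 bp; clusters confined to their slot
    ## so neighbouring clusters are separated by > max_cpg_spacing
    pos <- vector("list", ncl)
    for (i in seq_len(ncl)) {
      gaps <- sample(10:60, sizes[i], replace = TRUE)
      p <- (i - 1L) * slot_w + 500L + cumsum(gaps)
      pos[[i]] <- p
    }
    ## true DMRs live in clusters with enough methylation to lose
    eligible <- which(config@baseline_beta_by_class[classes] >= 0.5)
    if (config@n_true_dmrs > length(eligible))
      stop("not enough clusters with baseline >= 0.5 to host ",
           config@n_true_dmrs, " true DMRs")
    dmr_clusters <- sort(sample(eligible, config@n_true_dmrs))
    ## floxed intervals: two effect-free, well-methylated clusters
    flox_pool <- setdiff(eligible, dmr_clusters)
    flox_clusters <- if (length(flox_pool) >= 2) sort(sample(flox_pool, 2L))
                     else integer()
    list(classes = classes, sizes = sizes, pos = pos,
         dmr_clusters = dmr_clusters, flox_clusters = flox_clusters)
  })

  cluster_id <- rep(seq_along(layout$sizes), layout$sizes)
  pos <- unlist(layout$pos)
  n_cpg <- length(pos)
  class_per_cpg <- layout$classes[cluster_id]
  mu_baseline <- unname(config@baseline_beta_by_class[class_per_cpg])
  in_dmr <- cluster_id %in% layout$dmr_clusters

  sample_ids <- unlist(lapply(names(groups), function(g)
    sprintf("%s_%02d", g, seq_len(groups[[g]]))))
  genotype <- rep(names(groups), groups)
  effects <- config@dmr_effect_by_genotype

  mu <- matrix(mu_baseline, n_cpg, length(sample_ids))
  for (j in seq_along(sample_ids)) {
    eff <- if (genotype[j] %in% names(effects)) effects[[genotype[j]]] else 0
    if (eff > 0) mu[in_dmr, j] <- mu[in_dmr, j] - eff
  }
  if (any(mu < 0)) {
    msg("clamped ", sum(mu < 0), " mu values below 0")
    mu <- clamp01(mu)
  }

  counts <- with_seed(child_seed(config@seed, "counts"), {
    depth <- matrix(rdepth(n_cpg * length(sample_ids), config@mean_depth,
                           config@depth_dispersion),
                    n_cpg, length(sample_ids))
    meth <- matrix(rbetabinom(n_cpg * length(sample_ids), as.vector(depth),
                              as.vector(mu), config@beta_binomial_rho),
                   n_cpg, length(sample_ids))
    list(depth = depth, meth = meth)
  })
  colnames(counts$depth) <- colnames(counts$meth) <- sample_ids

  gr <- GRanges("chrS", IRanges(start = pos + 1L, width = 2L))
  si <- data.frame(genotype = genotype, group = genotype,
                   row.names = sample_ids)
  me <- CpGMethylome(gr, counts$meth, counts$depth, si)
  rowData(me)$class_label <- class_per_cpg
  rowData(me)$mu_baseline <- mu_baseline
  rowData(me)$cluster_id <- cluster_id
  metadata(me)$sim <- list(mean_depth = config@mean_depth,
                           depth_dispersion = config@depth_dispersion,
                           beta_binomial_rho = config@beta_binomial_rho)

  cluster_span <- function(i) {
    p <- layout$pos[[i]]
    GRanges("chrS", IRanges(min(p) + 1L, max(p) + 2L))
  }
  ann <- do.call(c, lapply(seq_along(layout$sizes), cluster_span))
  mcols(ann)$class_label <- layout$classes
  ## floxed interval = span of the middle third of the cluster's CpGs
  flox <- GRanges()
  for (i in layout$flox_clusters) {
    p <- layout$pos[[i]]
    lo <- min(ceiling(length(p) / 3) + 1L, length(p))
    hi <- max(lo, floor(2 * length(p) / 3))
    mid <- p[lo:hi]
    flox <- c(flox, GRanges("chrS", IRanges(min(mid) + 1L, max(mid) + 2L)))
  }
  if (length(flox)) mcols(flox)$class_label <- "floxed"
  annotation <- annotationTrack(c(ann, flox))

  truth_gr <- do.call(c, c(list(GRanges()),
                           lapply(layout$dmr_clusters, cluster_span)))
  for (g in names(effects))
    mcols(truth_gr)[[paste0("delta_", g)]] <-
      rep(effects[[g]], length(truth_gr))
  truth <- list(true_dmr_intervals = sort(truth_gr),
                floxed_intervals = flox,
                true_floxing_efficiency = config@floxing_efficiency)
  stopifnot(all(GenomicRanges::end(truth$true_dmr_intervals) <=
                  config@genome_length))

  list(methylome = me, annotation = annotation, truth = truth)
}

#' Simulate addback samples over an existing methylome
#'
#' Generates new samples whose expected methylation at true-DMR CpGs is
#' \code{KO + correction_level * (WT - KO)} and the class baseline
#' elsewhere, drawing depth and counts from the same models as
#' \code{\link{simulateMethylome}}. \code{correction_level = 0} reproduces
#' the knockout in expectation, \code{1} the wild type (full
#' remethylation).
#'
#' @param methylome a simulated \linkS4class{CpGMethylome} (must carry
#'   \code{rowData()$mu_baseline} and \code{metadata()$sim}).
#' @param truth truth list from \code{\link{simulateMethylome}}.
#' @param correction_level fraction in [0,1].
#' @param label group label for the new samples (e.g. "3aKO_3A1").
#' @param seed integer seed.
#' @param ko_genotype genotype whose deficit is being corrected.
#' @param n_samples number of addback samples (default 3).
#' @return a \linkS4class{CpGMethylome} containing only the new samples,
#'   column-bindable with the input.
#' @export
simulateAddback <- function(methylome, truth, correction_level, label,
                            seed, ko_genotype = "3aKO", n_samples = 3L) {
  stopifnot(correction_level >= 0, correction_level <= 1)
  delta_col <- paste0("delta_", ko_genotype)
  if (!delta_col %in% colnames(mcols(truth$true_dmr_intervals)))
    stop("unknown genotype label: ", ko_genotype)
  sim <- metadata(methylome)$sim
  if (is.null(sim)) stop("methylome lacks simulation parameters")
  mu0 <- rowData(methylome)$mu_baseline
  n_cpg <- nrow(methylome)

  hit <- queryHits(findOverlaps(rowRanges(methylome),
                                truth$true_dmr_intervals))
  eff <- mcols(truth$true_dmr_intervals)[[delta_col]][1]
  mu <- mu0
  mu[hit] <- clamp01(mu0[hit] - (1 - correction_level) * eff)

  counts <- with_seed(seed, {
    depth <- matrix(rdepth(n_cpg * n_samples, sim$mean_depth,
                           sim$depth_dispersion), n_cpg, n_samples)
    meth <- matrix(rbetabinom(n_cpg * n_samples, as.vector(depth),
                              rep(mu, n_samples), sim$beta_binomial_rho),
                   n_cpg, n_samples)
    list(depth = depth, meth = meth)
  })
  ids <- sprintf("%s_%02d", label, seq_len(n_samples))
  colnames(counts$depth) <- colnames(counts$meth) <- ids
  si <- data.frame(genotype = rep(ko_genotype, n_samples),
                   group = rep(label, n_samples), row.names = ids)
  out <- CpGMethylome(rowRanges(methylome), counts$meth, counts$depth, si)
  rowData(out) <- rowData(methylome)
  metadata(out)$sim <- sim
  out
}

#' Apply floxing-style coverage dropout inside intervals
#'
#' Depth inside the floxed intervals is binomially thinned to a fraction
#' \code{1 - efficiency} of its original value and methylated counts are
#' resampled without replacement from the original reads (hypergeometric),
#' so the methylation level is preserved in expectation while coverage
#' drops. \code{efficiency = 1} zeroes the depth.
#'
#' @param methylome a \linkS4class{CpGMethylome}.
#' @param floxed_intervals \code{GRanges} (or
#'   \linkS4class{AnnotationTrack}) of excised intervals.
#' @param efficiency excision fraction in [0,1].
#' @param seed integer seed.
#' @param samples sample ids to modify (default: all).
#' @return the modified \linkS4class{CpGMethylome}.
#' @export
simulateFloxedCoverage <- function(methylome, floxed_intervals, efficiency,
                                   seed, samples = colnames(methylome)) {
  stopifnot(efficiency >= 0, efficiency <= 1)
  gr <- rowRanges(methylome)
  if (length(floxed_intervals) == 0) stop("no floxed intervals supplied")
  genome_end <- max(GenomicRanges::end(gr))
  if (any(GenomicRanges::start(floxed_intervals) < 1) ||
      any(GenomicRanges::end(floxed_intervals) > genome_end + 1e4))
    stop("floxed intervals fall outside the simulated genome")
  idx <- queryHits(findOverlaps(gr, floxed_intervals))
  meth <- methCounts(methylome); depth <- readDepth(methylome)
  cols <- match(samples, colnames(methylome))
  if (anyNA(cols)) stop("unknown sample ids")
  with_seed(seed, {
    for (j in cols) {
      d <- depth[idx, j]; m <- meth[idx, j]
      d2 <- rbinom(length(d), d, 1 - efficiency)
      m2 <- rhyper(length(d), m, d - m, d2)
      depth[idx, j] <- d2
      meth[idx, j] <- m2
    }
  })
  out <- methylome
  SummarizedExperiment::assay(out, "meth") <- meth
  SummarizedExperiment::assay(out, "depth") <- depth
  out
}
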