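#' @import methods
#' @import GenomicRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- DataFrame queryHits
#'   subjectHits
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   rowData<- colData colData<- rowRanges
NULL

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Simulation configuration for synthetic bisulfite data
#'
#' Holds every knob of the synthetic whole-genome-bisulfite generator:
#' genome layout (CpG clusters with annotation classes), baseline methylation
#' per class, the set of genuinely differential regions and their
#' per-genotype hypomethylation depth, sequencing depth model, beta-binomial
#' overdispersion, group sizes, floxing efficiency and addback correction
#' level. Defaults reproduce the study conditions the package targets:
#' 18.6x mean coverage, group sizes WT=9 / 3aKO=4 / 3bKO=3 / DKO=3 /
#' R878H=6, effect severity DKO > 3aKO > R878H > 3bKO, 96% floxing.
#'
#' @slot genome_length genome size in bp (single chromosome "chrS").
#' @slot n_cpg_clusters number of CpG clusters scattered over the genome.
#' @slot cpg_per_cluster_mean CpGs per cluster (fixed size unless
#'   \code{cluster_size_jitter}).
#' @slot cluster_size_jitter logical; Poisson-vary cluster sizes.
#' @slot baseline_beta_by_class named numeric, baseline methylation fraction
#'   per annotation class.
#' @slot n_true_dmrs number of clusters carrying a genuine genotype effect.
#' @slot dmr_effect_by_genotype named numeric, hypomethylation depth
#'   (delta beta) per genotype inside true DMRs.
#' @slot mean_depth mean read depth per CpG per sample.
#' @slot depth_dispersion negative-binomial dispersion of depth
#'   (Var = mu + disp * mu^2); 0 gives Poisson.
#' @slot beta_binomial_rho beta-binomial overdispersion in [0,1).
#' @slot samples_per_group named integer, samples per genotype group.
#' @slot floxing_efficiency fraction of alleles excised in floxed intervals.
#' @slot correction_level default addback correction level in [0,1].
#' @slot seed integer root seed.
#' @export
setClass("SimConfig", representation(
  genome_length = "numeric",
  n_cpg_clusters = "integer",
  cpg_per_cluster_mean = "numeric",
  cluster_size_jitter = "logical",
  baseline_beta_by_class = "numeric",
  n_true_dmrs = "integer",
  dmr_effect_by_genotype = "numeric",
  mean_depth = "numeric",
  depth_dispersion = "numeric",
  beta_binomial_rho = "numeric",
  samples_per_group = "integer",
  floxing_efficiency = "numeric",
  correction_level = "numeric",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msgs <- character()
  frac <- c(object@baseline_beta_by_class, object@dmr_effect_by_genotype,
            object@floxing_efficiency, object@correction_level)
  if (any(frac < 0 | frac > 1)) msgs <- c(msgs, "all fractions must lie in [0,1]")
  if (object@mean_depth <= 0) msgs <- c(msgs, "mean_depth must be > 0")
  if (object@n_true_dmrs < 0) msgs <- c(msgs, "n_true_dmrs must be >= 0")
  if (object@beta_binomial_rho < 0 || object@beta_binomial_rho >= 1)
    msgs <- c(msgs, "beta_binomial_rho must be in [0,1)")
  if (object@depth_dispersion < 0) msgs <- c(msgs, "depth_dispersion must be >= 0")
  if (length(object@samples_per_group) == 0 ||
      is.null(names(object@samples_per_group)))
    msgs <- c(msgs, "samples_per_group must be a named integer vector")
  else if (any(object@samples_per_group < 1))
    msgs <- c(msgs, "every group needs at least one sample")
  if (is.null(names(object@baseline_beta_by_class)))
    msgs <- c(msgs, "baseline_beta_by_class must be named")
  if (object@n_true_dmrs > 0 && length(object@dmr_effect_by_genotype) == 0)
    msgs <- c(msgs, "dmr_effect_by_genotype required when n_true_dmrs > 0")
  if (object@n_cpg_clusters < 1) msgs <- c(msgs, "need at least one CpG cluster")
  if (object@n_true_dmrs > object@n_cpg_clusters)
    msgs <- c(msgs, "n_true_dmrs cannot exceed n_cpg_clusters")
  if (length(msgs)) msgs else TRUE
})

#' Build a simulation configuration
#'
#' Constructor for \linkS4class{SimConfig}; see the class documentation for
#' the meaning of every field. Defaults encode the study conditions:
#' 18.6x mean coverage, the published group sizes, severity ordering
#' DKO (0.5) > 3aKO (0.4) > R878H (0.2) > 3bKO (0.1), 96% floxing
#' efficiency, and 15-CpG clusters so that planted DMRs carry 15 CpGs.
#'
#' @param genome_length genome size in bp.
#' @param n_cpg_clusters number of CpG clusters.
#' @param cpg_per_cluster_mean CpGs per cluster.
#' @param cluster_size_jitter Poisson-vary cluster sizes (default FALSE).
#' @param baseline_beta_by_class named numeric of per-class baselines.
#' @param n_true_dmrs number of clusters with a genuine effect.
#' @param dmr_effect_by_genotype named numeric of per-genotype delta beta.
#' @param mean_depth mean per-CpG read depth.
#' @param depth_dispersion negative-binomial depth dispersion.
#' @param beta_binomial_rho beta-binomial overdispersion.
#' @param samples_per_group named vector of group sizes.
#' @param floxing_efficiency excision fraction for floxed intervals.
#' @param correction_level default addback correction level.
#' @param seed integer root seed.
#' @return a validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(n_cpg_clusters = 50L, n_true_dmrs = 5L, seed = 1L)
#' cfg
#' @export
simConfig <- function(genome_length = 2e6,
                      n_cpg_clusters = 400L,
                      cpg_per_cluster_mean = 15,
                      cluster_size_jitter = FALSE,
                      baseline_beta_by_class = c(
                        cpg_island = 0.10, shore = 0.55, shelf = 0.70,
                        promoter = 0.15, gene_body = 0.80, enhancer = 0.70,
                        open_sea = 0.85),
                      n_true_dmrs = 60L,
                      dmr_effect_by_genotype = c(
                        DKO = 0.5, `3aKO` = 0.4, R878H = 0.2, `3bKO` = 0.1),
                      mean_depth = 18.6,
                      depth_dispersion = 0.2,
                      beta_binomial_rho = 0.05,
                      samples_per_group = c(
                        WT = 9L, `3aKO` = 4L, `3bKO` = 3L, DKO = 3L,
                        R878H = 6L),
                      floxing_efficiency = 0.96,
                      correction_level = 1,
                      seed = 1L) {
  new("SimConfig",
      genome_length = as.numeric(genome_length),
      n_cpg_clusters = as.integer(n_cpg_clusters),
      cpg_per_cluster_mean = as.numeric(cpg_per_cluster_mean),
      cluster_size_jitter = isTRUE(cluster_size_jitter),
      baseline_beta_by_class = baseline_beta_by_class,
      n_true_dmrs = as.integer(n_true_dmrs),
      dmr_effect_by_genotype = dmr_effect_by_genotype,
      mean_depth = as.numeric(mean_depth),
      depth_dispersion = as.numeric(depth_dispersion),
      beta_binomial_rho = as.numeric(beta_binomial_rho),
      samples_per_group = setNames(as.integer(samples_per_group),
                                   names(samples_per_group)),
      floxing_efficiency = as.numeric(floxing_efficiency),
      correction_level = as.numeric(correction_level),
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@n_cpg_clusters, "CpG clusters over",
      format(object@genome_length, big.mark = ","), "bp;",
      object@n_true_dmrs, "true DMRs\n")
  cat("  groups:", paste0(names(object@samples_per_group), "=",
                          object@samples_per_group, collapse = ", "), "\n")
  cat("  depth:", object@mean_depth, "(dispersion",
      object@depth_dispersion, "), rho =", object@beta_binomial_rho, "\n")
  cat("  seed:", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## CpGMethylome
## ---------------------------------------------------------------------------

#' Per-CpG methylation counts across samples
#'
#' A \code{RangedSummarizedExperiment} with integer assays \code{meth}
#' (methylated read count) and \code{depth} (total read count) over
#' strand-collapsed CpG dinucleotides (0-based half-open, width 2), and
#' sample metadata columns \code{genotype} and \code{group}. Missing data
#' are encoded as depth 0, never as sentinel beta values.
#'
#' @export
setClass("CpGMethylome", contains = "RangedSummarizedExperiment")

setValidity("CpGMethylome", function(object) {
  msgs <- character()
  if (!all(c("meth", "depth") %in% names(assays(object))))
    return("assays 'meth' and 'depth' are required")
  m <- assay(object, "meth"); d <- assay(object, "depth")
  if (any(m < 0) || any(d < 0)) msgs <- c(msgs, "counts must be non-negative")
  if (any(m > d)) msgs <- c(msgs, "meth_count exceeds depth")
  if (!all(c("genotype", "group") %in% colnames(colData(object))))
    msgs <- c(msgs, "colData must contain 'genotype' and 'group'")
  gr <- rowRanges(object)
  if (length(gr)) {
    o <- order(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr))
    if (!identical(o, seq_along(gr)))
      msgs <- c(msgs, "CpG records must be sorted by (chrom, start)")
    key <- paste(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr))
    if (anyDuplicated(key)) msgs <- c(msgs, "duplicate CpG positions")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CpGMethylome
#'
#' @param gr \code{GRanges} of CpG positions (width-2, 0-based half-open
#'   when on disk; in memory ordinary \code{GRanges} 1-based convention).
#' @param meth,depth integer matrices (CpG x sample).
#' @param sample_info data.frame with columns \code{genotype} and
#'   \code{group}, rownames = sample ids.
#' @return a \linkS4class{CpGMethylome}.
#' @export
CpGMethylome <- function(gr, meth, depth, sample_info) {
  se <- SummarizedExperiment(
    assays = list(meth = meth, depth = depth),
    rowRanges = gr,
    colData = DataFrame(sample_info))
  as(se, "CpGMethylome")
}

#' Accessors for CpGMethylome
#'
#' \code{methCounts} and \code{readDepth} return the count matrices;
#' \code{betaValues} returns methylation fractions with \code{NA} where
#' depth is 0; \code{genotypes} and \code{sampleGroups} return per-sample
#' metadata.
#'
#' @param x a \linkS4class{CpGMethylome}.
#' @return matrix or character vector, matching the accessor.
#' @rdname CpGMethylome-accessors
#' @export
methCounts <- function(x) assay(x, "meth")

#' @rdname CpGMethylome-accessors
#' @export
readDepth <- function(x) assay(x, "depth")

#' @rdname CpGMethylome-accessors
#' @export
betaValues <- function(x) {
  d <- readDepth(x)
  b <- methCounts(x) / d
  b[d == 0] <- NA_real_
  b
}

#' @rdname CpGMethylome-accessors
#' @export
genotypes <- function(x) setNames(as.character(colData(x)$genotype), colnames(x))

#' @rdname CpGMethylome-accessors
#' @export
sampleGroups <- function(x) setNames(as.character(colData(x)$group), colnames(x))

setMethod("show", "CpGMethylome", function(object) {
  cat("CpGMethylome:", nrow(object), "CpGs x", ncol(object), "samples\n")
  tab <- table(sampleGroups(object))
  cat("  groups:", paste0(names(tab), "=", as.integer(tab), collapse = ", "), "\n")
  d <- readDepth(object)
  cat("  mean depth:", round(mean(d), 2), "\n")
})

## ---------------------------------------------------------------------------
## AnnotationTrack
## ---------------------------------------------------------------------------

#' Labeled genomic intervals
#'
#' A \code{GRanges} whose metadata column \code{class_label} assigns each
#' interval to a declared vocabulary (CpG island / shore / shelf / promoter
#' / gene body / enhancer / open sea; floxed intervals).
#'
#' @export
setClass("AnnotationTrack", contains = "GRanges")

setValidity("AnnotationTrack", function(object) {
  if (!"class_label" %in% colnames(mcols(object)))
    return("metadata column 'class_label' is required")
  TRUE
})

#' Construct an AnnotationTrack
#'
#' @param gr a \code{GRanges}.
#' @param class_label character vector of labels (recycled); if missing,
#'   \code{gr} must already carry a \code{class_label} column.
#' @return an \linkS4class{AnnotationTrack}, sorted.
#' @export
annotationTrack <- function(gr, class_label = NULL) {
  if (!is.null(class_label)) mcols(gr)$class_label <- rep_len(class_label, length(gr))
  as(sort(gr), "AnnotationTrack")
}

## ---------------------------------------------------------------------------
## DMRSet
## ---------------------------------------------------------------------------

#' A set of differentially methylated regions
#'
#' A \code{GRanges} with one range per DMR and required metadata columns
#' \code{n_cpg}, \code{mean_beta_A}, \code{mean_beta_B}, \code{diff}
#' (A - B), \code{p_value}, \code{q_value} and \code{direction}
#' ("hypo"/"hyper", orientation of B relative to A). The comparison label
#' (e.g. \code{"WT_vs_3aKO"}) lives in \code{metadata()$comparison_label}.
#'
#' @export
setClass("DMRSet", contains = "GRanges")

.dmr_cols <- c("n_cpg", "mean_beta_A", "mean_beta_B", "diff",
               "p_value", "q_value", "direction")

setValidity("DMRSet", function(object) {
  msgs <- character()
  miss <- setdiff(.dmr_cols, colnames(mcols(object)))
  if (length(miss))
    return(paste("missing DMR columns:", paste(miss, collapse = ", ")))
  if (length(object)) {
    mc <- mcols(object)
    if (any(mc$n_cpg < 1)) msgs <- c(msgs, "n_cpg must be >= 1")
    for (col in c("p_value", "q_value"))
      if (any(mc[[col]] < 0 | mc[[col]] > 1, na.rm = TRUE))
        msgs <- c(msgs, paste(col, "outside [0,1]"))
    if (!all(mc$direction %in% c("hypo", "hyper")))
      msgs <- c(msgs, "direction must be 'hypo' or 'hyper'")
    ## hypo means group B lost methylation relative to A: diff = A - B > 0
    bad <- (mc$direction == "hypo" & mc$diff < 0) |
           (mc$direction == "hyper" & mc$diff > 0)
    if (any(bad)) msgs <- c(msgs, "direction inconsistent with sign of diff")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a DMRSet
#'
#' @param gr \code{GRanges} carrying the required DMR metadata columns.
#' @param comparison_label character scalar naming the two-group comparison.
#' @return a \linkS4class{DMRSet}, sorted.
#' @export
DMRSet <- function(gr, comparison_label = "A_vs_B") {
  out <- as(sort(gr), "DMRSet")
  metadata(out)$comparison_label <- comparison_label
  out
}

#' @describeIn DMRSet comparison label accessor.
#' @param x a \code{DMRSet}.
#' @export
comparisonLabel <- function(x) metadata(x)$comparison_label

setMethod("show", "DMRSet", function(object) {
  cat("DMRSet '", comparisonLabel(object), "': ", length(object),
      " DMRs\n", sep = "")
  if (length(object)) {
    cat("  hypo:", sum(mcols(object)$direction == "hypo"),
        " hyper:", sum(mcols(object)$direction == "hyper"), "\n")
    cat("  mean width:", round(mean(GenomicRanges::width(object)), 1),
        "bp; mean CpGs:", round(mean(mcols(object)$n_cpg), 1), "\n")
  }
})

## ---------------------------------------------------------------------------
## IsoformModel
## ---------------------------------------------------------------------------

#' Junction-level isoform model
#'
#' Maps named splice junctions to the isoform they support. Inclusion
#' junctions support the isoform of interest; alternative junctions support
#' the competing isoform(s) and are aggregated by \code{sum} or \code{mean}
#' before the usage fraction is formed (the exon 21-24 junction set of
#' Dnmt3b1 is aggregated by mean).
#'
#' @slot isoform_name name of the isoform supported by inclusion junctions.
#' @slot inclusion_junctions character vector of junction ids.
#' @slot alternative_junctions character vector of junction ids.
#' @slot alternative_aggregation "sum" or "mean".
#' @export
setClass("IsoformModel", representation(
  isoform_name = "character",
  inclusion_junctions = "character",
  alternative_junctions = "character",
  alternative_aggregation = "character"
))

setValidity("IsoformModel", function(object) {
  msgs <- character()
  if (!length(object@inclusion_junctions) || !length(object@alternative_junctions))
    msgs <- c(msgs, "both junction sets must be non-empty")
  if (length(intersect(object@inclusion_junctions, object@alternative_junctions)))
    msgs <- c(msgs, "junction id sets must be disjoint")
  if (!object@alternative_aggregation %in% c("sum", "mean"))
    msgs <- c(msgs, "alternative_aggregation must be 'sum' or 'mean'")
  if (length(msgs)) msgs else TRUE
})

#' Construct an IsoformModel
#'
#' @param isoform_name isoform supported by the inclusion junctions.
#' @param inclusion_junctions character vector of junction ids.
#' @param alternative_junctions character vector of junction ids.
#' @param alternative_aggregation "sum" (default) or "mean".
#' @return an \linkS4class{IsoformModel}.
#' @examples
#' isoformModel("Dnmt3a1", "e6_e7", "utr_e7")
#' @export
isoformModel <- function(isoform_name, inclusion_junctions,
                         alternative_junctions,
                         alternative_aggregation = c("sum", "mean")) {
  new("IsoformModel",
      isoform_name = isoform_name,
      inclusion_junctions = inclusion_junctions,
      alternative_junctions = alternative_junctions,
      alternative_aggregation = match.arg(alternative_aggregation))
}

setMethod("show", "IsoformModel", function(object) {
  cat("IsoformModel '", object@isoform_name, "': ",
      length(object@inclusion_junctions), " inclusion vs ",
      length(object@alternative_junctions), " alternative junctions (",
      object@alternative_aggregation, ")\n", sep = "")
})
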