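## Synthetic splice-junction counts and PSM-level proteomics tables.

#' Simulate a splice-junction count table
#'
#' Per sample, reads supporting the inclusion junction(s) are drawn as
#' Binomial(\code{junction_depth}, usage) and the remainder is assigned to
#' the alternative junction(s): split multinomially when the model
#' aggregates alternatives by \code{sum}, or written identically to each
#' alternative junction when it aggregates by \code{mean} (so that the
#' mean count equals the remainder).
#'
#' @param usage_by_group named numeric, true isoform usage per group
#'   (default: the usage levels the package's examples target, 0.886 in WT
#'   and 0.885 in R878H).
#' @param junction_depth total junction-spanning reads per sample.
#' @param n_samples named integer, samples per group (default WT=10,
#'   R878H=12).
#' @param model an \linkS4class{IsoformModel}.
#' @param seed integer seed.
#' @return data.frame with columns \code{sample}, \code{group},
#'   \code{junction_id}, \code{count}, plus attribute \code{truth}
#'   (the usage_by_group vector).
#' @export
simulateJunctionCounts <- function(usage_by_group = c(WT = 0.886,
                                                      R878H = 0.885),
                                   junction_depth = 200L,
                                   n_samples = c(WT = 10L, R878H = 12L),
                                   model = isoformModel(
                                     "Dnmt3a1", "e6_e7", "utr_e7"),
                                   seed = 1L) {
  stopifnot(all(usage_by_group >= 0 & usage_by_group <= 1),
            identical(sort(names(usage_by_group)), sort(names(n_samples))))
  rows <- with_seed(seed, {
    out <- list()
    for (g in names(usage_by_group)) {
      for (i in seq_len(n_samples[[g]])) {
        sid <- sprintf("%s_%02d", g, i)
        inc_total <- rbinom(1L, junction_depth, usage_by_group[[g]])
        rem <- junction_depth - inc_total
        inc <- model@inclusion_junctions
        inc_counts <- if (length(inc) == 1L) inc_total else
          as.vector(stats::rmultinom(1L, inc_total,
                                     rep(1, length(inc))))
        alt <- model@alternative_junctions
        alt_counts <- if (model@alternative_aggregation == "sum") {
          if (length(alt) == 1L) rem else
            as.vector(stats::rmultinom(1L, rem, rep(1, length(alt))))
        } else rep(rem, length(alt))
        out[[sid]] <- data.frame(
          sample = sid, group = g,
          junction_id = c(inc, alt),
          count = c(inc_counts, alt_counts))
      }
    }
    out
  })
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(res, "truth") <- usage_by_group
  res
}

#' Simulate a PSM-level precursor intensity table with known truth
#'
#' Log2 intensities follow \code{protein base + peptide offset +
#' scale * (protein effect + PSM noise) + sample shift}; a fraction
#' \code{outlier_rate} of precursor-sample cells is displaced by
#' \code{outlier_sd} standard deviations (random sign). Protein effects: a
#' fraction \code{frac_diff} of proteins varies biologically across
#' samples (per-sample log2 deviations drawn from N(0, \code{effect_sd}));
#' the rest are null, so every sample's log2FC distribution is a
#' two-component mixture whose dominant mode sits at the sample shift.
#'
#' The returned truth records the quantities the ratio pipeline can
#' identify: per-sample shifts re-expressed relative to the
#' average-precursor reference (\code{shift_identifiable}) and the
#' noiseless protein log2FC matrix under the same reference
#' (\code{protein_log2fc}).
#'
#' @param n_proteins number of proteins.
#' @param peptides_per_protein peptides per protein (scalar or per-protein
#'   vector).
#' @param psm_per_peptide PSMs per peptide; Dixon's test needs > 2, and at
#'   small n its critical values are large, so the default is 6.
#' @param sample_shifts named numeric of per-sample log2 shifts.
#' @param sample_scales named numeric of per-sample spread multipliers.
#' @param outlier_rate fraction of precursor-sample cells displaced.
#' @param outlier_sd displacement in units of \code{psm_sd} (default 8).
#' @param psm_sd PSM-level log2 noise SD.
#' @param peptide_sd SD of per-peptide offsets.
#' @param frac_diff fraction of biologically varying proteins.
#' @param effect_sd SD of per-sample protein-level deviations (log2).
#' @param base_mean,base_sd log2 abundance distribution of proteins.
#' @param lengths optional named per-protein lengths (residues) recorded
#'   for stoichiometry; default 300-1500 uniformly.
#' @param molar optional named per-protein molar abundance multiplier
#'   applied to the protein base intensity (for co-purification
#'   stoichiometry simulations); default 1.
#' @param seed integer seed.
#' @return list(psm = data.frame, truth = list(sample_shifts,
#'   shift_identifiable, protein_log2fc, outliers, lengths, molar,
#'   sample_scales)).
#' @export
simulatePSMTable <- function(n_proteins = 300L,
                             peptides_per_protein = 4L,
                             psm_per_peptide = 6L,
                             sample_shifts = c(S1 = 0, S2 = 0, S3 = 0,
                                               S4 = 0, S5 = 0, S6 = 0),
                             sample_scales = NULL,
                             outlier_rate = 0,
                             outlier_sd = 8,
                             psm_sd = 0.2,
                             peptide_sd = 0.15,
                             frac_diff = 0.2,
                             effect_sd = 1,
                             base_mean = 20,
                             base_sd = 2,
                             lengths = NULL,
                             molar = NULL,
                             seed = 1L) {
  stopifnot(outlier_rate >= 0, outlier_rate < 1)
  samples <- names(sample_shifts)
  ns <- length(samples)
  if (is.null(sample_scales)) sample_scales <- setNames(rep(1, ns), samples)
  sample_scales <- sample_scales[samples]
  with_seed(seed, {
    prot <- sprintf("P%04d", seq_len(n_proteins))
    npep <- rep_len(peptides_per_protein, n_proteins)
    if (is.null(lengths)) lengths <- setNames(
      sample(300:1500, n_proteins, replace = TRUE), prot)
    else names(lengths) <- prot
    if (is.null(molar)) molar <- setNames(rep(1, n_proteins), prot)
    else names(molar) <- prot
    base <- rnorm(n_proteins, base_mean, base_sd) + log2(molar)
    is_diff <- runif(n_proteins) < frac_diff
    t_mat <- matrix(0, n_proteins, ns, dimnames = list(prot, samples))
    t_mat[is_diff, ] <- rnorm(sum(is_diff) * ns, 0, effect_sd)

    rows <- vector("list", n_proteins)
    out_flags <- vector("list", n_proteins)
    for (p in seq_len(n_proteins)) {
      pep_ids <- sprintf("%s_pep%02d", prot[p], seq_len(npep[p]))
      pep_off <- rnorm(npep[p], 0, peptide_sd)
      prec <- expand.grid(pep = seq_len(npep[p]),
                          psm = seq_len(psm_per_peptide))
      nprec <- nrow(prec)
      eps <- matrix(rnorm(nprec * ns, 0, psm_sd), nprec, ns)
      is_out <- matrix(runif(nprec * ns) < outlier_rate, nprec, ns)
      eps[is_out] <- eps[is_out] +
        sample(c(-1, 1), sum(is_out), TRUE) * outlier_sd * psm_sd
      dev <- sweep(eps + outer(rep(1, nprec), t_mat[p, ]), 2,
                   sample_scales, `*`)
      l2 <- base[p] + pep_off[prec$pep] + sweep(dev, 2, sample_shifts, `+`)
      rows[[p]] <- data.frame(
        protein_id = prot[p],
        peptide_id = pep_ids[prec$pep],
        psm_id = sprintf("%s_psm%d", pep_ids[prec$pep], prec$psm),
        sample_id = rep(samples, each = nprec),
        intensity = 2 ^ as.vector(l2))
      out_flags[[p]] <- data.frame(
        psm_id = sprintf("%s_psm%d", pep_ids[prec$pep], prec$psm),
        sample_id = rep(samples, each = nprec),
        outlier = as.vector(is_out))
    }
    psm <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    outliers <- do.call(rbind, c(out_flags, list(make.row.names = FALSE)))

    ## identifiable truth under the average-precursor reference: for a
    ## protein with noiseless per-sample deviation t_eff and shift s,
    ## r = (t_eff + s) - log2(mean_s 2^(t_eff + s)); the mode alignment
    ## (dominated by null proteins) subtracts s - log2(mean_s 2^s).
    t_eff <- sweep(t_mat, 2, sample_scales, `*`)
    shift_ident <- sample_shifts - log2(mean(2 ^ sample_shifts))
    lin <- 2 ^ sweep(t_eff, 2, sample_shifts, `+`)
    r_true <- log2(lin / rowMeans(lin))
    prot_l2fc <- sweep(r_true, 2, shift_ident, `-`)

    list(psm = psm,
         truth = list(sample_shifts = sample_shifts,
                      shift_identifiable = shift_ident,
                      protein_log2fc = prot_l2fc,
                      outliers = outliers[outliers$outlier, , drop = FALSE],
                      lengths = lengths,
                      molar = molar,
                      sample_scales = sample_scales))
  })
}
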