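## Splice-junction isoform usage and two-group comparison.

.junction_counts <- function(counts, model, samples) {
  get <- function(s, ids) {
    v <- vapply(ids, function(j) {
      hit <- counts$count[counts$sample == s & counts$junction_id == j]
      if (!length(hit)) {
        msg("junction '", j, "' absent in sample ", s, "; counted as 0")
        0
      } else sum(hit)
    }, numeric(1))
    v
  }
  inc <- vapply(samples, function(s) sum(get(s, model@inclusion_junctions)),
                numeric(1))
  alt <- vapply(samples, function(s) {
    a <- get(s, model@alternative_junctions)
    if (model@alternative_aggregation == "sum") sum(a) else mean(a)
  }, numeric(1))
  list(inc = inc, alt = alt)
}

#' Isoform usage from junction counts
#'
#' Usage is the number of reads supporting the inclusion junction(s) over
#' the total supporting both junction sets:
#' \code{u = J_inc / (J_inc + J_alt)}, with the alternative junctions
#' aggregated by sum or mean according to the model. Absent junctions are
#' counted as 0 (logged); \code{J_inc + J_alt = 0} yields NA (logged).
#'
#' @param counts junction count data.frame (\code{sample},
#'   \code{junction_id}, \code{count}).
#' @param model an \linkS4class{IsoformModel}.
#' @param per_sample return per-sample usages (default TRUE); otherwise a
#'   single pooled usage over summed counts.
#' @return named numeric vector of usages (or pooled scalar).
#' @export
isoformPercentage <- function(counts, model, per_sample = TRUE) {
  samples <- unique(counts$sample)
  if (!per_sample) {
    pooled <- counts
    pooled$sample <- "pooled"
    samples <- "pooled"
    counts <- stats::aggregate(count ~ sample + junction_id, pooled, sum)
  }
  jc <- .junction_counts(counts, model, samples)
  tot <- jc$inc + jc$alt
  u <- ifelse(tot > 0, jc$inc / tot, NA_real_)
  if (anyNA(u)) msg(sum(is.na(u)), " samples with zero junction reads")
  setNames(u, samples)
}

#' Two-group isoform usage comparison (Fisher's exact test on pooled
#' counts)
#'
#' Counts are pooled (summed) across samples within each group; the
#' resulting 2x2 table (inclusion vs alternative x group) is tested with
#' a two-sided Fisher's exact test (minimum-likelihood rule). When the
#' model aggregates alternative junctions by mean, the non-integer pooled
#' alternative count is rounded half-to-even before testing (logged).
#' The odds ratio is the sample OR, with a Haldane 0.5 correction when
#' any cell is zero (flagged).
#'
#' @param counts_A,counts_B junction count data.frames for the two groups.
#' @param model an \linkS4class{IsoformModel}.
#' @return list with \code{table} (2x2 integer matrix), \code{usage}
#'   (pooled usage per group), \code{odds_ratio}, \code{haldane},
#'   \code{p_value}.
#' @export
compareUsage <- function(counts_A, counts_B, model) {
  pool <- function(counts, label) {
    if (!nrow(counts)) stop("empty group: ", label)
    if (any(counts$count < 0) || any(counts$count != round(counts$count)))
      stop("counts must be non-negative integers")
    sums <- tapply(counts$count, counts$junction_id, sum)
    pooled <- data.frame(sample = "pooled",
                         junction_id = names(sums),
                         count = as.numeric(sums))
    jc <- .junction_counts(pooled, model, "pooled")
    if (jc$alt != round(jc$alt))
      msg("pooled alternative count ", jc$alt,
          " rounded half-to-even for the exact test")
    c(inc = unname(jc$inc), alt = unname(round_half_even(jc$alt)))
  }
  a <- pool(counts_A, "A"); b <- pool(counts_B, "B")
  tab <- matrix(c(a["inc"], a["alt"], b["inc"], b["alt"]), 2L, 2L,
                byrow = TRUE,
                dimnames = list(group = c("A", "B"),
                                junction = c("inclusion", "alternative")))
  ft <- fisher.test(tab, alternative = "two.sided")
  zero <- any(tab == 0)
  or <- if (zero) ((tab[1, 1] + 0.5) * (tab[2, 2] + 0.5)) /
                  ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
        else (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(table = tab,
       usage = c(A = unname(a["inc"] / sum(a)), B = unname(b["inc"] / sum(b))),
       odds_ratio = unname(or), haldane = zero,
       p_value = ft$p.value)
}
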