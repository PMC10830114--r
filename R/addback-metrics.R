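## Quantification of DMR remethylation after methyltransferase addback.

#' Per-DMR extent of methylation correction
#'
#' For each DMR, the methylation difference between addback and knockout
#' scaled by the difference between wild type and knockout:
#' \code{extent = (beta_addback - beta_ko) / (beta_wt - beta_ko)}.
#' 1 means remethylation to WT level, 0 no change from the knockout.
#' DMRs whose WT-KO contrast is smaller than \code{epsilon} are masked
#' (the ratio is undefined there); extents are never clipped, so values
#' above 1 (methylation beyond WT) are preserved.
#'
#' @param passive_wt,passive_ko,passive_addback named numeric vectors of
#'   per-DMR group-mean betas on the same DMR set (e.g. rows of a
#'   \code{\link{passiveMethylation}} matrix averaged per group).
#' @param epsilon minimum absolute WT-KO contrast (default 0.05).
#' @return data.frame with columns \code{dmr_id}, \code{beta_wt},
#'   \code{beta_ko}, \code{beta_addback}, \code{extent}, \code{masked}.
#' @export
correctionExtent <- function(passive_wt, passive_ko, passive_addback,
                             epsilon = 0.05) {
  ids <- names(passive_wt)
  if (is.null(ids)) ids <- sprintf("dmr_%05d", seq_along(passive_wt))
  if (!is.null(names(passive_ko)) &&
      !identical(names(passive_ko), names(passive_wt)) ||
      !is.null(names(passive_addback)) &&
      !identical(names(passive_addback), names(passive_wt)))
    stop("misaligned DMR ids across the three inputs")
  if (length(passive_ko) != length(passive_wt) ||
      length(passive_addback) != length(passive_wt))
    stop("inputs must align on the same DMR set")
  contrast <- passive_wt - passive_ko
  masked <- is.na(contrast) | abs(contrast) < epsilon |
    is.na(passive_addback)
  extent <- ifelse(masked, NA_real_,
                   (passive_addback - passive_ko) / contrast)
  n_masked <- sum(masked)
  if (n_masked) msg(n_masked, " DMRs masked (|WT - KO| < ", epsilon, ")")
  data.frame(dmr_id = ids, beta_wt = unname(passive_wt),
             beta_ko = unname(passive_ko),
             beta_addback = unname(passive_addback),
             extent = unname(extent), masked = unname(masked))
}

#' Distribution summary of correction extents
#'
#' Mean, median, quartiles and a density grid over unmasked records only.
#'
#' @param records data.frame from \code{\link{correctionExtent}}.
#' @param density_n grid size for the density estimate (default 256).
#' @return list with \code{n}, \code{n_masked}, \code{mean},
#'   \code{median}, \code{q25}, \code{q75}, and \code{density}
#'   (data.frame x/y).
#' @export
extentSummary <- function(records, density_n = 256L) {
  x <- records$extent[!records$masked]
  if (!length(x)) stop("all records are masked")
  dens <- stats::density(x, n = density_n)
  list(n = length(x), n_masked = sum(records$masked),
       mean = mean(x), median = median(x),
       q25 = unname(quantile(x, 0.25)), q75 = unname(quantile(x, 0.75)),
       density = data.frame(x = dens$x, y = dens$y))
}

#' Paired extents of two addbacks over the same DMRs
#'
#' @param records_a,records_b data.frames from
#'   \code{\link{correctionExtent}} on the same DMR set.
#' @param labels length-2 character, column labels.
#' @return data.frame with one row per DMR unmasked in both, columns
#'   \code{dmr_id} and one extent column per addback.
#' @export
pairedExtents <- function(records_a, records_b,
                          labels = c("addback_A", "addback_B")) {
  if (!identical(records_a$dmr_id, records_b$dmr_id))
    stop("records are not aligned on the same DMR set")
  keep <- !records_a$masked & !records_b$masked
  out <- data.frame(dmr_id = records_a$dmr_id[keep],
                    a = records_a$extent[keep],
                    b = records_b$extent[keep])
  names(out)[2:3] <- labels
  out
}
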