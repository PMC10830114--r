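## PSM-to-protein ratio pipeline: log2FC conversion relative to the
## average precursor intensity, recursive Dixon outlier removal, median
## roll-ups, two-component Gaussian-mixture mode alignment, trimmed-SD
## scaling, 2^d intensity calibration, and co-purification stoichiometry.

#' Convert PSM intensities to log2 ratios
#'
#' Each precursor (protein/peptide/psm triplet) is converted to
#' \code{log2(I / mean(I))}, the mean taken over the samples in which the
#' precursor was observed (arithmetic by default; geometric available).
#'
#' @param psm PSM data.frame (\code{protein_id}, \code{peptide_id},
#'   \code{psm_id}, \code{sample_id}, \code{intensity}).
#' @param mean_type "arithmetic" (default) or "geometric".
#' @return the input with a \code{log2fc} column appended.
#' @export
psmLog2FC <- function(psm, mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  if (any(psm$intensity <= 0)) stop("non-positive intensity")
  key <- paste(psm$protein_id, psm$peptide_id, psm$psm_id, sep = "\r")
  ref <- if (mean_type == "arithmetic")
    ave_by(psm$intensity, key, mean)
  else 2 ^ ave_by(log2(psm$intensity), key, mean)
  psm$log2fc <- log2(psm$intensity / ref)
  psm
}

## group-wise transform that returns a vector aligned with x
ave_by <- function(x, g, fun) {
  sp <- split(x, g)
  v <- vapply(sp, fun, numeric(1))
  unsplit(lapply(seq_along(sp), function(i) rep(v[i], length(sp[[i]]))), g)
}

## Two-sided Dixon critical values at alpha = 0.05, n = 3..30, following
## the standard r10 (n<=7) / r11 (8-10) / r21 (11-13) / r22 (14-30)
## schedule (Rorabacher 1991, 95% confidence, two-tailed). The classic
## Dean & Dixon Q table (one-sided 95%) is available as an option for
## n <= 7.
.dixon_crit_two_sided <- c(
  `3` = 0.970, `4` = 0.829, `5` = 0.710, `6` = 0.625, `7` = 0.568,
  `8` = 0.615, `9` = 0.570, `10` = 0.534,
  `11` = 0.625, `12` = 0.592, `13` = 0.565,
  `14` = 0.590, `15` = 0.568, `16` = 0.548, `17` = 0.531, `18` = 0.516,
  `19` = 0.503, `20` = 0.491, `21` = 0.480, `22` = 0.470, `23` = 0.461,
  `24` = 0.452, `25` = 0.445, `26` = 0.438, `27` = 0.432, `28` = 0.426,
  `29` = 0.419, `30` = 0.414)
.dixon_crit_one_sided <- c(
  `3` = 0.941, `4` = 0.765, `5` = 0.642, `6` = 0.560, `7` = 0.507)

.dixon_ratio <- function(x_sorted, n) {
  ## ratio for the maximum of a sorted sample; reverse+negate for minimum
  if (n <= 7) (x_sorted[n] - x_sorted[n - 1]) / (x_sorted[n] - x_sorted[1])
  else if (n <= 10)
    (x_sorted[n] - x_sorted[n - 1]) / (x_sorted[n] - x_sorted[2])
  else if (n <= 13)
    (x_sorted[n] - x_sorted[n - 2]) / (x_sorted[n] - x_sorted[2])
  else (x_sorted[n] - x_sorted[n - 2]) / (x_sorted[n] - x_sorted[3])
}

#' Recursive Dixon outlier removal
#'
#' Computes Dixon's ratio for the more extreme of the sample minimum and
#' maximum (r10 for n <= 7, r11/r21/r22 variants for larger n), removes
#' the value if the ratio exceeds the tabulated critical value, and
#' recurses; stops when nothing is removed or fewer than 3 values remain
#' (so at most n - 3 values are ever removed, in a deterministic order).
#'
#' @param values numeric vector, 3 <= n <= 30 (above 30, an error directs
#'   to \code{allow_large}; with \code{allow_large = TRUE} the n = 30
#'   critical value is used).
#' @param alpha only 0.05 is tabulated.
#' @param table "two_sided" (default; Rorabacher 1991 95% two-tailed) or
#'   "one_sided" (classic Dean & Dixon Q95, n <= 7 only, larger n fall
#'   back to the two-sided schedule).
#' @param allow_large opt-in for n > 30.
#' @return list with \code{kept} and \code{removed} numeric vectors.
#' @export
dixonFilter <- function(values, alpha = 0.05,
                        table = c("two_sided", "one_sided"),
                        allow_large = FALSE) {
  table <- match.arg(table)
  if (alpha != 0.05) stop("only alpha = 0.05 critical values are tabulated")
  if (length(values) > 30 && !allow_large)
    stop("n > 30 exceeds the tabulated range; set allow_large = TRUE to ",
         "test at the n = 30 critical value")
  crit_of <- function(n) {
    n_eff <- min(n, 30L)
    if (table == "one_sided" && n_eff <= 7)
      .dixon_crit_one_sided[[as.character(n_eff)]]
    else .dixon_crit_two_sided[[as.character(n_eff)]]
  }
  kept <- values
  removed <- numeric()
  repeat {
    n <- length(kept)
    if (n < 3) break
    s <- sort(kept)
    if (s[n] == s[1]) break
    q_max <- .dixon_ratio(s, n)
    q_min <- .dixon_ratio(rev(-s), n)
    if (q_max >= q_min) { q <- q_max; victim <- s[n] }
    else { q <- q_min; victim <- s[1] }
    if (q > crit_of(n)) {
      removed <- c(removed, victim)
      kept <- kept[-match(victim, kept)]
    } else break
  }
  list(kept = kept, removed = removed)
}

#' Median roll-ups from PSM to peptide to protein
#'
#' Per sample, the median PSM log2FC represents its peptide and the
#' median peptide log2FC represents the protein. Dixon filtering is
#' applied beforehand within each (sample, peptide) PSM group with more
#' than two PSMs when \code{dixon_alpha} is not NULL.
#'
#' @param psm PSM data.frame with a \code{log2fc} column (see
#'   \code{\link{psmLog2FC}}).
#' @param dixon_alpha alpha for the Dixon stage (default 0.05; NULL
#'   disables it).
#' @param dixon_table critical-value table, see \code{\link{dixonFilter}}.
#' @return list with \code{peptide} (sample, protein, peptide, log2fc,
#'   n_psm, n_removed) and \code{protein} (sample, protein, log2fc,
#'   n_peptide) data.frames.
#' @export
rollupMedians <- function(psm, dixon_alpha = 0.05,
                          dixon_table = "two_sided") {
  stopifnot("log2fc" %in% colnames(psm))
  key <- paste(psm$sample_id, psm$protein_id, psm$peptide_id, sep = "\r")
  groups <- split(psm$log2fc, key)
  pep_rows <- lapply(names(groups), function(k) {
    v <- groups[[k]]
    removed <- 0L
    if (!is.null(dixon_alpha) && length(v) > 2) {
      dx <- dixonFilter(v, dixon_alpha, dixon_table,
                        allow_large = length(v) > 30)
      removed <- length(dx$removed)
      v <- dx$kept
    }
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    data.frame(sample_id = parts[1], protein_id = parts[2],
               peptide_id = parts[3], log2fc = median(v),
               n_psm = length(v) + removed, n_removed = removed)
  })
  pep <- do.call(rbind, c(pep_rows, list(make.row.names = FALSE)))
  pkey <- paste(pep$sample_id, pep$protein_id, sep = "\r")
  prot_l2 <- vapply(split(pep$log2fc, pkey), median, numeric(1))
  n_pep <- vapply(split(pep$log2fc, pkey), length, integer(1))
  parts <- do.call(rbind, strsplit(names(prot_l2), "\r", fixed = TRUE))
  prot <- data.frame(sample_id = parts[, 1], protein_id = parts[, 2],
                     log2fc = unname(prot_l2), n_peptide = unname(n_pep))
  list(peptide = pep, protein = prot)
}

## Two-component univariate Gaussian mixture by EM. Deterministic:
## quantile initialization, loglik tolerance 1e-8, max 1000 iterations.
.em2 <- function(x, tol = 1e-8, max_iter = 1000L) {
  mu <- unname(quantile(x, c(0.25, 0.75)))
  if (mu[1] == mu[2]) mu <- mu + c(-1, 1) * max(sd(x), 1e-3) / 2
  sigma <- rep(max(sd(x), 1e-6), 2)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], sigma[1])
    d2 <- w[2] * dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    g <- d1 / tot
    w <- c(mean(g), 1 - mean(g))
    if (min(w) < 1e-3) return(NULL)
    mu <- c(sum(g * x) / sum(g), sum((1 - g) * x) / sum(1 - g))
    sigma <- sqrt(c(sum(g * (x - mu[1])^2) / sum(g),
                    sum((1 - g) * (x - mu[2])^2) / sum(1 - g)))
    if (any(sigma^2 < 1e-8)) return(NULL)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(w = w, mu = mu, sigma = sigma, loglik = ll)
}

## Global mode of the fitted density on a 4096-point grid spanning the
## data range +/- 1 SD, refined by golden-section search.
.mixture_mode <- function(fit, x) {
  dens <- function(t) fit$w[1] * dnorm(t, fit$mu[1], fit$sigma[1]) +
    fit$w[2] * dnorm(t, fit$mu[2], fit$sigma[2])
  s <- sd(x)
  grid <- seq(min(x) - s, max(x) + s, length.out = 4096L)
  i <- which.max(dens(grid))
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  optimize(dens, c(lo, hi), maximum = TRUE)$maximum
}

#' Mode alignment of per-sample protein log2FC distributions
#'
#' Fits a two-component Gaussian mixture to one sample's protein log2FC
#' values by deterministic EM (quantile initialization, tolerance 1e-8,
#' at most 1000 iterations), locates the global mode of the fitted
#' density, and shifts the values so that the mode sits at zero. If the
#' EM degenerates (component weight below 1e-3 or variance below 1e-8)
#' a single Gaussian is fitted instead (logged) and the mode is its mean.
#'
#' @param values numeric vector of one sample's protein log2FC.
#' @param min_proteins refuse to fit below this many values (default 20).
#' @param mode_type "density_mode" (default: global mode of the mixture
#'   density) or "dominant_mean" (mean of the heavier component).
#' @return list with \code{shift} (the additive shift d applied),
#'   \code{aligned} (values + shift), \code{fit}.
#' @export
mixtureAlign <- function(values, min_proteins = 20L,
                         mode_type = c("density_mode", "dominant_mean")) {
  mode_type <- match.arg(mode_type)
  x <- values[!is.na(values)]
  if (length(x) < min_proteins)
    stop("need at least ", min_proteins, " proteins per sample")
  fit <- .em2(x)
  if (is.null(fit)) {
    msg("EM degenerate; falling back to a single Gaussian")
    fit <- list(w = c(1, 0), mu = rep(mean(x), 2), sigma = rep(sd(x), 2))
    mode <- mean(x)
  } else {
    mode <- if (mode_type == "density_mode") .mixture_mode(fit, x)
            else fit$mu[which.max(fit$w)]
  }
  list(shift = -mode, aligned = values - mode, fit = fit)
}

#' Trimmed-SD scaling normalization across samples
#'
#' Standardizes the spread of aligned protein log2FC across samples. Per
#' sample, the SD is computed over the proteins lying inside both trim
#' windows: log2FC within its own [P5, P95] and intensity within its
#' [P5, P95] (intersection by default; union available). Each sample is
#' scaled by reference SD / sample SD, the reference being the median of
#' the per-sample trimmed SDs.
#'
#' @param aligned numeric matrix protein x sample of aligned log2FC.
#' @param intensity numeric matrix protein x sample of raw protein
#'   intensities.
#' @param trim_mode "intersection" (default) or "union" of the two
#'   percentile windows.
#' @param min_trimmed error if fewer than this many proteins survive the
#'   trim in any sample (default 10).
#' @return list with \code{scaled} matrix, \code{scale} per-sample
#'   factors, \code{trimmed_sd} per-sample SDs, and \code{trimmed}
#'   logical matrix marking the proteins inside the trim window per
#'   sample.
#' @export
scaleNormalize <- function(aligned, intensity,
                           trim_mode = c("intersection", "union"),
                           min_trimmed = 10L) {
  trim_mode <- match.arg(trim_mode)
  stopifnot(identical(dim(aligned), dim(intensity)))
  trimmed <- matrix(FALSE, nrow(aligned), ncol(aligned),
                    dimnames = dimnames(aligned))
  sds <- vapply(seq_len(ncol(aligned)), function(j) {
    x <- aligned[, j]; i <- intensity[, j]
    ok <- !is.na(x) & !is.na(i)
    qx <- quantile(x[ok], c(0.05, 0.95))
    qi <- quantile(i[ok], c(0.05, 0.95))
    in_x <- x >= qx[1] & x <= qx[2]
    in_i <- i >= qi[1] & i <= qi[2]
    keep <- ok & if (trim_mode == "intersection") in_x & in_i
                 else in_x | in_i
    if (sum(keep) < min_trimmed)
      stop("fewer than ", min_trimmed, " proteins inside the trim window")
    trimmed[, j] <<- keep
    sd(x[keep])
  }, numeric(1))
  ref <- median(sds)
  sc <- ref / sds
  scaled <- sweep(aligned, 2, sc, `*`)
  list(scaled = scaled, scale = setNames(sc, colnames(aligned)),
       trimmed_sd = setNames(sds, colnames(aligned)), trimmed = trimmed)
}

#' Calibrate protein intensities by the normalization distance
#'
#' \code{I' = I * 2^d} where d is the distance between the protein
#' log2FC after and before ratio normalization, per protein and sample.
#'
#' @param raw_intensity numeric matrix protein x sample.
#' @param d numeric matrix of log2FC distances (final - raw).
#' @return calibrated intensity matrix.
#' @export
calibrateIntensities <- function(raw_intensity, d) {
  stopifnot(identical(dim(raw_intensity), dim(d)))
  raw_intensity * 2 ^ d
}

#' Full PSM-to-protein ratio normalization pipeline
#'
#' Runs, in order: log2FC conversion relative to the average precursor
#' intensity; recursive Dixon outlier removal within each
#' (sample, peptide) PSM group with more than two PSMs; median roll-ups
#' PSM -> peptide -> protein; two-component Gaussian-mixture mode
#' alignment per sample; trimmed-SD scaling across samples; and 2^d
#' intensity calibration, d being the total log2FC displacement of the
#' normalization. Protein raw intensity is the sum of the protein's PSM
#' intensities per sample.
#'
#' @param psm PSM data.frame (see \code{\link{readPSMTable}}).
#' @param dixon_alpha Dixon stage alpha (default 0.05, NULL disables).
#' @param mean_type precursor reference mean, "arithmetic" or
#'   "geometric".
#' @param trim_mode,min_trimmed see \code{\link{scaleNormalize}}.
#' @param min_proteins see \code{\link{mixtureAlign}}.
#' @return list with \code{protein} (long data.frame: protein_id,
#'   sample_id, log2fc_raw, log2fc_aligned, log2fc_scaled, shift_d,
#'   raw_intensity, calibrated_intensity), \code{sample_shift}
#'   (per-sample mixture shift), \code{scale} (per-sample scale factors),
#'   \code{peptide} roll-up table, and the intermediate matrices.
#' @examples
#' sim <- simulatePSMTable(n_proteins = 60L,
#'                         sample_shifts = c(S1 = 0.4, S2 = 0, S3 = -0.4),
#'                         seed = 3L)
#' fit <- normalizePSM(sim$psm)
#' head(fit$protein)
#' @export
normalizePSM <- function(psm, dixon_alpha = 0.05,
                         mean_type = "arithmetic",
                         trim_mode = "intersection",
                         min_proteins = 20L, min_trimmed = 10L) {
  psm <- psmLog2FC(psm, mean_type)
  roll <- rollupMedians(psm, dixon_alpha)
  prot <- roll$protein
  samples <- sort(unique(prot$sample_id))
  proteins <- sort(unique(prot$protein_id))
  raw <- matrix(NA_real_, length(proteins), length(samples),
                dimnames = list(proteins, samples))
  raw[cbind(match(prot$protein_id, proteins),
            match(prot$sample_id, samples))] <- prot$log2fc

  shift <- setNames(numeric(length(samples)), samples)
  aligned <- raw
  for (s in samples) {
    al <- mixtureAlign(raw[, s], min_proteins)
    shift[s] <- al$shift
    aligned[, s] <- al$aligned
  }

  ikey <- paste(psm$sample_id, psm$protein_id, sep = "\r")
  isum <- vapply(split(psm$intensity, ikey), sum, numeric(1))
  iparts <- do.call(rbind, strsplit(names(isum), "\r", fixed = TRUE))
  imat <- matrix(NA_real_, length(proteins), length(samples),
                 dimnames = list(proteins, samples))
  imat[cbind(match(iparts[, 2], proteins),
             match(iparts[, 1], samples))] <- unname(isum)

  sc <- scaleNormalize(aligned, imat, trim_mode, min_trimmed)
  d <- sc$scaled - raw
  calibrated <- calibrateIntensities(imat, d)

  long <- data.frame(
    protein_id = rep(proteins, times = length(samples)),
    sample_id = rep(samples, each = length(proteins)),
    log2fc_raw = as.vector(raw),
    log2fc_aligned = as.vector(aligned),
    log2fc_scaled = as.vector(sc$scaled),
    shift_d = as.vector(d),
    raw_intensity = as.vector(imat),
    calibrated_intensity = as.vector(calibrated))
  list(protein = long, sample_shift = shift, scale = sc$scale,
       peptide = roll$peptide,
       matrices = list(raw = raw, aligned = aligned, scaled = sc$scaled,
                       intensity = imat, calibrated = calibrated))
}

#' Co-purification stoichiometry relative to a reference protein
#'
#' Length-normalized abundance ratios:
#' \code{ratio_p = (A_p / L_p) / (A_ref / L_ref)}, the abundance being
#' calibrated intensity (or any abundance measure such as peptide
#' counts). A ratio of r for protein p reads "reference : p = 1/r : 1",
#' i.e. bait:partner molar stoichiometry.
#'
#' @param abundance named numeric vector of per-protein abundances.
#' @param lengths named numeric vector of protein lengths (residues).
#' @param reference name of the reference (bait) protein.
#' @return named numeric vector of molar ratios relative to the
#'   reference (reference itself = 1).
#' @export
stoichiometry <- function(abundance, lengths, reference) {
  if (!reference %in% names(abundance)) stop("reference protein absent")
  if (any(lengths[names(abundance)] <= 0)) stop("lengths must be positive")
  dens <- abundance / lengths[names(abundance)]
  dens / dens[[reference]]
}
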