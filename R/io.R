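## Readers/writers for every table the pipeline touches. All interval files
## are 0-based half-open on disk; in-memory GRanges use R's 1-based
## convention. Converters between the two conventions are pure inverses.

.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

## ---------------------------------------------------------------------------
## methylome: per-sample bedGraph-like TSV plus a sample sheet
## ---------------------------------------------------------------------------

#' Write a CpGMethylome as per-sample methylation tables
#'
#' One TSV per sample with columns \code{chrom start end beta depth}
#' (bedGraph-compatible columns 1-4, 0-based half-open), plus a sample
#' sheet \code{samples.tsv} mapping file to sample id, genotype and group.
#' Missing data are written as depth 0 with beta NA.
#'
#' @param x a \linkS4class{CpGMethylome}.
#' @param dir output directory (created if needed).
#' @return invisibly, the path to the sample sheet.
#' @seealso \code{\link{readMethylome}}
#' @export
writeMethylome <- function(x, dir) {
  stopifnot(is(x, "CpGMethylome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gr <- rowRanges(x)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  meth <- methCounts(x); depth <- readDepth(x)
  files <- character(ncol(x))
  for (j in seq_len(ncol(x))) {
    beta <- ifelse(depth[, j] > 0, meth[, j] / depth[, j], NA_real_)
    df <- data.frame(chrom = chrom, start = start0, end = end0,
                     beta = .fmt_num(beta), depth = depth[, j])
    files[j] <- paste0(colnames(x)[j], ".meth.tsv")
    write.table(df, file.path(dir, files[j]), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
  }
  sheet <- data.frame(file = files, sample_id = colnames(x),
                      genotype = genotypes(x), group = sampleGroups(x))
  sheet_path <- file.path(dir, "samples.tsv")
  write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(sheet_path)
}

.read_one_methylome_file <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c("character", "integer", "integer",
                                  "character", "integer"))
  beta <- suppressWarnings(as.numeric(df$beta))
  bad_beta <- which(!is.na(beta) & (beta < 0 | beta > 1))
  if (length(bad_beta))
    stop("malformed methylation record in ", basename(path), " line ",
         bad_beta[1] + 1L, ": beta outside [0,1] implies meth_count > depth",
         call. = FALSE)
  if (any(df$depth < 0))
    stop("negative depth in ", basename(path), " line ",
         which(df$depth < 0)[1] + 1L, call. = FALSE)
  o <- order(df$chrom, df$start)
  if (!identical(o, seq_len(nrow(df)))) {
    first_bad <- which(o != seq_len(nrow(df)))[1]
    stop("unsorted input in ", basename(path), ": first violation at line ",
         first_bad + 1L, call. = FALSE)
  }
  meth <- as.integer(round(ifelse(is.na(beta), 0, beta) * df$depth))
  list(chrom = df$chrom, start0 = df$start, end0 = df$end,
       meth = meth, depth = df$depth)
}

#' Read a CpGMethylome from per-sample tables and a sample sheet
#'
#' @param sample_sheet path to a TSV with columns \code{file},
#'   \code{sample_id}, \code{genotype}, \code{group}; file paths are
#'   resolved relative to the sheet's directory.
#' @return a validated \linkS4class{CpGMethylome}. Malformed lines
#'   (beta outside [0,1], i.e. meth_count > depth; unsorted records) raise
#'   errors citing the offending file and line.
#' @export
readMethylome <- function(sample_sheet) {
  sheet <- read.delim(sample_sheet, stringsAsFactors = FALSE)
  need <- c("file", "sample_id", "genotype", "group")
  if (!all(need %in% colnames(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  dir <- dirname(sample_sheet)
  parts <- lapply(file.path(dir, sheet$file), .read_one_methylome_file)
  key0 <- paste(parts[[1]]$chrom, parts[[1]]$start0)
  for (i in seq_along(parts)[-1]) {
    if (!identical(paste(parts[[i]]$chrom, parts[[i]]$start0), key0))
      stop("sample ", sheet$sample_id[i],
           " has a different CpG position set than ", sheet$sample_id[1])
  }
  gr <- GRanges(parts[[1]]$chrom,
                IRanges(parts[[1]]$start0 + 1L, parts[[1]]$end0))
  meth <- do.call(cbind, lapply(parts, `[[`, "meth"))
  depth <- do.call(cbind, lapply(parts, `[[`, "depth"))
  colnames(meth) <- colnames(depth) <- sheet$sample_id
  si <- data.frame(genotype = sheet$genotype, group = sheet$group,
                   row.names = sheet$sample_id)
  CpGMethylome(gr, meth, depth, si)
}

## ---------------------------------------------------------------------------
## DMR sets: BED6+ dialect (documented in README)
## ---------------------------------------------------------------------------

.dmr_file_cols <- c("chrom", "start", "end", "name", "score", "strand",
                    "n_cpg", "mean_beta_A", "mean_beta_B", "diff",
                    "p_value", "q_value", "direction")

#' Write / read a DMRSet
#'
#' BED6+7 dialect: \code{chrom start end name score strand} followed by
#' \code{n_cpg mean_beta_A mean_beta_B diff p_value q_value direction},
#' 0-based half-open, with \code{#comparison_label=} and a commented header
#' line. Round trips are lossless (numerics at 17 significant digits).
#'
#' @param dmrs a \linkS4class{DMRSet}.
#' @param path output file.
#' @param allow_overlaps write even if intervals overlap (default FALSE).
#' @return invisibly, \code{path}.
#' @export
writeDMRs <- function(dmrs, path, allow_overlaps = FALSE) {
  stopifnot(is(dmrs, "DMRSet"))
  if (!allow_overlaps && length(dmrs) > 1) {
    red <- GenomicRanges::reduce(granges(dmrs), min.gapwidth = 0L)
    if (length(red) < length(dmrs))
      stop("DMR intervals overlap; pass allow_overlaps = TRUE to force")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#comparison_label=", comparisonLabel(dmrs)), con)
  writeLines(paste0("#", paste(.dmr_file_cols, collapse = "\t")), con)
  if (length(dmrs)) {
    mc <- mcols(dmrs)
    df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(dmrs)),
      start = GenomicRanges::start(dmrs) - 1L,
      end = GenomicRanges::end(dmrs),
      name = sprintf("dmr_%05d", seq_along(dmrs)),
      score = 0L, strand = ".",
      n_cpg = mc$n_cpg,
      mean_beta_A = .fmt_num(mc$mean_beta_A),
      mean_beta_B = .fmt_num(mc$mean_beta_B),
      diff = .fmt_num(mc$diff),
      p_value = .fmt_num(mc$p_value),
      q_value = .fmt_num(mc$q_value),
      direction = mc$direction)
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname writeDMRs
#' @export
readDMRs <- function(path) {
  lines <- readLines(path)
  label <- sub("^#comparison_label=", "", lines[1])
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    gr <- GRanges()
    for (col in .dmr_cols) mcols(gr)[[col]] <- vector(
      if (col %in% c("direction")) "character" else "numeric", 0L)
    return(DMRSet(gr, label))
  }
  df <- read.delim(text = body, header = FALSE, col.names = .dmr_file_cols,
                   stringsAsFactors = FALSE)
  for (col in c("p_value", "q_value")) {
    bad <- which(!is.na(df[[col]]) & (df[[col]] < 0 | df[[col]] > 1))
    if (length(bad))
      stop("validation error reading ", basename(path), ": ", col, " = ",
           df[[col]][bad[1]], " outside [0,1] at record ", bad[1])
  }
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
  mcols(gr) <- DataFrame(n_cpg = df$n_cpg, mean_beta_A = df$mean_beta_A,
                         mean_beta_B = df$mean_beta_B, diff = df$diff,
                         p_value = df$p_value, q_value = df$q_value,
                         direction = df$direction)
  DMRSet(gr, label)
}

## ---------------------------------------------------------------------------
## annotation BED
## ---------------------------------------------------------------------------

#' Write / read an AnnotationTrack as BED4
#'
#' Plain BED with the class label in the name column (0-based half-open).
#'
#' @param track an \linkS4class{AnnotationTrack}.
#' @param path file path.
#' @return invisibly \code{path} / an \linkS4class{AnnotationTrack}.
#' @export
writeAnnotation <- function(track, path) {
  stopifnot(is(track, "AnnotationTrack"))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(track)),
                   start = GenomicRanges::start(track) - 1L,
                   end = GenomicRanges::end(track),
                   name = mcols(track)$class_label)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeAnnotation
#' @export
readAnnotation <- function(path) {
  df <- read.delim(path, header = FALSE,
                   col.names = c("chrom", "start", "end", "name"),
                   stringsAsFactors = FALSE)
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
  annotationTrack(gr, df$name)
}

## ---------------------------------------------------------------------------
## junction counts and PSM tables
## ---------------------------------------------------------------------------

#' Write / read a junction count table
#'
#' Long TSV with columns \code{sample}, \code{junction_id}, \code{count}
#' and optionally \code{group}.
#'
#' @param counts data.frame with those columns.
#' @param path file path.
#' @return invisibly \code{path} / the validated data.frame.
#' @export
writeJunctionCounts <- function(counts, path) {
  stopifnot(all(c("sample", "junction_id", "count") %in% colnames(counts)))
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeJunctionCounts
#' @export
readJunctionCounts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "junction_id", "count") %in% colnames(df)))
  if (any(df$count < 0) || any(df$count != round(df$count)))
    stop("junction counts must be non-negative integers")
  df
}

#' Write / read a PSM-level precursor intensity table
#'
#' TSV with columns \code{protein_id}, \code{peptide_id}, \code{psm_id},
#' \code{sample_id}, \code{intensity} (strictly positive).
#'
#' @param psm data.frame with those columns.
#' @param path file path.
#' @return invisibly \code{path} / the validated data.frame.
#' @export
writePSMTable <- function(psm, path) {
  stopifnot(all(c("protein_id", "peptide_id", "psm_id", "sample_id",
                  "intensity") %in% colnames(psm)))
  out <- psm
  out$intensity <- .fmt_num(out$intensity)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePSMTable
#' @export
readPSMTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "peptide_id", "psm_id", "sample_id", "intensity")
  stopifnot(all(need %in% colnames(df)))
  if (any(!is.finite(df$intensity)) || any(df$intensity <= 0))
    stop("intensities must be positive and finite")
  key <- with(df, paste(protein_id, peptide_id, psm_id, sample_id))
  if (anyDuplicated(key))
    stop("duplicate (protein, peptide, psm, sample) records")
  df
}

## ---------------------------------------------------------------------------
## external DMR tables with configurable column maps
## ---------------------------------------------------------------------------

#' Summary statistics of an interval table
#'
#' Reads a delimited DMR table whose column names are supplied through a
#' configurable map, and returns the summary statistics used to describe
#' DMR sets: interval count, hypo/hyper counts when a direction or
#' difference column exists, mean width and mean CpGs per interval.
#'
#' @param path delimited file with a header.
#' @param column_map named list mapping the roles \code{chrom},
#'   \code{start}, \code{end} and optionally \code{n_cpg}, \code{diff},
#'   \code{direction} to column names in the file.
#' @param sep field separator (default tab).
#' @param zero_based whether start coordinates are 0-based half-open
#'   (default TRUE).
#' @return list with \code{n}, \code{n_hypo}, \code{n_hyper},
#'   \code{mean_width}, \code{mean_cpg}.
#' @export
summarizeDMRTable <- function(path,
                              column_map = list(chrom = "chrom",
                                                start = "start", end = "end",
                                                n_cpg = "n_cpg",
                                                direction = "direction"),
                              sep = "\t", zero_based = TRUE) {
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  gv <- function(role) {
    nm <- column_map[[role]]
    if (is.null(nm) || !nm %in% colnames(df)) NULL else df[[nm]]
  }
  start <- gv("start"); end <- gv("end")
  if (is.null(start) || is.null(end)) stop("column_map must locate start/end")
  width <- end - start + if (zero_based) 0L else 1L
  dir <- gv("direction"); dff <- gv("diff")
  if (is.null(dir) && !is.null(dff)) dir <- ifelse(dff > 0, "hypo", "hyper")
  ncpg <- gv("n_cpg")
  list(n = nrow(df),
       n_hypo = if (is.null(dir)) NA_integer_ else sum(dir == "hypo"),
       n_hyper = if (is.null(dir)) NA_integer_ else sum(dir == "hyper"),
       mean_width = mean(width),
       mean_cpg = if (is.null(ncpg)) NA_real_ else mean(ncpg))
}
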