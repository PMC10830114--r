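## End-to-end orchestration: simulate -> call -> analyze -> report, driven
## by one YAML config and one root seed, with a checksummed run manifest.

#' Default pipeline configuration
#'
#' Returns the configuration list \code{\link{runPipeline}} consumes,
#' with a toy-scale genome (the stage structure and all statistical
#' models are identical to full-scale runs; only sizes differ).
#'
#' @param seed root seed; every stage derives a named substream from it.
#' @return nested list (serializable to YAML).
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    sim = list(n_cpg_clusters = 120L, n_true_dmrs = 12L,
               samples_per_group = list(WT = 3L, `3aKO` = 3L, `3bKO` = 3L,
                                        DKO = 3L)),
    comparisons = list(list(a = "WT", b = "3aKO"),
                       list(a = "WT", b = "3bKO"),
                       list(a = "WT", b = "DKO")),
    dmr_params = list(),
    addback = list(ko = "3aKO", levels = c(0, 0.5, 1)),
    floxing = list(efficiency = 0.96),
    isoform = list(junction_depth = 200L),
    psm = list(n_proteins = 80L,
               sample_shifts = list(S1 = 0.5, S2 = 0, S3 = -0.5, S4 = 0))
  )
}

.config_merge <- function(base, override) {
  named <- function(x) is.list(x) && !is.null(names(x)) &&
    all(nzchar(names(x)))
  if (!named(base) || !named(override)) return(override)
  for (nm in names(override)) {
    if (named(base[[nm]]) && named(override[[nm]]))
      base[[nm]] <- .config_merge(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the full pipeline
#'
#' Executes simulate, call-dmrs, unify, passive, canyon, annot-summary,
#' floxing, correction, isoform and psm-normalize in dependency order
#' under \code{outdir}, writing every table through the package writers.
#' Any stage failure aborts with the failing stage named. Re-running with
#' an identical config and seed reproduces identical file checksums.
#'
#' @param config a config list (see \code{\link{defaultPipelineConfig}})
#'   or path to a YAML file with the same structure; partial configs are
#'   merged over the defaults.
#' @param outdir output directory.
#' @param seed optional override of \code{config$seed}.
#' @return the run manifest (list), invisibly; also written to
#'   \code{manifest.yaml} with md5 checksums, row counts and wall time
#'   per stage.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outdir,
                        seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  config <- .config_merge(defaultPipelineConfig(), config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(seed = config$seed,
                   config_hash = .hash_obj(config),
                   stages = list())
  outputs <- character()
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      status = "ok",
      outputs = res$files,
      rows = res$rows,
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    outputs <<- c(outputs, res$files)
    res$value
  }

  root <- config$seed
  spg <- unlist(config$sim$samples_per_group)
  sim_cfg <- do.call(simConfig, c(
    config$sim[setdiff(names(config$sim), "samples_per_group")],
    list(samples_per_group = spg, seed = child_seed(root, "sim"))))

  sim <- stage("simulate", function() {
    s <- simulateMethylome(sim_cfg)
    sheet <- writeMethylome(s$methylome, file.path(outdir, "methylome"))
    ann <- file.path(outdir, "annotation.bed")
    writeAnnotation(s$annotation, ann)
    tr <- file.path(outdir, "true_dmrs.bed")
    writeAnnotation(annotationTrack(granges(s$truth$true_dmr_intervals),
                                    "true_dmr"), tr)
    list(value = s, files = c(sheet, ann, tr),
         rows = nrow(s$methylome))
  })

  dmr_sets <- list()
  for (cmp in config$comparisons) {
    nm <- paste0(cmp$a, "_vs_", cmp$b)
    dmr_sets[[nm]] <- stage(paste0("call-dmrs:", nm), function() {
      if (!all(c(cmp$a, cmp$b) %in% sampleGroups(sim$methylome)))
        stop("missing input group for comparison ", nm)
      d <- callDMRs(sim$methylome, cmp$a, cmp$b,
                    do.call(dmrParams, config$dmr_params))
      f <- file.path(outdir, paste0("dmrs_", nm, ".bed"))
      writeDMRs(d, f)
      list(value = d, files = f, rows = length(d))
    })
  }

  unified <- stage("unify", function() {
    u <- unifiedDMRSet(dmr_sets, sim$methylome)
    f <- file.path(outdir, "dmrs_unified.bed")
    writeDMRs(u, f)
    list(value = u, files = f, rows = length(u))
  })

  passive <- stage("passive", function() {
    m <- passiveMethylation(unified, sim$methylome)
    f <- file.path(outdir, "passive_matrix.tsv")
    write.table(round(m, 6), f, sep = "\t", quote = FALSE)
    list(value = m, files = f, rows = nrow(m))
  })

  stage("canyon", function() {
    cp <- canyonProfile(unified, sim$methylome)
    f <- file.path(outdir, "canyon_profile.tsv")
    write.table(cp, f, sep = "\t", quote = FALSE, row.names = FALSE)
    list(value = cp, files = f, rows = nrow(cp))
  })

  stage("annot-summary", function() {
    am <- annotationSummary(sim$methylome, sim$annotation)
    f <- file.path(outdir, "annotation_summary.tsv")
    write.table(round(am, 6), f, sep = "\t", quote = FALSE)
    list(value = am, files = f, rows = nrow(am))
  })

  stage("floxing", function() {
    flox <- sim$truth$floxed_intervals
    eff <- floxingEfficiency(
      simulateFloxedCoverage(sim$methylome, flox,
                             config$floxing$efficiency,
                             child_seed(root, "flox")),
      flox)
    f <- file.path(outdir, "floxing_efficiency.tsv")
    write.table(data.frame(sample = names(eff),
                           efficiency = round(eff, 6)),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    list(value = eff, files = f, rows = length(eff))
  })

  stage("correction", function() {
    ko <- config$addback$ko
    geno <- sampleGroups(sim$methylome)
    base_dmrs <- dmr_sets[[paste0("WT_vs_", ko)]]
    if (is.null(base_dmrs)) base_dmrs <- unified
    recs <- list()
    for (lev in config$addback$levels) {
      ab <- simulateAddback(sim$methylome, sim$truth, lev,
                            sprintf("%s_ab%02.0f", ko, lev * 100),
                            child_seed(root, paste0("addback", lev)),
                            ko_genotype = ko)
      pm_ab <- passiveMethylation(base_dmrs, ab)
      pm <- passiveMethylation(base_dmrs, sim$methylome)
      rec <- correctionExtent(
        rowMeans(pm[, geno == "WT", drop = FALSE], na.rm = TRUE),
        rowMeans(pm[, geno == ko, drop = FALSE], na.rm = TRUE),
        rowMeans(pm_ab, na.rm = TRUE))
      rec$correction_level <- lev
      recs[[as.character(lev)]] <- rec
    }
    all_rec <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
    f <- file.path(outdir, "correction_extent.tsv")
    write.table(all_rec, f, sep = "\t", quote = FALSE, row.names = FALSE)
    list(value = all_rec, files = f, rows = nrow(all_rec))
  })

  stage("isoform", function() {
    jc <- simulateJunctionCounts(junction_depth =
                                   config$isoform$junction_depth,
                                 seed = child_seed(root, "junctions"))
    model <- isoformModel("Dnmt3a1", "e6_e7", "utr_e7")
    cmpr <- compareUsage(jc[jc$group == "WT", ],
                         jc[jc$group != "WT", ], model)
    f1 <- file.path(outdir, "junction_counts.tsv")
    writeJunctionCounts(jc, f1)
    f2 <- file.path(outdir, "isoform_usage.tsv")
    write.table(data.frame(group = names(cmpr$usage),
                           usage = round(cmpr$usage, 6),
                           p_value = cmpr$p_value,
                           odds_ratio = round(cmpr$odds_ratio, 6)),
                f2, sep = "\t", quote = FALSE, row.names = FALSE)
    list(value = cmpr, files = c(f1, f2), rows = nrow(jc))
  })

  stage("psm-normalize", function() {
    ps <- simulatePSMTable(
      n_proteins = config$psm$n_proteins,
      sample_shifts = unlist(config$psm$sample_shifts),
      seed = child_seed(root, "psm"))
    fit <- normalizePSM(ps$psm)
    f1 <- file.path(outdir, "psm_table.tsv")
    writePSMTable(ps$psm, f1)
    f2 <- file.path(outdir, "protein_ratios.tsv")
    out <- fit$protein
    for (col in c("log2fc_raw", "log2fc_aligned", "log2fc_scaled",
                  "shift_d", "raw_intensity", "calibrated_intensity"))
      out[[col]] <- round(out[[col]], 6)
    write.table(out, f2, sep = "\t", quote = FALSE, row.names = FALSE)
    list(value = fit, files = c(f1, f2), rows = nrow(fit$protein))
  })

  rel <- sort(unique(sub(paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                                          outdir), "/?"), "", outputs)))
  manifest$outputs <- lapply(setNames(nm = rel), function(f) {
    p <- file.path(outdir, f)
    list(md5 = unname(tools::md5sum(p)), bytes = file.size(p))
  })
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}

.hash_obj <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(x), tf)
  unname(tools::md5sum(tf))
}
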