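## pipeline module: end-to-end orchestration (simulate or load -> QC ->
## DMS -> mQTL/GE -> co-methylation -> AEI -> meQTL -> intervals) with a
## reproducible report bundle (TSVs + JSON manifest)

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Read a long-format methylation TSV
#'
#' Accepts either the wide dialect (\code{rep1}, \code{rep2} columns) or
#' the long dialect (\code{replicate}, \code{value_pct}); applies
#' [replicateQC()] per record.
#'
#' @param path TSV with columns \code{donor_id}, \code{tissue},
#'   \code{locus}, \code{cpg_index} plus replicate columns.
#' @param qcThreshold replicate-range threshold (percentage points).
#' @return long methylation table with \code{qc_pass} and
#'   \code{mean_beta}.
#' @export
readMethylationTsv <- function(path, qcThreshold = 5) {
  if (!file.exists(path))
    .stopf("methylation file not found: %s", path,
           class = "devmqtl_io_error")
  d <- read.delim(path)
  if (all(c("replicate", "value_pct") %in% names(d))) {
    wide <- stats::reshape(
      d[, c("donor_id", "tissue", "locus", "cpg_index", "replicate",
            "value_pct")],
      idvar = c("donor_id", "tissue", "locus", "cpg_index"),
      timevar = "replicate", direction = "wide")
    names(wide) <- sub("^value_pct\\.", "rep", names(wide))
    d <- wide
  }
  if (!all(c("rep1", "rep2") %in% names(d)))
    .stopf("methylation file needs rep1/rep2 or replicate/value_pct columns",
           class = "devmqtl_parse_error")
  qc <- lapply(seq_len(nrow(d)), function(i)
    replicateQC(c(d$rep1[i], d$rep2[i]), qcThreshold))
  d$qc_pass <- vapply(qc, `[[`, TRUE, "qc_pass")
  d$mean_beta <- vapply(qc, `[[`, 1, "mean") / 100
  d
}

#' Read a long-format AEI TSV
#'
#' Accepts the wide dialect (\code{cdna1..3}, \code{gdna1..3}) or the
#' material dialect (one row per \code{material} of \code{cDNA}/
#' \code{gDNA} with \code{rep1..rep3}); returns normalized records via
#' [aeiRecords()].
#'
#' @param path TSV path.
#' @param qcThreshold triplicate-range threshold.
#' @return AEI record table.
#' @export
readAeiTsv <- function(path, qcThreshold = 5) {
  if (!file.exists(path))
    .stopf("AEI file not found: %s", path, class = "devmqtl_io_error")
  d <- read.delim(path)
  if ("material" %in% names(d)) {
    id <- c("donor_id", "gene", "tissue",
            intersect(c("locus", "rsid"), names(d)))
    cd <- d[d$material == "cDNA", c(id, "rep1", "rep2", "rep3")]
    gd <- d[d$material == "gDNA", c(id, "rep1", "rep2", "rep3")]
    names(cd)[names(cd) %in% paste0("rep", 1:3)] <- paste0("cdna", 1:3)
    names(gd)[names(gd) %in% paste0("rep", 1:3)] <- paste0("gdna", 1:3)
    d <- merge(cd, gd, by = id)
  }
  aeiRecords(d, qcThreshold)
}

.defaultConfig <- function() {
  list(
    simulate = TRUE,
    seed = 1L,
    cohort = list(n_fl = 19L, n_fc = 75L, n_ac = 100L,
                  replicate_sd = 1.5, triplicate_sd = 1.5,
                  dropout_rate = 0.05),
    qc = list(threshold = 5),
    stats = list(alpha = 0.05, dms_tissues = c("FC", "AC"),
                 mqtl_adjust = "bh", meqtl_adjust = "bonferroni"),
    intervals = list(k_fetal = 4L, k_aged = 3L, min_overlap_frac = 0),
    output = list(dendrogram = TRUE))
}

.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

.validateConfig <- function(cfg) {
  bad <- character()
  if (!is.numeric(cfg$seed)) bad <- c(bad, "seed")
  if (!is.numeric(cfg$qc$threshold) || cfg$qc$threshold < 0)
    bad <- c(bad, "qc.threshold")
  if (!is.numeric(cfg$stats$alpha) || cfg$stats$alpha <= 0 ||
      cfg$stats$alpha >= 1)
    bad <- c(bad, "stats.alpha")
  if (!is.numeric(cfg$intervals$k_fetal) || !is.numeric(cfg$intervals$k_aged))
    bad <- c(bad, "intervals.k_fetal/k_aged")
  if (length(bad))
    .stopf("invalid config key(s): %s", paste(bad, collapse = ", "),
           class = "devmqtl_config_error")
  cfg
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage in a fixed order and writes a report bundle:
#' QC'd methylation, differential methylation (FC vs AC by default),
#' per-tissue mQTL scan with genotypic effects, the co-methylation
#' matrix and dendrogram, AEI summaries, the meQTL scan, consensus
#' peak sets with shared/unique classification and CpG intersection, and
#' a JSON run manifest with per-stage record counts. Identical config
#' and seed give identical bundles.
#'
#' @param config path to a YAML config file, or a config list; omitted
#'   keys fall back to defaults (\code{simulate: true} demo cohort).
#' @param outdir output directory for the bundle (created).
#' @param seed optional integer overriding the config seed.
#' @return invisibly, the manifest list.
#' @examples
#' \donttest{
#' out <- runPipeline(list(cohort = list(n_fl = 6, n_fc = 12, n_ac = 12)),
#'                    outdir = tempfile("bundle"))
#' out$counts$mqtl
#' }
#' @export
runPipeline <- function(config = list(), outdir, seed = NULL) {
  cfgInput <- NULL
  if (is.character(config)) {
    cfgInput <- config
    if (!file.exists(config))
      .stopf("config file not found: %s", config,
             class = "devmqtl_config_error")
    config <- yaml::read_yaml(config)
  }
  cfg <- .validateConfig(.mergeConfig(.defaultConfig(), config))
  if (!is.null(seed)) cfg$seed <- seed
  cfg$seed <- as.integer(cfg$seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  panel <- readLocusTable(system.file("extdata", "oa_locus_panel.tsv",
                                      package = "devmqtl"))
  counts <- list()

  if (isTRUE(cfg$simulate)) {
    spec <- cohortSpec(seed = cfg$seed,
                       nPerTissue = c(FL = cfg$cohort$n_fl,
                                      FC = cfg$cohort$n_fc,
                                      AC = cfg$cohort$n_ac),
                       replicateSd = cfg$cohort$replicate_sd,
                       triplicateSd = cfg$cohort$triplicate_sd,
                       dropoutRate = cfg$cohort$dropout_rate)
    cohort <- simulateCohort(spec, panel)
    meth <- cohort$methylation
    ## re-apply QC at the configured threshold
    qc <- lapply(seq_len(nrow(meth)), function(i)
      replicateQC(c(meth$rep1[i], meth$rep2[i]), cfg$qc$threshold))
    meth$qc_pass <- vapply(qc, `[[`, TRUE, "qc_pass")
    meth$mean_beta <- vapply(qc, `[[`, 1, "mean") / 100
    aeiRaw <- cohort$aei
    aei <- aeiRecords(aeiRaw, cfg$qc$threshold)
    donors <- cohort$donors
    peakSamples <- cohort$peaks$samples
  } else {
    if (is.null(cfg$inputs$methylation) || !file.exists(cfg$inputs$methylation))
      .stopf("missing input: %s", cfg$inputs$methylation %||% "inputs.methylation",
             class = "devmqtl_io_error")
    meth <- readMethylationTsv(cfg$inputs$methylation, cfg$qc$threshold)
    aei <- if (!is.null(cfg$inputs$aei)) readAeiTsv(cfg$inputs$aei,
                                                    cfg$qc$threshold)
           else NULL
    donors <- if (!is.null(cfg$inputs$donors)) read.delim(cfg$inputs$donors)
              else NULL
    peakSamples <- NULL
    if (!is.null(cfg$inputs$peaks)) {
      peakSamples <- lapply(names(cfg$inputs$peaks), function(id)
        readPeakBed(cfg$inputs$peaks[[id]], id, sub("[0-9]+$", "", id)))
      names(peakSamples) <- names(cfg$inputs$peaks)
    }
  }

  ## stage: methylation QC
  counts$methylation <- list(loaded = nrow(meth),
                             qc_excluded = sum(!meth$qc_pass))
  .writeTsv(meth, file.path(outdir, "methylation_qc.tsv"))

  ## stage: differential methylation
  dms <- differentialMethylationPanel(meth, cfg$stats$dms_tissues[1L],
                                      cfg$stats$dms_tissues[2L],
                                      cfg$stats$alpha)
  counts$dms <- list(tested = sum(!is.na(dms$p)),
                     significant = sum(dms$significant))
  .writeTsv(dms, file.path(outdir, "dms.tsv"))

  ## stage: mQTL / genotypic effect
  if (!is.null(donors)) {
    mqtl <- mqtlPanel(meth, donors, cfg$stats$alpha)
    counts$mqtl <- list(tested = sum(!is.na(mqtl$p)),
                        significant = sum(mqtl$significant))
    .writeTsv(mqtl, file.path(outdir, "mqtl.tsv"))
    ge <- stats::reshape(
      mqtl[, c("tissue", "locus", "cpg_index", "ge")],
      idvar = c("locus", "cpg_index"), timevar = "tissue",
      direction = "wide")
    .writeTsv(ge, file.path(outdir, "ge_matrix.tsv"))
  }

  ## stage: co-methylation
  bm <- betaMatrix(meth)
  corr <- correlationMatrix(bm)
  .writeTsv(cbind(cpg = rownames(corr@r), as.data.frame(corr@r)),
            file.path(outdir, "comethylation_r.tsv"))
  if (isTRUE(cfg$output$dendrogram) && ncol(bm) >= 2L && !anyNA(corr@r)) {
    hc <- hierarchicalOrder(corr)
    jsonlite::write_json(
      list(order = hc$order, tree = dendrogramJSON(hc$hclust)),
      file.path(outdir, "dendrogram.json"), auto_unbox = TRUE, digits = NA)
  }
  counts$comethylation <- list(cpgs = ncol(bm))

  ## stage: AEI + meQTL
  if (!is.null(aei) && nrow(aei)) {
    counts$aei <- list(loaded = nrow(aei),
                       qc_excluded = sum(!aei$qc_pass))
    .writeTsv(aei, file.path(outdir, "aei_records.tsv"))
    aeiSum <- aeiSummaryTable(aei, cfg$stats$alpha)
    counts$aei$significant <- sum(aeiSum$significant)
    .writeTsv(aeiSum, file.path(outdir, "aei_summary.tsv"))
    meqtl <- meqtlPanel(meth, aei, cfg$stats$alpha)
    counts$meqtl <- list(tested = sum(!is.na(meqtl$p)),
                         significant = sum(meqtl$significant))
    .writeTsv(meqtl, file.path(outdir, "meqtl.tsv"))
  }

  ## stage: intervals
  if (!is.null(peakSamples) && length(peakSamples)) {
    grp <- vapply(peakSamples, function(s) s@group, "")
    kOf <- function(g) if (g %in% c("FH", "FK")) cfg$intervals$k_fetal
                       else cfg$intervals$k_aged
    cons <- lapply(c(FH = "FH", FK = "FK", AH = "AH", AK = "AK"),
                   function(g) {
      ss <- peakSamples[grp == g]
      if (!length(ss)) return(GRanges())
      consensusPeaks(ss, min(kOf(g), length(ss)))
    })
    cls <- classifySharedUnique(cons$FH, cons$FK, cons$AH, cons$AK,
                                cfg$intervals$min_overlap_frac)
    counts$intervals <- as.list(cls$counts)
    regions <- as.data.frame(cls$regions)
    .writeTsv(regions, file.path(outdir, "peak_regions.tsv"))
    cpgPoints <- data.frame(chrom = panel@cpgs$chrom,
                            pos = panel@cpgs$pos,
                            locus = panel@cpgs$locus,
                            cpg_index = panel@cpgs$cpg_index)
    hits <- intersectPoints(cpgPoints, cls$regions)
    .writeTsv(hits, file.path(outdir, "cpg_open_chromatin.tsv"))
    counts$intervals$cpg_in_open <- sum(hits$hit)
  }

  ## manifest
  files <- list.files(outdir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(packageVersion("devmqtl")),
    seed = cfg$seed,
    config = cfg,
    config_file = cfgInput,
    inputs = if (!is.null(cfgInput))
      as.list(tools::md5sum(cfgInput)) else list(),
    outputs = as.list(tools::md5sum(files)),
    counts = counts)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(manifest)
}

#' Render a human-readable bundle summary
#'
#' Reads only the bundle's TSVs and manifest; emits one markdown report
#' with per-stage counts. Stages whose outputs are absent are marked
#' missing rather than failing.
#'
#' @param outdir a bundle directory written by [runPipeline()].
#' @return character vector of markdown lines (also printed invisibly
#'   usable via \code{writeLines}).
#' @export
renderSummary <- function(outdir) {
  lines <- c("# Pipeline summary", "")
  grab <- function(file) {
    p <- file.path(outdir, file)
    if (file.exists(p)) read.delim(p) else NULL
  }
  meth <- grab("methylation_qc.tsv")
  lines <- c(lines, if (is.null(meth)) "- methylation: stage missing"
    else sprintf("- methylation: %d records, %d QC-excluded",
                 nrow(meth), sum(!meth$qc_pass)))
  dms <- grab("dms.tsv")
  lines <- c(lines, if (is.null(dms)) "- differential methylation: stage missing"
    else sprintf("- differential methylation: %d/%d CpGs significant",
                 sum(dms$significant), nrow(dms)))
  mqtl <- grab("mqtl.tsv")
  if (is.null(mqtl)) {
    lines <- c(lines, "- mQTL: stage missing")
  } else {
    for (tis in sort(unique(mqtl$tissue)))
      lines <- c(lines, sprintf(
        "- mQTL [%s]: %d/%d CpGs significant, mean GE %.1f pp", tis,
        sum(mqtl$significant[mqtl$tissue == tis]),
        sum(mqtl$tissue == tis),
        mean(mqtl$ge[mqtl$tissue == tis], na.rm = TRUE)))
  }
  aeiSum <- grab("aei_summary.tsv")
  if (is.null(aeiSum)) {
    lines <- c(lines, "- AEI: stage missing")
  } else {
    for (tis in sort(unique(aeiSum$tissue)))
      lines <- c(lines, sprintf(
        "- AEI [%s]: %d/%d genes significant", tis,
        sum(aeiSum$significant[aeiSum$tissue == tis]),
        sum(aeiSum$tissue == tis)))
  }
  meqtl <- grab("meqtl.tsv")
  lines <- c(lines, if (is.null(meqtl)) "- meQTL: stage missing"
    else sprintf("- meQTL: %d/%d CpG x gene pairs significant",
                 sum(meqtl$significant), nrow(meqtl)))
  pk <- grab("peak_regions.tsv")
  if (is.null(pk)) {
    lines <- c(lines, "- intervals: stage missing")
  } else {
    tab <- table(pk$category)
    lines <- c(lines, sprintf("- intervals: %s",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)),
            collapse = ", ")))
  }
  lines
}
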