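## locus_config module: reader/validator for the locus definition table

.LOCUS_COLS <- c("locus", "rsid", "chrom", "snv_pos", "nea", "ea", "eaf",
                 "cpg_index", "cg_id", "cpg_pos", "genes", "annotation")

#' Read a locus definition table
#'
#' Parses the tab-separated locus/CpG panel that drives the analysis: one
#' row per CpG with the locus-level association-SNV columns repeated on
#' every row (no merged cells). Multi-SNV loci encode their SNVs as
#' comma-separated values in the \code{rsid}, \code{snv_pos}, \code{nea},
#' \code{ea} and \code{eaf} columns; the first listed SNV is designated
#' the genotyping SNV unless \code{genotypingSnv} overrides it.
#'
#' @param path path to a TSV file with columns \code{locus}, \code{rsid},
#'   \code{chrom}, \code{snv_pos}, \code{nea}, \code{ea}, \code{eaf},
#'   \code{cpg_index}, \code{cg_id}, \code{cpg_pos}, \code{genes},
#'   \code{annotation} and optionally \code{discovery_p}.
#' @param genotypingSnv optional named character vector mapping locus id
#'   (as character) to the rsid to use for dosage at multi-SNV loci.
#' @return a validated [LocusPanel-class] object.
#' @examples
#' panel <- readLocusTable(system.file("extdata", "oa_locus_panel.tsv",
#'                                     package = "devmqtl"))
#' cpgCount(panel)
#' @export
readLocusTable <- function(path, genotypingSnv = NULL) {
  if (!file.exists(path))
    .stopf("locus table not found: %s", path, class = "devmqtl_io_error")
  raw <- tryCatch(
    read.delim(path, colClasses = "character", check.names = FALSE),
    error = function(e) .stopf("cannot parse locus table %s: %s", path,
                               conditionMessage(e),
                               class = "devmqtl_parse_error"))
  if (nrow(raw) == 0L)
    .stopf("locus table %s has no data rows", path,
           class = "devmqtl_parse_error")
  missing_cols <- setdiff(.LOCUS_COLS, names(raw))
  if (length(missing_cols))
    .stopf("locus table missing column(s): %s",
           paste(missing_cols, collapse = ", "),
           class = "devmqtl_parse_error")
  if (!"discovery_p" %in% names(raw)) raw$discovery_p <- NA_character_

  num <- function(x, col) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !(is.na(x) | x == ""))
    if (length(bad))
      .stopf("malformed value in column '%s' at data line %d of %s",
             col, bad[1L], basename(path), class = "devmqtl_parse_error")
    out
  }

  cpgs <- data.frame(
    locus = as.integer(num(raw$locus, "locus")),
    cpg_index = as.integer(num(raw$cpg_index, "cpg_index")),
    chrom = raw$chrom,
    pos = num(raw$cpg_pos, "cpg_pos"),
    cg_id = ifelse(raw$cg_id == "" | is.na(raw$cg_id), NA_character_,
                   raw$cg_id),
    discovery_p = num(raw$discovery_p, "discovery_p"),
    annotation = raw$annotation,
    stringsAsFactors = FALSE)
  if (anyNA(cpgs$locus) || anyNA(cpgs$cpg_index) || anyNA(cpgs$pos))
    .stopf("locus, cpg_index and cpg_pos are mandatory in %s",
           basename(path), class = "devmqtl_parse_error")

  snv_rows <- raw[!duplicated(raw$locus), , drop = FALSE]
  snv_list <- lapply(seq_len(nrow(snv_rows)), function(i) {
    row <- snv_rows[i, ]
    rsids <- strsplit(row$rsid, ",", fixed = TRUE)[[1L]]
    split_num <- function(x, col) num(strsplit(x, ",", fixed = TRUE)[[1L]],
                                      col)
    split_chr <- function(x) strsplit(x, ",", fixed = TRUE)[[1L]]
    k <- length(rsids)
    pos <- split_num(row$snv_pos, "snv_pos")
    nea <- split_chr(row$nea); ea <- split_chr(row$ea)
    eaf <- split_num(row$eaf, "eaf")
    if (length(pos) != k || length(nea) != k || length(ea) != k ||
        length(eaf) != k)
      .stopf("locus %s: SNV columns disagree in multiplicity", row$locus,
             class = "devmqtl_parse_error")
    loc <- as.integer(num(row$locus, "locus"))
    geno <- rep(FALSE, k)
    want <- if (!is.null(genotypingSnv)) genotypingSnv[as.character(loc)]
            else NA_character_
    geno[if (!is.na(want) && want %in% rsids) match(want, rsids) else 1L] <-
      TRUE
    data.frame(locus = loc, rsid = rsids, chrom = row$chrom, pos = pos,
               nea = nea, ea = ea, eaf = eaf, genotyping = geno,
               stringsAsFactors = FALSE)
  })
  snvs <- do.call(rbind, snv_list)

  genes <- lapply(seq_len(nrow(snv_rows)), function(i)
    strsplit(snv_rows$genes[i], ",", fixed = TRUE)[[1L]])
  names(genes) <- as.character(snvs$locus[!duplicated(snvs$locus)])

  panel <- new("LocusPanel", snvs = snvs, cpgs = cpgs, genes = genes)
  panel
}

#' Write a locus definition table
#'
#' Serializes a [LocusPanel-class] back to the flat TSV dialect consumed by
#' [readLocusTable()]; \code{readLocusTable(writeLocusTable(panel, f))}
#' reproduces the panel field for field.
#'
#' @param panel a [LocusPanel-class].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeLocusTable <- function(panel, path) {
  stopifnot(is(panel, "LocusPanel"))
  snvs <- panel@snvs
  join <- function(x) vapply(x, paste, "", collapse = ",")
  by_locus <- split(snvs, snvs$locus)
  loc_level <- do.call(rbind, lapply(by_locus, function(s) data.frame(
    locus = s$locus[1L],
    rsid = paste(s$rsid, collapse = ","),
    chrom = s$chrom[1L],
    snv_pos = paste(format(s$pos, scientific = FALSE, trim = TRUE),
                    collapse = ","),
    nea = paste(s$nea, collapse = ","), ea = paste(s$ea, collapse = ","),
    eaf = paste(format(s$eaf, trim = TRUE), collapse = ","),
    genes = paste(panel@genes[[as.character(s$locus[1L])]], collapse = ","),
    stringsAsFactors = FALSE)))
  out <- merge(panel@cpgs, loc_level, by = "locus", sort = FALSE)
  out <- out[order(out$locus, out$cpg_index), ]
  tbl <- data.frame(
    locus = out$locus, rsid = out$rsid, chrom = out$chrom.y,
    snv_pos = out$snv_pos, nea = out$nea, ea = out$ea, eaf = out$eaf,
    cpg_index = out$cpg_index,
    cg_id = ifelse(is.na(out$cg_id), "", out$cg_id),
    cpg_pos = format(out$pos, scientific = FALSE, trim = TRUE),
    discovery_p = ifelse(is.na(out$discovery_p), "",
                         format(out$discovery_p, trim = TRUE)),
    genes = out$genes, annotation = out$annotation,
    stringsAsFactors = FALSE, check.names = FALSE)
  write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count CpG sites in a panel
#'
#' @param panel a [LocusPanel-class].
#' @param locus optional integer locus id; when given, counts only that
#'   locus's CpGs.
#' @return integer count.
#' @export
cpgCount <- function(panel, locus = NULL) {
  stopifnot(is(panel, "LocusPanel"))
  if (is.null(locus)) return(nrow(panel@cpgs))
  if (!locus %in% panel@cpgs$locus)
    .stopf("unknown locus id: %s", locus, class = "devmqtl_lookup_error")
  sum(panel@cpgs$locus == locus)
}

#' Validate a locus panel against its invariants
#'
#' Checks every structural invariant of the panel and returns violations
#' as data rather than raising: each element names the locus, the field
#' and the rule broken. An empty character vector means the panel is valid.
#'
#' @param panel a [LocusPanel-class] (or an object with the same slots,
#'   e.g. one being constructed).
#' @return character vector of violation descriptions (empty if valid).
#' @export
validateLocusTable <- function(panel) {
  snvs <- panel@snvs; cpgs <- panel@cpgs; genes <- panel@genes
  v <- character()
  bad <- which(!(snvs$eaf > 0 & snvs$eaf < 1))
  for (i in bad)
    v <- c(v, sprintf("locus %d, field eaf: EAF must lie strictly in (0,1), got %g",
                      snvs$locus[i], snvs$eaf[i]))
  bad <- which(!(snvs$nea %in% c("A", "C", "G", "T") &
                 snvs$ea %in% c("A", "C", "G", "T")))
  for (i in bad)
    v <- c(v, sprintf("locus %d, field alleles: alleles must be single nucleotides",
                      snvs$locus[i]))
  bad <- which(snvs$nea == snvs$ea)
  for (i in bad)
    v <- c(v, sprintf("locus %d, field alleles: effect and non-effect allele must differ",
                      snvs$locus[i]))
  bad <- which(snvs$pos < 1)
  for (i in bad)
    v <- c(v, sprintf("locus %d, field pos: position must be >= 1",
                      snvs$locus[i]))
  key <- paste(cpgs$locus, cpgs$cpg_index)
  if (anyDuplicated(key))
    v <- c(v, sprintf("locus %s, field cpg_index: (locus, cpg_index) must be unique",
                      cpgs$locus[duplicated(key)][1L]))
  if (anyDuplicated(cpgs$pos))
    v <- c(v, sprintf("locus %d, field cpg_pos: CpG position %s duplicated across the table",
                      cpgs$locus[duplicated(cpgs$pos)][1L],
                      format(cpgs$pos[duplicated(cpgs$pos)][1L],
                             scientific = FALSE)))
  for (loc in unique(snvs$locus)) {
    g <- genes[[as.character(loc)]]
    if (is.null(g) || !length(g) || all(g == ""))
      v <- c(v, sprintf("locus %d, field genes: gene list must be non-empty",
                        loc))
    if (sum(snvs$genotyping[snvs$locus == loc]) != 1L)
      v <- c(v, sprintf("locus %d, field genotyping: exactly one genotyping SNV required",
                        loc))
  }
  orphan <- setdiff(unique(cpgs$locus), unique(snvs$locus))
  for (loc in orphan)
    v <- c(v, sprintf("locus %d, field locus: CpGs reference a locus with no SNV entry",
                      loc))
  v
}

#' Association SNVs of a panel
#' @param panel a [LocusPanel-class].
#' @param genotypingOnly if \code{TRUE}, only the dosage-defining SNV per
#'   locus.
#' @return data.frame of SNVs.
#' @export
associationSnvs <- function(panel, genotypingOnly = FALSE) {
  stopifnot(is(panel, "LocusPanel"))
  s <- panel@snvs
  if (genotypingOnly) s <- s[s$genotyping, , drop = FALSE]
  s
}

#' CpG sites of a panel
#' @param panel a [LocusPanel-class].
#' @param locus optional locus id filter.
#' @return data.frame of CpG sites.
#' @export
cpgSites <- function(panel, locus = NULL) {
  stopifnot(is(panel, "LocusPanel"))
  cp <- panel@cpgs
  if (!is.null(locus)) {
    if (!locus %in% cp$locus)
      .stopf("unknown locus id: %s", locus, class = "devmqtl_lookup_error")
    cp <- cp[cp$locus == locus, , drop = FALSE]
  }
  cp
}

#' Effector genes of a panel
#' @param panel a [LocusPanel-class].
#' @return named list of gene symbol vectors, one per locus.
#' @export
effectorGenes <- function(panel) {
  stopifnot(is(panel, "LocusPanel"))
  panel@genes
}

#' Serialize a locus panel to JSON
#'
#' Emits the panel as a JSON string for the pipeline manifest: one object
#' per locus with its SNVs, genes and ordered CpG list.
#'
#' @param panel a [LocusPanel-class].
#' @param pretty pretty-print the JSON.
#' @return a JSON character scalar.
#' @export
locusPanelJSON <- function(panel, pretty = TRUE) {
  stopifnot(is(panel, "LocusPanel"))
  loci <- lapply(sort(unique(panel@snvs$locus)), function(loc) {
    list(
      locus = loc,
      snvs = panel@snvs[panel@snvs$locus == loc,
                        c("rsid", "chrom", "pos", "nea", "ea", "eaf",
                          "genotyping")],
      genes = panel@genes[[as.character(loc)]],
      cpgs = panel@cpgs[panel@cpgs$locus == loc,
                        c("cpg_index", "chrom", "pos", "cg_id",
                          "discovery_p", "annotation")])
  })
  jsonlite::toJSON(loci, pretty = pretty, auto_unbox = TRUE, digits = NA,
                   na = "null", dataframe = "rows")
}

#' @describeIn LocusPanel-class compact console summary
#' @param object a \code{LocusPanel}.
#' @export
setMethod("show", "LocusPanel", function(object) {
  nl <- length(unique(object@snvs$locus))
  cat(sprintf("LocusPanel: %d loci, %d CpG sites, %d association SNV(s)\n",
              nl, nrow(object@cpgs), nrow(object@snvs)))
  per <- table(object@cpgs$locus)
  cat("  CpGs per locus:",
      paste(sprintf("%s:%d", names(per), as.integer(per)), collapse = " "),
      "\n")
  cat("  genes:",
      paste(unlist(object@genes), collapse = ", "), "\n")
})
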