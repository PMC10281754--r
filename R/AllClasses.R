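#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importFrom stats coef cutree dist hclust lm p.adjust pnorm pt
#'   qt rbinom rnorm runif setNames as.dist binom.test t.test
#'   wilcox.test
#' @importFrom utils read.delim write.table packageVersion
NULL

#' Locus definition panel
#'
#' Holds the targeted panel driving every downstream stage: for each locus
#' the genome-wide association SNV(s) with effect-allele frequencies, the
#' putative effector genes, and the ordered CpG sites measured by
#' pyrosequencing. Coordinates are stored as printed in the source table
#' (1-based); conversion to half-open intervals happens only in the
#' interval-algebra layer.
#'
#' @slot snvs data.frame with one row per association SNV: \code{locus},
#'   \code{rsid}, \code{chrom}, \code{pos} (1-based), \code{nea},
#'   \code{ea}, \code{eaf}, \code{genotyping} (logical; the SNV used for
#'   dosage at multi-SNV loci).
#' @slot cpgs data.frame with one row per CpG: \code{locus},
#'   \code{cpg_index}, \code{chrom}, \code{pos}, \code{cg_id} (optional
#'   array probe id, \code{NA} if absent), \code{discovery_p} (optional),
#'   \code{annotation}.
#' @slot genes named list, one character vector of gene symbols per locus.
#'
#' @seealso [readLocusTable()], [cpgCount()], [validateLocusTable()]
#' @export
setClass("LocusPanel",
  representation(snvs = "data.frame", cpgs = "data.frame", genes = "list"))

setValidity("LocusPanel", function(object) {
  v <- validateLocusTable(object)
  if (length(v)) paste(v, collapse = "; ") else TRUE
})

#' Synthetic cohort specification
#'
#' Describes a simulated study cohort: sample sizes per tissue, per-locus
#' effect structure (tissue baselines, genotypic effects, allelic-imbalance
#' means, methylation-expression coupling), technical noise and dropout,
#' and the layout of the toy open-chromatin experiment. Together with a
#' seed it fully determines every simulated data set.
#'
#' @slot seed integer master seed.
#' @slot nPerTissue named integer; donors per methylation/AEI tissue
#'   (\code{FL}, \code{FC}, \code{AC}).
#' @slot nPeakSamples named integer; samples per peak group (\code{FH},
#'   \code{FK}, \code{AH}, \code{AK}).
#' @slot effects data.frame, one row per locus x tissue:
#'   \code{locus}, \code{tissue}, \code{baseline_beta} (proportion),
#'   \code{ge_target} (percentage points), \code{aei_log2_mean},
#'   \code{meqtl_slope} (log2-ratio change per M-value unit).
#' @slot replicateSd,triplicateSd numeric; Gaussian technical sd on the
#'   percentage scale for methylation duplicates and allele-count
#'   triplicates.
#' @slot dropoutRate numeric in [0,1]; probability a donor x CpG record is
#'   missing.
#' @slot donorSd numeric; sd (beta units) of the per-donor, per-locus
#'   biological methylation effect shared by a locus's CpGs.
#' @slot peakSim list; toy-genome peak layout (see [cohortSpec()]).
#' @slot markerDeltaCt numeric; Ct shift of cartilage marker genes in FC
#'   relative to FL (negative = higher expression).
#'
#' @seealso [cohortSpec()], [simulateCohort()]
#' @export
setClass("CohortSpec",
  representation(seed = "integer", nPerTissue = "integer",
    nPeakSamples = "integer", effects = "data.frame",
    replicateSd = "numeric", triplicateSd = "numeric",
    dropoutRate = "numeric", donorSd = "numeric", peakSim = "list",
    markerDeltaCt = "numeric"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (any(object@nPerTissue < 0) || any(object@nPeakSamples < 0))
    msg <- c(msg, "sample counts must be >= 0")
  if (object@dropoutRate < 0 || object@dropoutRate > 1)
    msg <- c(msg, "dropoutRate must lie in [0,1]")
  if (object@replicateSd < 0 || object@triplicateSd < 0 ||
      object@donorSd < 0)
    msg <- c(msg, "noise sds must be >= 0")
  eff <- object@effects
  need <- c("locus", "tissue", "baseline_beta", "ge_target",
            "aei_log2_mean", "meqtl_slope")
  if (!all(need %in% names(eff))) {
    msg <- c(msg, paste("effects must have columns:",
                        paste(need, collapse = ", ")))
  } else {
    if (any(eff$baseline_beta <= 0 | eff$baseline_beta >= 1))
      msg <- c(msg, "baseline_beta must lie in (0,1)")
    if (any(eff$ge_target < 0 | eff$ge_target > 100))
      msg <- c(msg, "ge_target must lie in [0,100] percentage points")
  }
  p <- object@peakSim
  if (!is.null(p$presenceProb) &&
      (p$presenceProb < 0 || p$presenceProb > 1))
    msg <- c(msg, "peakSim$presenceProb must lie in [0,1]")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Per-sample open-chromatin peak set
#'
#' One sample's called peaks, normalized (sorted, self-merged) at
#' construction so downstream interval algebra can assume disjointness.
#'
#' @slot sampleId character scalar.
#' @slot group character scalar; one of \code{FH}, \code{FK}, \code{AH},
#'   \code{AK}.
#' @slot peaks a [GenomicRanges::GRanges] of disjoint, sorted intervals.
#'
#' @seealso [peakSet()], [consensusPeaks()]
#' @export
setClass("PeakSet",
  representation(sampleId = "character", group = "character",
    peaks = "GRanges"))

setValidity("PeakSet", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L) msg <- c(msg, "sampleId must be scalar")
  if (!object@group %in% c("FH", "FK", "AH", "AK"))
    msg <- c(msg, "group must be one of FH, FK, AH, AK")
  gr <- object@peaks
  if (length(gr)) {
    red <- GenomicRanges::reduce(gr)  # reduce() output is sorted + disjoint
    same <- length(red) == length(gr) &&
      all(GenomicRanges::start(red) == GenomicRanges::start(gr)) &&
      all(GenomicRanges::end(red) == GenomicRanges::end(gr)) &&
      all(as.character(GenomicRanges::seqnames(red)) ==
          as.character(GenomicRanges::seqnames(gr)))
    if (!same)
      msg <- c(msg, "peaks must be sorted and disjoint after normalization")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Pairwise CpG correlation structure
#'
#' Pairwise-complete Pearson correlations of methylation beta values across
#' a CpG panel, with the number of complete observation pairs backing each
#' coefficient. Pairs supported by fewer complete observations than the
#' declared minimum are \code{NA}, never fabricated.
#'
#' @slot labels character; ordered CpG labels ("locus.cpg_index").
#' @slot r symmetric numeric matrix of correlations in [-1, 1].
#' @slot nPairs integer matrix of pairwise-complete sample counts.
#' @slot minPairs integer; minimum pairs required for a coefficient.
#'
#' @seealso [correlationMatrix()], [hierarchicalOrder()], [clusterBlocks()]
#' @export
setClass("CpGCorrelation",
  representation(labels = "character", r = "matrix", nPairs = "matrix",
    minPairs = "integer"))

setValidity("CpGCorrelation", function(object) {
  msg <- character()
  r <- object@r
  k <- length(object@labels)
  if (!all(dim(r) == c(k, k))) msg <- c(msg, "r must be labels x labels")
  if (!all(dim(object@nPairs) == c(k, k)))
    msg <- c(msg, "nPairs must be labels x labels")
  ok <- is.finite(r)
  if (any(abs(r[ok]) > 1 + 1e-12)) msg <- c(msg, "|r| must be <= 1")
  if (k && any(abs(diag(r) - 1) > 1e-12, na.rm = TRUE))
    msg <- c(msg, "diagonal of r must be 1")
  if (k && any(abs(r - t(r)) > 1e-12, na.rm = TRUE))
    msg <- c(msg, "r must be symmetric")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})
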