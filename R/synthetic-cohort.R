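## synthetic_cohort module: simulated cohorts with the statistical
## structure the downstream analysis assumes (Hardy-Weinberg genotypes,
## additive genotype effects on methylation, technical replicate noise,
## methylation-coupled allelic imbalance, planted open-chromatin regions).

.TISSUES <- c("FL", "FC", "AC")
.PEAK_GROUPS <- c("FH", "FK", "AH", "AK")

.defaultEffects <- function() {
  ## per-locus tissue baselines (beta), genotypic-effect targets
  ## (percentage points), allelic-imbalance log2 means and
  ## methylation-expression coupling; values chosen once to mirror the
  ## qualitative structure of targeted skeletal mQTL panels: strong
  ## cartilage-specific effects at locus 4, a broad developmental effect
  ## at locus 1, a limb-specific effect at locus 7
  base <- expand.grid(locus = 1:7, tissue = .TISSUES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  baseline <- matrix(c(
    ## FL    FC    AC
    0.90, 0.45, 0.55,   # locus 1
    0.50, 0.45, 0.50,   # locus 2
    0.40, 0.45, 0.50,   # locus 3
    0.87, 0.55, 0.60,   # locus 4
    0.50, 0.40, 0.45,   # locus 5
    0.45, 0.50, 0.50,   # locus 6
    0.30, 0.25, 0.30),  # locus 7
    ncol = 3, byrow = TRUE, dimnames = list(NULL, .TISSUES))
  ge <- matrix(c(
    10.0, 33.9, 13.8,
     8.0, 15.0, 12.0,
    10.0, 15.0, 12.0,
     7.6, 38.7, 59.2,
    10.0, 20.0, 15.0,
    12.0, 15.0, 10.0,
    42.0,  7.5, 11.2),
    ncol = 3, byrow = TRUE, dimnames = list(NULL, .TISSUES))
  aei <- matrix(c(
    0.10,  log2(1.17),  log2(1.95),
   -0.05,  log2(0.93), -0.10,
    0.08,  log2(1.08),  0.10,
   -0.15,  log2(0.89), -0.15,
   -0.20,  log2(0.81), -0.25,
    0.00,  0.00,       -0.32,
   -0.40,  log2(0.73), -0.35),
    ncol = 3, byrow = TRUE, dimnames = list(NULL, .TISSUES))
  slope <- c(0.4, 0.4, 0, 0.4, 0, 0, 0.4)  # log2-ratio per M-unit
  ti <- match(base$tissue, .TISSUES)
  base$baseline_beta <- baseline[cbind(base$locus, ti)]
  base$ge_target <- ge[cbind(base$locus, ti)]
  base$aei_log2_mean <- aei[cbind(base$locus, ti)]
  base$meqtl_slope <- slope[base$locus]
  base
}

#' Construct a synthetic cohort specification
#'
#' Returns a [CohortSpec-class] describing the simulated study. Defaults
#' reproduce the design of a targeted skeletal mQTL panel: 19 fetal limb
#' (FL), 75 fetal cartilage (FC) and 100 aged cartilage (AC) donors for
#' the molecular measurements, and 6/6/5/5 fetal-hip/fetal-knee/aged-hip/
#' aged-knee (FH/FK/AH/AK) samples for the open-chromatin experiment.
#' Per-locus effect structure defaults are documented in the package
#' vignette; every field can be overridden.
#'
#' @param seed integer master seed; with the spec it fully determines all
#'   simulated outputs.
#' @param nPerTissue named integer vector of donors for \code{FL},
#'   \code{FC}, \code{AC}.
#' @param nPeakSamples named integer vector of peak samples for
#'   \code{FH}, \code{FK}, \code{AH}, \code{AK}.
#' @param effects data.frame as described in [CohortSpec-class]; defaults
#'   to the built-in per-locus table.
#' @param replicateSd technical sd (percentage points) of pyrosequencing
#'   duplicates.
#' @param triplicateSd technical sd (percentage points) of allele-ratio
#'   triplicates.
#' @param dropoutRate probability that a donor x CpG measurement is
#'   missing.
#' @param donorSd sd (beta units) of the per-donor, per-locus biological
#'   methylation effect shared by a locus's CpGs; this is the donor-level
#'   variance that couples methylation to allelic expression.
#' @param peakSim list describing the toy open-chromatin genome:
#'   \code{contig}, \code{genomeLength}, counts of planted
#'   \code{nShared}/\code{nFetalOnly}/\code{nAgedOnly} regions,
#'   \code{width}, per-sample \code{presenceProb} and boundary
#'   \code{jitter} (bp).
#' @param markerDeltaCt Ct shift of cartilage marker genes in FC relative
#'   to FL (negative means higher expression in FC).
#' @return a validated [CohortSpec-class].
#' @examples
#' spec <- cohortSpec(seed = 1, nPerTissue = c(FL = 10, FC = 20, AC = 20))
#' spec
#' @export
cohortSpec <- function(seed = 1L,
                       nPerTissue = c(FL = 19L, FC = 75L, AC = 100L),
                       nPeakSamples = c(FH = 6L, FK = 6L, AH = 5L, AK = 5L),
                       effects = .defaultEffects(),
                       replicateSd = 1.5,
                       triplicateSd = 1.5,
                       dropoutRate = 0.05,
                       donorSd = 0.05,
                       peakSim = list(contig = "chrT",
                                      genomeLength = 1e7,
                                      nShared = 120L, nFetalOnly = 77L,
                                      nAgedOnly = 97L, width = 400L,
                                      presenceProb = 0.9, jitter = 25L),
                       markerDeltaCt = -2) {
  n <- setNames(as.integer(nPerTissue[.TISSUES]), .TISSUES)
  np <- setNames(as.integer(nPeakSamples[.PEAK_GROUPS]), .PEAK_GROUPS)
  if (anyNA(n) || anyNA(np))
    .stopf("nPerTissue needs FL/FC/AC and nPeakSamples needs FH/FK/AH/AK",
           class = "devmqtl_domain_error")
  new("CohortSpec", seed = as.integer(seed), nPerTissue = n,
      nPeakSamples = np, effects = effects, replicateSd = replicateSd,
      triplicateSd = triplicateSd, dropoutRate = dropoutRate,
      donorSd = donorSd, peakSim = peakSim, markerDeltaCt = markerDeltaCt)
}

#' @describeIn CohortSpec-class compact console summary
#' @param object a \code{CohortSpec}.
#' @export
setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec (seed", object@seed, ")\n")
  cat("  donors:",
      paste(sprintf("%s=%d", names(object@nPerTissue), object@nPerTissue),
            collapse = " "), "\n")
  cat("  peak samples:",
      paste(sprintf("%s=%d", names(object@nPeakSamples),
                    object@nPeakSamples), collapse = " "), "\n")
  cat(sprintf("  noise: replicate sd %.2f%%, triplicate sd %.2f%%, dropout %.2f\n",
              object@replicateSd, object@triplicateSd, object@dropoutRate))
  cat(sprintf("  loci: %d with effect structure\n",
              length(unique(object@effects$locus))))
})

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Draws effect-allele dosages (0/1/2) i.i.d. from Hardy-Weinberg
#' proportions: P(2) = eaf^2, P(1) = 2 eaf (1-eaf), P(0) = (1-eaf)^2.
#'
#' @param eaf effect-allele frequency, strictly inside (0,1).
#' @param n number of donors (>= 0).
#' @param seed optional integer; when given, the draw is reproducible.
#' @return integer vector of dosages of length \code{n}.
#' @examples
#' simulateGenotypes(0.83, 10, seed = 1)
#' @export
simulateGenotypes <- function(eaf, n, seed = NULL) {
  if (!is.finite(eaf) || eaf <= 0 || eaf >= 1)
    .stopf("eaf must lie strictly in (0,1), got %g", eaf,
           class = "devmqtl_domain_error")
  if (n < 0) .stopf("n must be >= 0", class = "devmqtl_domain_error")
  if (n == 0) return(integer(0))
  if (!is.null(seed)) set.seed(seed)
  ## sum of two independent allele draws = binomial(2, eaf)
  rbinom(n, size = 2L, prob = eaf)
}

#' Simulate the donor roster
#'
#' Builds the donor table for the methylation/AEI tissues: ids, tissue,
#' age (days post-conception for fetal tissues, years for aged), sex, and
#' one effect-allele dosage column per locus drawn from Hardy-Weinberg
#' proportions at the panel's EAF.
#'
#' @param spec a [CohortSpec-class].
#' @param panel a [LocusPanel-class]; EAFs are taken from each locus's
#'   genotyping SNV.
#' @return data.frame with columns \code{donor_id}, \code{tissue},
#'   \code{age}, \code{sex} and \code{dosage.<locus>}.
#' @export
simulateDonors <- function(spec, panel) {
  stopifnot(is(spec, "CohortSpec"), is(panel, "LocusPanel"))
  set.seed(.deriveSeed(spec@seed, 1L))
  rows <- lapply(.TISSUES, function(tis) {
    n <- spec@nPerTissue[[tis]]
    if (n == 0) return(NULL)
    age <- switch(tis,
      FL = round(runif(n, 32, 84)),
      FC = round(runif(n, 56, 119)),
      AC = round(runif(n, 25, 91)))
    data.frame(donor_id = sprintf("%s%03d", tis, seq_len(n)), tissue = tis,
               age = age, sex = sample(c("M", "F"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  donors <- do.call(rbind, rows)
  snvs <- associationSnvs(panel, genotypingOnly = TRUE)
  for (i in seq_len(nrow(snvs))) {
    donors[[paste0("dosage.", snvs$locus[i])]] <-
      simulateGenotypes(snvs$eaf[i], nrow(donors))
  }
  donors
}

## latent per-donor x CpG beta used by both methylation and AEI stages;
## donorEffects is a donors x loci matrix of biological effects shared by
## all CpGs of a locus
.latentBeta <- function(spec, donors, panel, cpgOffsets, donorEffects,
                        eps = 0.01) {
  cpgs <- panel@cpgs
  eff <- spec@effects
  lociIds <- sort(unique(eff$locus))
  out <- vector("list", nrow(cpgs))
  for (i in seq_len(nrow(cpgs))) {
    loc <- cpgs$locus[i]
    dos <- donors[[paste0("dosage.", loc)]]
    e <- eff[eff$locus == loc, ]
    base <- setNames(e$baseline_beta, e$tissue)[donors$tissue]
    ge <- setNames(e$ge_target, e$tissue)[donors$tissue]
    de <- donorEffects[, match(loc, lociIds)]
    beta <- .clamp(base + dos * ge / 2 / 100 + cpgOffsets[i] + de,
                   eps, 1 - eps)
    out[[i]] <- beta
  }
  ## donors x cpgs matrix
  do.call(cbind, out)
}

#' Simulate pyrosequencing methylation measurements
#'
#' For each donor x CpG the latent beta is
#' \code{clamp(baseline[tissue] + dosage * ge_target/2/100 + cpg_offset,
#' eps, 1-eps)}; each of two technical replicates is \code{100*beta} plus
#' Gaussian noise (sd \code{replicateSd}), truncated to [0,100]. Records
#' are dropped independently with probability \code{dropoutRate}. QC and
#' mean beta are filled by [replicateQC()] semantics.
#'
#' @param spec a [CohortSpec-class].
#' @param donors donor table from [simulateDonors()].
#' @param panel a [LocusPanel-class].
#' @param qcThreshold replicate-range QC threshold in percentage points.
#' @return long data.frame with columns \code{donor_id}, \code{tissue},
#'   \code{locus}, \code{cpg_index}, \code{rep1}, \code{rep2},
#'   \code{qc_pass}, \code{mean_beta} (NA unless QC passes).
#' @export
simulateMethylation <- function(spec, donors, panel, qcThreshold = 5) {
  stopifnot(is(spec, "CohortSpec"), is(panel, "LocusPanel"))
  set.seed(.deriveSeed(spec@seed, 2L))
  cpgs <- panel@cpgs
  ## small fixed per-CpG offsets around the locus baseline so CpGs within
  ## a locus are distinguishable but co-regulated
  cpgOffsets <- rnorm(nrow(cpgs), 0, 0.03)
  nLoci <- length(unique(spec@effects$locus))
  donorEffects <- matrix(rnorm(nrow(donors) * nLoci, 0, spec@donorSd),
                         nrow(donors), nLoci)
  beta <- .latentBeta(spec, donors, panel, cpgOffsets, donorEffects)
  nd <- nrow(donors); nc <- nrow(cpgs)
  idx_d <- rep(seq_len(nd), times = nc)
  idx_c <- rep(seq_len(nc), each = nd)
  lat <- as.vector(beta)
  rep1 <- .clamp(100 * lat + rnorm(length(lat), 0, spec@replicateSd), 0, 100)
  rep2 <- .clamp(100 * lat + rnorm(length(lat), 0, spec@replicateSd), 0, 100)
  keep <- runif(length(lat)) >= spec@dropoutRate
  rec <- data.frame(
    donor_id = donors$donor_id[idx_d], tissue = donors$tissue[idx_d],
    locus = cpgs$locus[idx_c], cpg_index = cpgs$cpg_index[idx_c],
    rep1 = rep1, rep2 = rep2, stringsAsFactors = FALSE)[keep, , drop = FALSE]
  if (nrow(rec)) {
    rng <- abs(rec$rep1 - rec$rep2)
    rec$qc_pass <- rng <= qcThreshold
    rec$mean_beta <- ifelse(rec$qc_pass, (rec$rep1 + rec$rep2) / 2 / 100,
                            NA_real_)
  } else {
    rec$qc_pass <- logical(0); rec$mean_beta <- numeric(0)
  }
  rownames(rec) <- NULL
  rec
}

#' Simulate allelic expression imbalance measurements
#'
#' Heterozygous donors only. The latent log2 allelic ratio for a donor is
#' \code{aei_log2_mean[tissue] + meqtl_slope * (M_donor - mean M)}, where
#' \code{M_donor} is the donor's mean M-value over the locus's QC-passing
#' CpGs, coupling allelic imbalance to methylation. The ratio is converted
#' to an allele-A percentage; cDNA triplicates are that percentage plus
#' Gaussian noise (sd \code{triplicateSd}), gDNA triplicates are centred
#' on 50\%.
#'
#' @param spec a [CohortSpec-class].
#' @param donors donor table from [simulateDonors()].
#' @param methylation long methylation table from [simulateMethylation()].
#' @param panel a [LocusPanel-class].
#' @return data.frame with columns \code{donor_id}, \code{tissue},
#'   \code{locus}, \code{gene}, \code{cdna1..3}, \code{gdna1..3}.
#' @export
simulateAEI <- function(spec, donors, methylation, panel) {
  stopifnot(is(spec, "CohortSpec"), is(panel, "LocusPanel"))
  set.seed(.deriveSeed(spec@seed, 3L))
  eff <- spec@effects
  out <- list()
  for (loc in sort(unique(eff$locus))) {
    dos <- donors[[paste0("dosage.", loc)]]
    het <- which(dos == 1L)
    if (!length(het)) next
    e <- eff[eff$locus == loc, ]
    meth <- methylation[methylation$locus == loc & methylation$qc_pass, ]
    mM <- tapply(betaToM(meth$mean_beta), meth$donor_id, mean)
    ## centre on the heterozygote mean within tissue: AEI is only
    ## measured in heterozygotes, and centring on all genotypes would
    ## fold the mQTL effect into every tissue's AEI mean
    hetIds <- donors$donor_id[het]
    mHet <- mM[names(mM) %in% hetIds]
    hetTissue <- donors$tissue[match(names(mHet), donors$donor_id)]
    tissueMeanM <- tapply(as.numeric(mHet), hetTissue, mean)
    genes <- panel@genes[[as.character(loc)]]
    for (gene in genes) {
      d <- donors[het, , drop = FALSE]
      if (length(mM)) {
        donorM <- as.numeric(mM[d$donor_id])
        ref <- as.numeric(tissueMeanM[d$tissue])
        ref[is.na(ref)] <- mean(mM, na.rm = TRUE)
        donorM[is.na(donorM)] <- ref[is.na(donorM)]
        centred <- donorM - ref
      } else {
        centred <- numeric(nrow(d))  # no methylation to couple to
      }
      lmean <- setNames(e$aei_log2_mean, e$tissue)[d$tissue]
      slope <- e$meqtl_slope[1L]
      log2r <- lmean + slope * centred
      ratio <- 2^log2r
      pctA <- 100 * ratio / (1 + ratio)
      cd <- replicate(3, .clamp(pctA + rnorm(length(pctA), 0,
                                             spec@triplicateSd), 1, 99))
      gd <- replicate(3, .clamp(50 + rnorm(length(pctA), 0,
                                           spec@triplicateSd), 1, 99))
      cd <- matrix(cd, ncol = 3); gd <- matrix(gd, ncol = 3)
      out[[length(out) + 1L]] <- data.frame(
        donor_id = d$donor_id, tissue = d$tissue, locus = loc, gene = gene,
        cdna1 = cd[, 1], cdna2 = cd[, 2], cdna3 = cd[, 3],
        gdna1 = gd[, 1], gdna2 = gd[, 2], gdna3 = gd[, 3],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(donor_id = character(0), tissue = character(0),
                      locus = integer(0), gene = character(0),
                      cdna1 = numeric(0), cdna2 = numeric(0),
                      cdna3 = numeric(0), gdna1 = numeric(0),
                      gdna2 = numeric(0), gdna3 = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate per-sample open-chromatin peak sets
#'
#' Plants three region classes on a toy genome: shared-by-all, fetal-only
#' (FH/FK) and aged-only (AH/AK). Regions are laid on a regular grid so
#' they never collide. Each sample then contains each of its group's
#' planted regions independently with probability
#' \code{peakSim$presenceProb}, with boundaries jittered uniformly by up
#' to \code{peakSim$jitter} bp.
#'
#' @param spec a [CohortSpec-class].
#' @return list with elements \code{samples} (list of [PeakSet-class], one
#'   per sample) and \code{truth} (a \code{GRanges} of planted regions
#'   with a \code{class} column: \code{shared}, \code{fetal},
#'   \code{aged}).
#' @export
simulatePeakSets <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  set.seed(.deriveSeed(spec@seed, 4L))
  p <- spec@peakSim
  nTot <- p$nShared + p$nFetalOnly + p$nAgedOnly
  if (nTot == 0) {
    truth <- GenomicRanges::GRanges()
  } else {
    pitch <- floor(p$genomeLength / (nTot + 1))
    if (pitch <= p$width + 2 * p$jitter)
      .stopf("toy genome too small for requested planted regions",
             class = "devmqtl_domain_error")
    starts <- pitch * seq_len(nTot)
    cls <- sample(rep(c("shared", "fetal", "aged"),
                      c(p$nShared, p$nFetalOnly, p$nAgedOnly)))
    truth <- GenomicRanges::GRanges(p$contig,
      IRanges::IRanges(start = starts, width = p$width), class = cls)
  }
  samples <- list()
  for (grp in .PEAK_GROUPS) {
    want <- c("shared", if (grp %in% c("FH", "FK")) "fetal" else "aged")
    base <- truth[truth$class %in% want]
    for (i in seq_len(spec@nPeakSamples[[grp]])) {
      keep <- runif(length(base)) < p$presenceProb
      gr <- base[keep]
      if (length(gr) && p$jitter > 0) {
        js <- as.integer(round(runif(length(gr), -p$jitter, p$jitter)))
        je <- as.integer(round(runif(length(gr), -p$jitter, p$jitter)))
        GenomicRanges::start(gr) <- pmax(1L, GenomicRanges::start(gr) + js)
        GenomicRanges::end(gr) <- pmax(GenomicRanges::start(gr),
                                       GenomicRanges::end(gr) + je)
      }
      S4Vectors::mcols(gr) <- NULL
      samples[[sprintf("%s%02d", grp, i)]] <-
        peakSet(gr, sampleId = sprintf("%s%02d", grp, i), group = grp)
    }
  }
  list(samples = samples, truth = truth)
}

#' Simulate marker-gene qPCR expression
#'
#' Ct values for cartilage marker genes (COL2A1, ACAN, MATN3) and
#' housekeeping genes (18S, HPRT1, GAPDH) per donor, with a configurable
#' marker Ct shift in FC relative to FL (\code{markerDeltaCt}; negative
#' means markers amplify earlier, i.e. higher expression, in cartilage).
#'
#' @param spec a [CohortSpec-class].
#' @param donors donor table from [simulateDonors()].
#' @param ctSd technical sd of Ct values (cycles).
#' @return long data.frame: \code{donor_id}, \code{tissue}, \code{gene},
#'   \code{role} (marker/housekeeper), \code{ct}.
#' @export
simulateMarkerExpression <- function(spec, donors, ctSd = 0.25) {
  stopifnot(is(spec, "CohortSpec"))
  set.seed(.deriveSeed(spec@seed, 5L))
  if (nrow(donors) == 0)
    return(data.frame(donor_id = character(0), tissue = character(0),
                      gene = character(0), role = character(0),
                      ct = numeric(0)))
  markers <- c("COL2A1", "ACAN", "MATN3")
  house <- c("18S", "HPRT1", "GAPDH")
  houseCt <- c(`18S` = 12, HPRT1 = 24, GAPDH = 19)
  markerCt <- c(COL2A1 = 26, ACAN = 27, MATN3 = 28)
  rows <- list()
  for (g in c(markers, house)) {
    isMarker <- g %in% markers
    base <- if (isMarker) markerCt[[g]] else houseCt[[g]]
    shift <- if (isMarker) ifelse(donors$tissue == "FC",
                                  spec@markerDeltaCt, 0) else 0
    rows[[g]] <- data.frame(
      donor_id = donors$donor_id, tissue = donors$tissue, gene = g,
      role = if (isMarker) "marker" else "housekeeper",
      ct = base + shift + rnorm(nrow(donors), 0, ctSd),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Simulate a complete cohort
#'
#' Runs every simulation stage in a fixed order under the spec's master
#' seed: donors and genotypes, methylation duplicates, AEI triplicates,
#' marker expression and peak sets. Identical spec (including seed) gives
#' identical output.
#'
#' @param spec a [CohortSpec-class].
#' @param panel a [LocusPanel-class]; defaults to the bundled panel.
#' @return named list: \code{donors}, \code{methylation}, \code{aei},
#'   \code{expression}, \code{peaks} (list with \code{samples},
#'   \code{truth}), \code{panel}, \code{spec}.
#' @examples
#' cohort <- simulateCohort(cohortSpec(seed = 7,
#'   nPerTissue = c(FL = 6, FC = 10, AC = 10)))
#' head(cohort$methylation)
#' @export
simulateCohort <- function(spec, panel = readLocusTable(
    system.file("extdata", "oa_locus_panel.tsv", package = "devmqtl"))) {
  donors <- simulateDonors(spec, panel)
  meth <- simulateMethylation(spec, donors, panel)
  aei <- simulateAEI(spec, donors, meth, panel)
  expr <- simulateMarkerExpression(spec, donors)
  peaks <- simulatePeakSets(spec)
  list(donors = donors, methylation = meth, aei = aei, expression = expr,
       peaks = peaks, panel = panel, spec = spec)
}
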