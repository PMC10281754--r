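## genomic_intervals module: consensus peak derivation, four-way
## shared/unique classification, point intersection, chromatin-state
## enrichment, LD-proxy prioritization.
##
## Internally every interval is a GRanges (1-based, closed, the
## Bioconductor convention); conversion from BED's 0-based half-open
## coordinates is confined to the I/O helpers below, and 1-based point
## positions (as printed in locus tables) map directly onto GRanges.

#' Construct a per-sample peak set
#'
#' Normalizes the intervals (sort + self-merge) so every [PeakSet-class]
#' holds disjoint, sorted peaks regardless of how its input was split.
#'
#' @param gr a \code{GRanges} of called peaks (any order, overlaps
#'   allowed).
#' @param sampleId sample identifier.
#' @param group one of \code{FH}, \code{FK}, \code{AH}, \code{AK}.
#' @return a [PeakSet-class].
#' @export
peakSet <- function(gr, sampleId, group) {
  new("PeakSet", sampleId = as.character(sampleId),
      group = as.character(group), peaks = reduce(sort(gr)))
}

#' Peaks of a peak set
#' @param x a [PeakSet-class].
#' @return the normalized \code{GRanges}.
#' @export
peaks <- function(x) { stopifnot(is(x, "PeakSet")); x@peaks }

#' @describeIn PeakSet-class compact console summary
#' @param object a \code{PeakSet}.
#' @export
setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet %s (group %s): %d peaks, %s bp\n", object@sampleId,
              object@group, length(object@peaks),
              format(sum(width(object@peaks)), big.mark = ",")))
})

#' Read a BED file of peaks
#'
#' @param path BED3+ file path.
#' @param sampleId,group passed to [peakSet()]; when \code{NULL} the raw
#'   \code{GRanges} is returned instead.
#' @return a [PeakSet-class] (or \code{GRanges} if ids are \code{NULL}).
#' @export
readPeakBed <- function(path, sampleId = NULL, group = NULL) {
  if (!file.exists(path))
    .stopf("BED file not found: %s", path, class = "devmqtl_io_error")
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(sampleId)) return(gr)
  peakSet(gr, sampleId, group)
}

#' Write intervals as BED
#'
#' @param gr a \code{GRanges}; an mcol named \code{name} (or the column
#'   named by \code{nameCol}) becomes BED column 4.
#' @param path output path.
#' @param nameCol optional mcol to use as the BED name field.
#' @return \code{path}, invisibly.
#' @export
writeBed <- function(gr, path, nameCol = NULL) {
  if (!is.null(nameCol)) {
    gr$name <- mcols(gr)[[nameCol]]
  }
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Consensus peaks supported by at least k samples
#'
#' Base-level definition: a genomic position belongs to the consensus iff
#' it is covered by peaks from at least \code{minSamples} of the
#' \code{n} samples; the result is the set of maximal such intervals,
#' sorted and disjoint. This occupancy rule (e.g. 4/6 fetal, 3/5 aged
#' samples) is deterministic and order-independent.
#'
#' @param samples list of [PeakSet-class] (all one group) or of
#'   \code{GRanges}.
#' @param minSamples integer k, \code{1 <= k <= length(samples)}.
#' @return a \code{GRanges} of consensus intervals.
#' @export
consensusPeaks <- function(samples, minSamples) {
  n <- length(samples)
  if (minSamples < 1 || minSamples > n)
    .stopf("minSamples must lie in [1, %d], got %s", n, minSamples,
           class = "devmqtl_domain_error")
  grs <- lapply(samples, function(s) if (is(s, "PeakSet")) peaks(s) else
                reduce(sort(s)))
  if (is(samples[[1L]], "PeakSet")) {
    grp <- unique(vapply(samples, function(s) s@group, ""))
    if (length(grp) != 1L)
      .stopf("all samples must belong to one group, got: %s",
             paste(grp, collapse = ", "), class = "devmqtl_domain_error")
  }
  cov <- coverage(do.call(c, unname(grs)))
  ir <- slice(cov, lower = minSamples, rangesOnly = TRUE)
  gr <- as(ir, "GRanges")
  sort(gr[width(gr) >= 1])
}

#' Classify regions shared between and unique to tissue groups
#'
#' Works on the merged union of the four consensus sets. Each union
#' region is labeled \code{all_four} if it overlaps (>= 1 bp, or the
#' fraction set by \code{minOverlapFrac}) a region in every set,
#' \code{fetal_unique} if it overlaps FH or FK but neither aged set,
#' \code{aged_unique} for the converse, and \code{other} otherwise.
#'
#' @param FH,FK,AH,AK consensus \code{GRanges} per group.
#' @param minOverlapFrac minimum fraction of the union region that a
#'   set's overlap must cover to count (default 0: any >= 1 bp overlap).
#' @return list: \code{regions} (union \code{GRanges} with a
#'   \code{category} mcol and per-set logical mcols) and \code{counts}
#'   (named integer vector over categories).
#' @export
classifySharedUnique <- function(FH, FK, AH, AK, minOverlapFrac = 0) {
  sets <- list(FH = FH, FK = FK, AH = AH, AK = AK)
  union <- reduce(sort(do.call(c, unname(sets))))
  hit <- function(set) {
    if (minOverlapFrac <= 0) return(overlapsAny(union, set))
    ov <- findOverlaps(union, set)
    w <- width(pintersect(union[queryHits(ov)], set[subjectHits(ov)]))
    cover <- tapply(w, queryHits(ov), sum)
    out <- logical(length(union))
    idx <- as.integer(names(cover))
    out[idx] <- as.numeric(cover) / width(union)[idx] >= minOverlapFrac
    out
  }
  inSet <- vapply(sets, hit, logical(length(union)))
  if (length(union) == 1L) inSet <- matrix(inSet, nrow = 1,
                                           dimnames = list(NULL, names(sets)))
  fet <- inSet[, "FH"] | inSet[, "FK"]
  aged <- inSet[, "AH"] | inSet[, "AK"]
  category <- ifelse(rowSums(inSet) == 4L, "all_four",
              ifelse(fet & !aged, "fetal_unique",
              ifelse(aged & !fet, "aged_unique", "other")))
  mcols(union)$category <- category
  for (nm in names(sets)) mcols(union)[[paste0("in_", nm)]] <- inSet[, nm]
  counts <- setNames(integer(4),
                     c("all_four", "fetal_unique", "aged_unique", "other"))
  tab <- table(category)
  counts[names(tab)] <- as.integer(tab)
  list(regions = union, counts = counts)
}

#' Intersect point positions with intervals
#'
#' Points are 1-based positions (CpGs, SNVs) as printed in locus tables;
#' they are matched against 1-based closed \code{GRanges} intervals,
#' which is equivalent to the BED half-open rule "s <= p-1 < e" after
#' import. Points on chromosomes absent from the intervals simply miss
#' (recorded, not an error).
#'
#' @param points data.frame with columns \code{chrom} and \code{pos}
#'   (1-based); other columns are carried through.
#' @param intervals a \code{GRanges}.
#' @return \code{points} with \code{hit} (logical), \code{n_hits}, and
#'   \code{hit_intervals} (comma-separated "start-end" strings of
#'   1-based overlapping intervals, empty when none).
#' @export
intersectPoints <- function(points, intervals) {
  stopifnot(all(c("chrom", "pos") %in% names(points)))
  out <- points
  out$hit <- FALSE; out$n_hits <- 0L; out$hit_intervals <- ""
  if (!nrow(points) || !length(intervals)) return(out)
  pg <- GRanges(as.character(points$chrom),
                IRanges(points$pos, points$pos))
  ov <- suppressWarnings(findOverlaps(pg, intervals))
  if (length(ov)) {
    qh <- queryHits(ov); sh <- subjectHits(ov)
    lab <- sprintf("%d-%d", start(intervals)[sh], end(intervals)[sh])
    agg <- tapply(lab, qh, paste, collapse = ",")
    cnt <- table(qh)
    idx <- as.integer(names(agg))
    out$hit[idx] <- TRUE
    out$n_hits[idx] <- as.integer(cnt[names(agg)])
    out$hit_intervals[idx] <- as.character(agg)
  }
  out
}

#' Chromatin-state enrichment of peaks
#'
#' Assigns every peak to the chromatin state with which it shares the
#' most bases (ties broken by state-map order; peaks with no overlap get
#' \code{"unannotated"}). Observed is the fraction of peaks per state;
#' expected is the state's share of the total state-map length; fold is
#' observed/expected and the p-value is a two-sided exact binomial test
#' of the observed peak count against the expected fraction.
#'
#' @param peaks a \code{GRanges} of peaks.
#' @param stateMap a \code{GRanges} partitioning the analyzed contigs,
#'   with a \code{state} mcol (BED4 name column after
#'   [readPeakBed()]).
#' @return data.frame: \code{state}, \code{n_peaks}, \code{observed},
#'   \code{expected}, \code{fold}, \code{p}.
#' @export
stateEnrichment <- function(peaks, stateMap) {
  if (is.null(stateMap$state)) {
    if (!is.null(stateMap$name)) stateMap$state <- stateMap$name
    else .stopf("stateMap needs a 'state' (or BED 'name') column",
                class = "devmqtl_domain_error")
  }
  states <- unique(stateMap$state)
  ov <- findOverlaps(peaks, stateMap)
  w <- width(pintersect(peaks[queryHits(ov)], stateMap[subjectHits(ov)]))
  assigned <- rep("unannotated", length(peaks))
  if (length(ov)) {
    df <- data.frame(peak = queryHits(ov),
                     state = stateMap$state[subjectHits(ov)], w = w)
    agg <- stats::aggregate(w ~ peak + state, df, sum)
    ## deterministic winner: max overlap, ties to earlier state-map order
    agg$stateOrd <- match(agg$state, states)
    agg <- agg[order(agg$peak, -agg$w, agg$stateOrd), ]
    best <- agg[!duplicated(agg$peak), ]
    assigned[best$peak] <- best$state
  }
  genomeLen <- sum(as.numeric(width(stateMap)))
  stateLen <- tapply(as.numeric(width(stateMap)), stateMap$state, sum)
  n <- length(peaks)
  rows <- lapply(states, function(st) {
    k <- sum(assigned == st)
    expFrac <- unname(stateLen[st]) / genomeLen
    data.frame(state = st, n_peaks = k, observed = k / n,
               expected = expFrac, fold = (k / n) / expFrac,
               p = binom.test(k, n, expFrac)$p.value)
  })
  out <- do.call(rbind, rows)
  k <- sum(assigned == "unannotated")
  if (k > 0)
    out <- rbind(out, data.frame(state = "unannotated", n_peaks = k,
                                 observed = k / n, expected = NA_real_,
                                 fold = NA_real_, p = NA_real_))
  rownames(out) <- NULL
  out
}

#' Prioritize LD-proxy variants by open chromatin
#'
#' Keeps proxies in high linkage disequilibrium with the association
#' signal (\code{ld_r2 > r2Min}, strict) and classifies each by which
#' consensus open-chromatin sets contain its position:
#' \code{all_tissues} (all four), \code{fetal_only} (FH and/or FK but no
#' aged set), \code{aged_only} (converse), \code{partial} (some mixture),
#' \code{none} (open in no tissue). The prioritized set is the kept
#' variants whose class is not \code{none}.
#'
#' @param proxies data.frame with \code{rsid}, \code{chrom}, \code{pos}
#'   (1-based) and \code{ld_r2}; extra columns carried through.
#' @param consensus named list of \code{GRanges}: \code{FH}, \code{FK},
#'   \code{AH}, \code{AK}.
#' @param r2Min LD threshold (default 0.8, strict inequality).
#' @return data.frame of kept proxies with per-set logical columns
#'   \code{in_FH..in_AK}, \code{class}, and \code{prioritized}
#'   (\code{class != "none"}).
#' @export
prioritizeVariants <- function(proxies, consensus, r2Min = 0.8) {
  stopifnot(all(c("rsid", "chrom", "pos", "ld_r2") %in% names(proxies)))
  if (any(proxies$ld_r2 < 0 | proxies$ld_r2 > 1))
    .stopf("ld_r2 must lie in [0,1]", class = "devmqtl_domain_error")
  keep <- proxies[proxies$ld_r2 > r2Min, , drop = FALSE]
  if (!nrow(keep)) {
    keep$class <- character(0); keep$prioritized <- logical(0)
    return(keep)
  }
  pg <- GRanges(as.character(keep$chrom), IRanges(keep$pos, keep$pos))
  for (nm in c("FH", "FK", "AH", "AK"))
    keep[[paste0("in_", nm)]] <-
      suppressWarnings(overlapsAny(pg, consensus[[nm]]))
  fet <- keep$in_FH | keep$in_FK
  aged <- keep$in_AH | keep$in_AK
  nIn <- keep$in_FH + keep$in_FK + keep$in_AH + keep$in_AK
  keep$class <- ifelse(nIn == 4L, "all_tissues",
                ifelse(fet & !aged, "fetal_only",
                ifelse(aged & !fet, "aged_only",
                ifelse(nIn > 0L, "partial", "none"))))
  keep$prioritized <- keep$class != "none"
  rownames(keep) <- NULL
  keep
}
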