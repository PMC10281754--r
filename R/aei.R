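## aei module: allelic expression imbalance from triplicate
## pyrosequencing allele percentages, exact signed-rank inference

#' Normalize a cDNA/gDNA allelic ratio
#'
#' Converts each replicate's allele-A percentage to the allelic ratio
#' \code{A / (100 - A)}; the record's normalized ratio is the geometric
#' mean cDNA ratio divided by the geometric mean gDNA ratio, cancelling
#' assay bias measured in genomic DNA (expected 50/50 in a heterozygote).
#' The geometric mean keeps the allele labelling symmetric: swapping
#' allele A and B maps the ratio exactly to its reciprocal. The record
#' fails QC if either triplicate's range on the percentage scale exceeds
#' \code{qcThreshold}; the ratio is still reported for inspection.
#'
#' @param cdnaPcts numeric vector of 3 cDNA allele-A percentages,
#'   strictly inside (0,100).
#' @param gdnaPcts numeric vector of 3 gDNA allele-A percentages.
#' @param qcThreshold triplicate-range QC threshold in percentage points
#'   (default 5).
#' @return one-row data.frame: \code{qc_pass}, \code{ratio},
#'   \code{log2_ratio}.
#' @examples
#' normalizeRatio(c(60, 60, 60), c(50, 50, 50))  # ratio 1.5
#' @export
normalizeRatio <- function(cdnaPcts, gdnaPcts, qcThreshold = 5) {
  if (length(cdnaPcts) != 3L || length(gdnaPcts) != 3L)
    .stopf("cDNA and gDNA triplicates must each have 3 values",
           class = "devmqtl_domain_error")
  vals <- c(cdnaPcts, gdnaPcts)
  if (any(!is.finite(vals)))
    .stopf("allele percentages must be finite",
           class = "devmqtl_domain_error")
  if (any(vals <= 0 | vals >= 100))
    .stopf("allele percentage at 0 or 100 gives a degenerate ratio",
           class = "devmqtl_degenerate_ratio")
  qc <- (max(cdnaPcts) - min(cdnaPcts)) <= qcThreshold &&
        (max(gdnaPcts) - min(gdnaPcts)) <= qcThreshold
  gm <- function(x) exp(mean(log(x)))
  ratio <- gm(cdnaPcts / (100 - cdnaPcts)) /
           gm(gdnaPcts / (100 - gdnaPcts))
  data.frame(qc_pass = qc, ratio = ratio, log2_ratio = log2(ratio))
}

#' Build AEI records from raw triplicates
#'
#' Applies [normalizeRatio()] to every row of a raw AEI table (columns
#' \code{cdna1..3}, \code{gdna1..3} plus identifying columns), appending
#' \code{qc_pass}, \code{ratio} and \code{log2_ratio}.
#'
#' @param raw data.frame as produced by [simulateAEI()] or read from the
#'   long AEI input format.
#' @param qcThreshold triplicate-range QC threshold (percentage points).
#' @return \code{raw} with the three derived columns appended.
#' @export
aeiRecords <- function(raw, qcThreshold = 5) {
  if (!nrow(raw)) {
    raw$qc_pass <- logical(0); raw$ratio <- numeric(0)
    raw$log2_ratio <- numeric(0)
    return(raw)
  }
  derived <- do.call(rbind, lapply(seq_len(nrow(raw)), function(i)
    normalizeRatio(as.numeric(raw[i, c("cdna1", "cdna2", "cdna3")]),
                   as.numeric(raw[i, c("gdna1", "gdna2", "gdna3")]),
                   qcThreshold)))
  cbind(raw, derived)
}

#' Exact Wilcoxon signed-rank test
#'
#' Two-sided test of symmetry about zero for a vector of (log2 allelic
#' ratio) values. Zeros are dropped before ranking; tied magnitudes get
#' midranks. For \code{n <= exactLimit} the null distribution of the
#' positive-rank sum is computed exactly by the standard counting
#' recursion over all \code{2^n} sign assignments (run on doubled ranks
#' so midranks stay integral); above that a normal approximation with
#' tie correction and continuity correction is used. The smallest
#' attainable two-sided p at n unanimous-direction observations is
#' \code{2 / 2^n} (0.0078 at n = 8, 0.0156 at n = 7).
#'
#' @param x numeric vector of values (e.g. log2 ratios).
#' @param exactLimit largest n for which the exact distribution is
#'   enumerated (default 25).
#' @return two-sided p-value in (0, 1].
#' @examples
#' signedRankExact(-(1:8) / 10)   # 2 / 2^8 = 0.0078125
#' @export
signedRankExact <- function(x, exactLimit = 25L) {
  x <- x[is.finite(x)]
  x <- x[x != 0]
  n <- length(x)
  if (n == 0L)
    .stopf("signed-rank test undefined: no nonzero values",
           class = "devmqtl_undefined_test")
  r <- rank(abs(x))          # midranks for ties
  W <- sum(r[x > 0])
  if (n <= exactLimit) {
    r2 <- as.integer(round(2 * r))   # doubled ranks are integers
    total <- sum(r2)
    ## counting recursion: distribution of the doubled positive-rank sum
    f <- numeric(total + 1L); f[1L] <- 1
    for (ri in r2) {
      g <- f * 0.5
      shifted <- c(numeric(ri), g[seq_len(total + 1L - ri)])
      f <- g + shifted
    }
    w2 <- as.integer(round(2 * W))
    pLo <- sum(f[seq_len(w2 + 1L)])
    pHi <- sum(f[(w2 + 1L):(total + 1L)])
    return(min(1, 2 * min(pLo, pHi)))
  }
  ## normal approximation with tie and continuity correction
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Per-gene AEI summary
#'
#' Summarizes QC-passing heterozygote AEI records for one gene and
#' tissue: mean and median normalized ratio and the two-sided exact
#' signed-rank p-value of the log2 ratios against balance. If every log2
#' ratio is exactly zero the test is undefined; the summary reports
#' \code{p = NA}, a note, and \code{significant = FALSE}.
#'
#' @param records AEI record table (see [aeiRecords()]); rows should
#'   already be restricted to QC-passing heterozygotes of one gene and
#'   tissue, but \code{gene}/\code{tissue} columns are filtered again
#'   defensively.
#' @param gene gene symbol.
#' @param tissue tissue label.
#' @param alpha significance level (default 0.05).
#' @return one-row data.frame: \code{gene}, \code{tissue}, \code{n},
#'   \code{mean_ratio}, \code{median_ratio}, \code{p},
#'   \code{significant}, \code{note}.
#' @export
geneAEISummary <- function(records, gene, tissue, alpha = 0.05) {
  rec <- records[records$gene == gene & records$tissue == tissue &
                 records$qc_pass, , drop = FALSE]
  if (!nrow(rec))
    return(data.frame(gene = gene, tissue = tissue, n = 0L,
                      mean_ratio = NA_real_, median_ratio = NA_real_,
                      p = NA_real_, significant = FALSE,
                      note = "no QC-passing heterozygotes"))
  p <- tryCatch(signedRankExact(rec$log2_ratio),
                devmqtl_undefined_test = function(e) NA_real_)
  note <- if (is.na(p)) "all ratios exactly balanced; test undefined"
          else ""
  data.frame(gene = gene, tissue = tissue, n = nrow(rec),
             mean_ratio = mean(rec$ratio),
             median_ratio = median(rec$ratio), p = p,
             significant = !is.na(p) && p < alpha, note = note)
}

#' AEI summaries for every gene x tissue
#'
#' @param records AEI record table from [aeiRecords()].
#' @param alpha significance level.
#' @return data.frame of [geneAEISummary()] rows.
#' @export
aeiSummaryTable <- function(records, alpha = 0.05) {
  rec <- records[records$qc_pass, , drop = FALSE]
  if (!nrow(rec))
    return(data.frame(gene = character(0), tissue = character(0),
                      n = integer(0), mean_ratio = numeric(0),
                      median_ratio = numeric(0), p = numeric(0),
                      significant = logical(0), note = character(0)))
  combos <- unique(rec[, c("gene", "tissue")])
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i)
    geneAEISummary(rec, combos$gene[i], combos$tissue[i], alpha)))
  rownames(out) <- NULL
  out
}

#' Two-group AEI comparison for unphased transcript variants
#'
#' When the transcript SNV is in linkage equilibrium with the association
#' SNV (as for RUNX2-style loci), per-donor ratios cannot be oriented by
#' phase. Instead, cDNA allelic ratios are compared between donors
#' heterozygous and homozygous at the association SNV with a two-sided
#' Wilcoxon rank-sum test (exact where no ties permit).
#'
#' @param hetRatios numeric ratios from association-SNV heterozygotes.
#' @param homRatios numeric ratios from association-SNV homozygotes.
#' @return one-row data.frame: \code{n_het}, \code{n_hom}, \code{p}.
#' @export
aeiUnphasedTest <- function(hetRatios, homRatios) {
  if (!length(hetRatios) || !length(homRatios))
    .stopf("both genotype groups must be non-empty",
           class = "devmqtl_insufficient_data")
  wt <- suppressWarnings(wilcox.test(hetRatios, homRatios))
  data.frame(n_het = length(hetRatios), n_hom = length(homRatios),
             p = wt$p.value)
}
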