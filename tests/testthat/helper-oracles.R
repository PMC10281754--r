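# Independent brute-force oracles used to cross-check the package's
# implementations on small instances. These deliberately share no code
# with the package: everything is per-base vectors or full enumeration.

suppressPackageStartupMessages(library(GenomicRanges))

bundledPanel <- function() {
  readLocusTable(system.file("extdata", "oa_locus_panel.tsv",
                             package = "devmqtl"))
}

# exact two-sided signed-rank p by literal enumeration of all 2^n sign
# assignments (midranks for ties)
bruteSignedRank <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  W <- sum(r[x > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  stats <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  pLo <- mean(stats <= W + 1e-9)
  pHi <- mean(stats >= W - 1e-9)
  min(1, 2 * min(pLo, pHi))
}

# per-base consensus on a small 1..len toy chromosome; grs is a list of
# GRanges on one chromosome
bruteConsensus <- function(grs, k, len = 2000L) {
  cov <- integer(len)
  for (gr in grs) {
    covered <- logical(len)
    for (i in seq_along(gr)) {
      s <- max(1L, start(gr)[i]); e <- min(len, end(gr)[i])
      if (s <= e) covered[s:e] <- TRUE
    }
    cov <- cov + covered
  }
  inCons <- cov >= k
  # runs of TRUE -> intervals
  r <- rle(inCons)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# brute point-in-interval: 1-based point vs 1-based closed intervals
brutePointHits <- function(pos, chrom, gr) {
  vapply(seq_along(pos), function(i) {
    any(as.character(seqnames(gr)) == chrom[i] &
        start(gr) <= pos[i] & end(gr) >= pos[i])
  }, logical(1))
}

# per-base four-way category counts on one small chromosome
bruteClassify <- function(sets, len = 2000L) {
  base <- function(gr) {
    covered <- logical(len)
    for (i in seq_along(gr)) {
      s <- max(1L, start(gr)[i]); e <- min(len, end(gr)[i])
      if (s <= e) covered[s:e] <- TRUE
    }
    covered
  }
  b <- lapply(sets, base)
  union <- b$FH | b$FK | b$AH | b$AK
  r <- rle(union); ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  cats <- vapply(keep, function(j) {
    span <- starts[j]:ends[j]
    inSet <- vapply(b, function(v) any(v[span]), logical(1))
    fet <- inSet["FH"] || inSet["FK"]; aged <- inSet["AH"] || inSet["AK"]
    if (all(inSet)) "all_four"
    else if (fet && !aged) "fetal_unique"
    else if (aged && !fet) "aged_unique"
    else "other"
  }, character(1))
  counts <- setNames(integer(4),
                     c("all_four", "fetal_unique", "aged_unique", "other"))
  tab <- table(cats)
  counts[names(tab)] <- as.integer(tab)
  counts
}

# random small GRanges on chrT within 1..len
randomToyGRanges <- function(nIntervals, len = 2000L, maxWidth = 120L) {
  s <- sample.int(len - maxWidth, nIntervals, replace = TRUE)
  w <- sample.int(maxWidth, nIntervals, replace = TRUE)
  GRanges("chrT", IRanges(s, width = w))
}

# naive average-linkage agglomeration on a distance matrix, returning
# merge heights (sorted) for comparison against hclust
bruteAverageLinkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestH <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < bestH - 1e-12) { bestH <- h; best <- c(i, j) }
    }
    heights <- c(heights, bestH)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1L]] <- merged
  }
  sort(heights)
}

# Welch two-sample t-test p-value from first principles
bruteWelchP <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * pt(-abs(tstat), df)
}

# OLS slope p-value from first principles
bruteOlsP <- function(y, x) {
  n <- length(y)
  bx <- cov(x, y) / var(x)
  a <- mean(y) - bx * mean(x)
  res <- y - a - bx * x
  se <- sqrt(sum(res^2) / (n - 2) / sum((x - mean(x))^2))
  2 * pt(-abs(bx / se), n - 2)
}

# tiny in-code locus table fixture for parse/validation edge cases
writeTinyLocusTsv <- function(path, eaf = "0.5", dupPos = FALSE) {
  hdr <- paste(c("locus", "rsid", "chrom", "snv_pos", "nea", "ea", "eaf",
                 "cpg_index", "cg_id", "cpg_pos", "discovery_p", "genes",
                 "annotation"), collapse = "\t")
  r1 <- paste(c("1", "rs1", "1", "1000", "A", "G", eaf, "1", "", "2000",
                "", "GENE1", "enhancer"), collapse = "\t")
  pos2 <- if (dupPos) "2000" else "2050"
  r2 <- paste(c("1", "rs1", "1", "1000", "A", "G", eaf, "2", "cg1", pos2,
                "0.01", "GENE1", "enhancer"), collapse = "\t")
  writeLines(c(hdr, r1, r2), path)
  path
}
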