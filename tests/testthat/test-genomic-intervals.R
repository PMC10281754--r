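gr <- function(starts, ends, chrom = "chrT")
  GRanges(chrom, IRanges(starts, ends))

test_that("consensus peaks implement base-level k-of-n coverage", {
  # three identical samples, k = 2
  s3 <- replicate(3, gr(100, 199), simplify = FALSE)
  cons <- consensusPeaks(s3, 2)
  expect_equal(start(cons), 100)
  expect_equal(end(cons), 199)

  # staggered samples (BED [0,10), [5,15), [12,20) in 1-based closed
  # form), k = 2 -> bases 6..10 and 13..15
  st <- list(gr(1, 10), gr(6, 15), gr(13, 20))
  cons2 <- consensusPeaks(st, 2)
  expect_equal(start(cons2), c(6, 13))
  expect_equal(end(cons2), c(10, 15))

  expect_error(consensusPeaks(st, 4), class = "devmqtl_domain_error")
  expect_error(consensusPeaks(st, 0), class = "devmqtl_domain_error")

  # k = 1 is the merged union; k = n is the intersection, checked against
  # independent GenomicRanges implementations
  set.seed(41)
  for (i in 1:20) {
    grs <- replicate(4, randomToyGRanges(sample(3:8, 1)), simplify = FALSE)
    u <- consensusPeaks(grs, 1)
    expect_identical(ranges(u), ranges(reduce(sort(do.call(c, grs)))))
    itr <- Reduce(GenomicRanges::intersect, lapply(grs, reduce))
    expect_identical(ranges(consensusPeaks(grs, 4)), ranges(sort(itr)))
  }
})

test_that("consensus equals per-base brute force on random instances", {
  set.seed(43)
  for (i in 1:100) {
    n <- sample(3:6, 1)
    grs <- replicate(n, randomToyGRanges(sample(2:10, 1)),
                     simplify = FALSE)
    k <- sample(seq_len(n), 1)
    got <- consensusPeaks(grs, k)
    want <- bruteConsensus(grs, k)
    expect_identical(start(got), want$start)
    expect_identical(end(got), want$end)
  }
})

test_that("consensus is invariant to input order and to pre-split peaks", {
  set.seed(47)
  grs <- replicate(5, randomToyGRanges(6), simplify = FALSE)
  a <- consensusPeaks(grs, 3)
  b <- consensusPeaks(rev(grs), 3)
  expect_identical(ranges(a), ranges(b))
  # splitting one sample's peaks into adjacent pieces changes nothing
  split1 <- grs
  g <- split1[[1]]
  pieces <- c(GRanges("chrT", IRanges(start(g), start(g) + 4)),
              GRanges("chrT", IRanges(start(g) + 5, end(g))))
  split1[[1]] <- pieces
  expect_identical(ranges(consensusPeaks(split1, 3)), ranges(a))
})

test_that("shared/unique classification matches set algebra", {
  # identical four sets
  base <- gr(c(100, 500), c(199, 599))
  cls <- classifySharedUnique(base, base, base, base)
  expect_identical(unname(cls$counts["all_four"]), 2L)
  expect_identical(sum(cls$counts[c("fetal_unique", "aged_unique",
                                    "other")]), 0L)

  # one planted region per category
  fh <- gr(c(100, 1000), c(199, 1099))   # 100s shared, 1000s fetal
  fk <- gr(c(100, 1000), c(199, 1099))
  ah <- gr(c(100, 2000), c(199, 2099))   # 2000s aged
  ak <- gr(c(100, 2000), c(199, 2099))
  cls2 <- classifySharedUnique(fh, fk, ah, ak)
  expect_identical(unname(cls2$counts[c("all_four", "fetal_unique",
                                        "aged_unique")]), c(1L, 1L, 1L))

  # empty aged sets: everything fetal-unique
  cls3 <- classifySharedUnique(fh, fk, GRanges(), GRanges())
  expect_identical(unname(cls3$counts["fetal_unique"]), 2L)

  # base conservation: labeled lengths sum to the union length
  set.seed(53)
  sets <- lapply(1:4, function(i) reduce(randomToyGRanges(8)))
  cls4 <- classifySharedUnique(sets[[1]], sets[[2]], sets[[3]], sets[[4]])
  expect_identical(sum(width(cls4$regions)),
                   sum(width(reduce(do.call(c, sets)))))

  # category counts equal the per-base brute force on random instances
  for (i in 1:60) {
    sets <- list(FH = randomToyGRanges(sample(2:6, 1)),
                 FK = randomToyGRanges(sample(2:6, 1)),
                 AH = randomToyGRanges(sample(2:6, 1)),
                 AK = randomToyGRanges(sample(2:6, 1)))
    got <- classifySharedUnique(sets$FH, sets$FK, sets$AH, sets$AK)$counts
    expect_identical(got, bruteClassify(sets))
  }
})

test_that("point intersection follows the half-open convention", {
  # BED [99,100) is GRanges [100,100]: position 100 hits
  hit <- intersectPoints(data.frame(chrom = "chrT", pos = 100),
                         gr(100, 100))
  expect_true(hit$hit)
  # BED [0,99) is GRanges [1,99]: position 100 misses
  miss <- intersectPoints(data.frame(chrom = "chrT", pos = 100),
                          gr(1, 99))
  expect_false(miss$hit)
  # unknown chromosome: miss, not an error
  other <- intersectPoints(data.frame(chrom = "chrZ", pos = 100),
                           gr(1, 200))
  expect_false(other$hit)

  # all overlapping intervals are reported
  multi <- intersectPoints(data.frame(chrom = "chrT", pos = 150),
                           gr(c(100, 140), c(200, 160)))
  expect_identical(multi$n_hits, 2L)
  expect_match(multi$hit_intervals, "100-200")

  # random points vs brute-force double loop
  set.seed(59)
  for (i in 1:20) {
    ivs <- randomToyGRanges(20)
    pts <- data.frame(chrom = sample(c("chrT", "chrZ"), 100,
                                     replace = TRUE, prob = c(0.9, 0.1)),
                      pos = sample.int(2000, 100, replace = TRUE))
    got <- intersectPoints(pts, ivs)
    expect_identical(got$hit, brutePointHits(pts$pos, pts$chrom, ivs))
  }
})

test_that("state enrichment assigns by maximal overlap with binomial p", {
  # half/half genome, peaks uniform: fold ~ 1
  states <- GRanges("chrT", IRanges(c(1, 50001), c(50000, 100000)),
                    state = c("Enh", "Quies"))
  set.seed(61)
  pk <- GRanges("chrT", IRanges(sample.int(99500, 400), width = 200))
  enr <- stateEnrichment(pk, states)
  expect_equal(enr$fold[enr$state == "Enh"], 1, tolerance = 0.25)
  expect_equal(enr$fold[enr$state == "Quies"], 1, tolerance = 0.25)

  # all peaks inside a 10% state: fold = 10
  states10 <- GRanges("chrT", IRanges(c(1, 10001), c(10000, 100000)),
                      state = c("Enh", "Quies"))
  pk10 <- GRanges("chrT", IRanges(seq(100, 9000, by = 500), width = 50))
  enr10 <- stateEnrichment(pk10, states10)
  expect_equal(enr10$fold[enr10$state == "Enh"], 10)
  expect_equal(enr10$observed[enr10$state == "Enh"], 1)

  # binomial p equals the independent exact computation
  k <- enr$n_peaks[enr$state == "Enh"]; n <- sum(enr$n_peaks)
  pexp <- 0.5
  dens <- dbinom(0:n, n, pexp)
  pOracle <- sum(dens[dens <= dbinom(k, n, pexp) * (1 + 1e-7)])
  expect_equal(enr$p[enr$state == "Enh"], pOracle, tolerance = 1e-9)

  # a peak outside the map is unannotated
  pkOut <- c(pk10[1], GRanges("chrT", IRanges(200000, 200100)))
  enrOut <- stateEnrichment(pkOut, states10)
  expect_identical(enrOut$n_peaks[enrOut$state == "unannotated"], 1L)
})

test_that("LD-proxy prioritization filters on r2 and classifies by tissue", {
  cons <- list(FH = gr(c(100, 1000), c(199, 1099)),
               FK = gr(c(100, 1000), c(199, 1099)),
               AH = gr(c(100, 2000), c(199, 2099)),
               AK = gr(c(100, 2000), c(199, 2099)))
  prox <- data.frame(
    rsid = paste0("rs", 1:5), chrom = "chrT",
    pos = c(150, 1050, 2050, 5000, 150),
    ld_r2 = c(0.9, 0.95, 0.85, 0.99, 0.75))
  res <- prioritizeVariants(prox, cons)
  expect_identical(nrow(res), 4L)          # rs5 excluded at r2 = 0.75
  expect_false("rs5" %in% res$rsid)
  expect_identical(res$class[res$rsid == "rs1"], "all_tissues")
  expect_identical(res$class[res$rsid == "rs2"], "fetal_only")
  expect_identical(res$class[res$rsid == "rs3"], "aged_only")
  expect_identical(res$class[res$rsid == "rs4"], "none")
  expect_identical(sum(res$prioritized), 3L)
  # boundary is strict: r2 = 0.8 exactly is excluded
  prox2 <- data.frame(rsid = "rsX", chrom = "chrT", pos = 150, ld_r2 = 0.8)
  expect_identical(nrow(prioritizeVariants(prox2, cons)), 0L)
  expect_error(prioritizeVariants(
    data.frame(rsid = "r", chrom = "chrT", pos = 1, ld_r2 = 1.4), cons),
    class = "devmqtl_domain_error")
})

test_that("peak sets normalize on construction and BED I/O round-trips", {
  messy <- GRanges("chrT", IRanges(c(300, 100, 150), c(400, 160, 220)))
  ps <- peakSet(messy, "s1", "FH")
  expect_identical(length(peaks(ps)), 2L)   # overlapping pair merged
  expect_identical(start(peaks(ps)), c(100L, 300L))

  f <- withr::local_tempfile(fileext = ".bed")
  writeBed(peaks(ps), f)
  back <- readPeakBed(f, "s1", "FH")
  expect_identical(ranges(peaks(back)), ranges(peaks(ps)))
  expect_error(readPeakBed(tempfile()), class = "devmqtl_io_error")
})
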