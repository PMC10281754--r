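test_that("ratio normalization follows the cDNA/gDNA definition", {
  r <- normalizeRatio(c(60, 60, 60), c(50, 50, 50))
  expect_true(r$qc_pass)
  expect_equal(r$ratio, 1.5)
  expect_equal(r$log2_ratio, log2(1.5))

  r0 <- normalizeRatio(c(50, 50, 50), c(50, 50, 50))
  expect_equal(r0$ratio, 1)
  expect_equal(r0$log2_ratio, 0)

  # triplicate range 6 > 5 on the percentage scale fails QC
  rq <- normalizeRatio(c(60, 66, 60), c(50, 50, 50))
  expect_false(rq$qc_pass)

  expect_error(normalizeRatio(c(0, 50, 50), c(50, 50, 50)),
               class = "devmqtl_degenerate_ratio")
  expect_error(normalizeRatio(c(100, 50, 50), c(50, 50, 50)),
               class = "devmqtl_degenerate_ratio")
  expect_error(normalizeRatio(c(50, 50), c(50, 50, 50)),
               class = "devmqtl_domain_error")

  # allele-label flip maps ratio to its reciprocal
  set.seed(3)
  for (i in 1:25) {
    cd <- runif(3, 30, 70); gd <- runif(3, 45, 55)
    a <- normalizeRatio(cd, gd)
    b <- normalizeRatio(100 - cd, 100 - gd)
    expect_equal(b$ratio, 1 / a$ratio, tolerance = 1e-12)
    expect_equal(b$log2_ratio, -a$log2_ratio, tolerance = 1e-12)
  }
})

test_that("exact signed-rank p-values hit the unanimous-direction extremes", {
  # eight same-sign values with distinct magnitudes: p = 2/2^8
  expect_equal(signedRankExact(-(1:8) / 10), 2 / 256)
  expect_equal(round(signedRankExact(-(1:8) / 10), 3), 0.008)
  # seven: p = 2/2^7
  expect_equal(signedRankExact((1:7) / 10), 2 / 128)
  expect_equal(round(signedRankExact((1:7) / 10), 3), 0.016)
  # perfectly symmetric pair
  expect_equal(signedRankExact(c(0.3, -0.3)), 1)
  # zeros are dropped before ranking
  expect_equal(signedRankExact(c(0, 0, -(1:8) / 10)), 2 / 256)
  expect_error(signedRankExact(c(0, 0)), class = "devmqtl_undefined_test")
})

test_that("counting recursion equals literal 2^n enumeration", {
  set.seed(19)
  for (i in 1:120) {
    n <- sample(2:12, 1)
    x <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties/zeros
    x <- x[x != 0]
    if (length(x) == 0) next
    expect_equal(signedRankExact(x), bruteSignedRank(x),
                 tolerance = 1e-12)
  }
  # four values, three negative one positive, hand-enumerated over 2^4:
  # ranks 1..4, W+ = 2; subsets with sum <= 2 are {}, {1}, {2}, so
  # P(W <= 2) = 3/16 and the two-sided p is 6/16
  expect_equal(signedRankExact(c(-0.4, -0.3, 0.2, -0.1)), 6 / 16)
})

test_that("signed-rank p is invariant to allele flip and matches wilcox area", {
  set.seed(23)
  x <- rnorm(10)
  expect_equal(signedRankExact(x), signedRankExact(-x))
  # agreement with the standard exact implementation when no ties
  x <- x[abs(x) > 1e-6]
  ref <- wilcox.test(x, exact = TRUE)$p.value
  expect_equal(signedRankExact(x), ref, tolerance = 1e-12)
  # large-n approximation path stays close to the reference
  set.seed(24)
  y <- rnorm(40, 0.3)
  ref2 <- wilcox.test(y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(signedRankExact(y), ref2, tolerance = 1e-10)
})

test_that("per-gene summaries aggregate QC-passing heterozygotes", {
  rec <- data.frame(
    donor_id = sprintf("d%d", 1:6), gene = "RWDD2B", tissue = "FC",
    qc_pass = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    ratio = c(0.7, 0.75, 0.8, 0.72, 0.68, 2.0),
    log2_ratio = log2(c(0.7, 0.75, 0.8, 0.72, 0.68, 2.0)))
  s <- geneAEISummary(rec, "RWDD2B", "FC")
  expect_identical(s$n, 5L)                       # QC-failing row excluded
  expect_equal(s$mean_ratio, mean(rec$ratio[1:5]))
  expect_equal(s$p, 2 / 32)                       # unanimous at n = 5
  expect_false(s$significant)                     # 0.0625 > 0.05

  # degenerate: all ratios exactly balanced
  recB <- within(rec, { ratio <- 1; log2_ratio <- 0 })
  sB <- geneAEISummary(recB, "RWDD2B", "FC")
  expect_true(is.na(sB$p))
  expect_false(sB$significant)
  expect_match(sB$note, "undefined")

  s0 <- geneAEISummary(rec[0, ], "RWDD2B", "FC")
  expect_identical(s0$n, 0L)
})

test_that("a planted imbalance is recovered from the synthetic cohort", {
  eff <- cohortSpec()@effects
  eff$aei_log2_mean <- ifelse(eff$tissue == "FC", -0.45, 0)
  eff$meqtl_slope <- 0
  spec <- cohortSpec(seed = 31, nPerTissue = c(FL = 0L, FC = 80L, AC = 0L),
                     effects = eff, triplicateSd = 1, dropoutRate = 0)
  co <- simulateCohort(spec, bundledPanel())
  rec <- aeiRecords(co$aei)
  s <- aeiSummaryTable(rec)
  sub <- s[s$tissue == "FC" & s$n >= 10, ]
  # 2^-0.45 ~ 0.732
  expect_equal(mean(sub$mean_ratio), 2^-0.45, tolerance = 0.05)
  expect_true(all(sub$significant))
})

test_that("unphased two-group comparison behaves as a rank-sum test", {
  set.seed(37)
  het <- rnorm(10, 1.4, 0.1); hom <- rnorm(12, 1.0, 0.1)
  res <- aeiUnphasedTest(het, hom)
  expect_identical(c(res$n_het, res$n_hom), c(10L, 12L))
  expect_equal(res$p, wilcox.test(het, hom)$p.value)
  expect_lt(res$p, 0.01)
  expect_error(aeiUnphasedTest(numeric(0), hom),
               class = "devmqtl_insufficient_data")
})
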