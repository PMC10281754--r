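smallSpec <- function(seed = 3, ...) {
  cohortSpec(seed = seed, nPerTissue = c(FL = 8L, FC = 15L, AC = 15L), ...)
}

test_that("genotype simulation follows Hardy-Weinberg proportions", {
  expect_identical(simulateGenotypes(0.5, 0), integer(0))
  expect_error(simulateGenotypes(0, 10), class = "devmqtl_domain_error")
  expect_error(simulateGenotypes(1.2, 10), class = "devmqtl_domain_error")

  d <- simulateGenotypes(0.83, 2e4, seed = 42)
  expect_true(all(d %in% 0:2))
  # P(dosage 2) = 0.83^2 = 0.6889
  expect_equal(mean(d == 2), 0.6889, tolerance = 0.02)

  # chi-square GOF against HWE at n = 1e4 is non-significant (alpha 1e-3)
  for (eaf in c(0.2, 0.47, 0.5)) {
    d <- simulateGenotypes(eaf, 1e4, seed = 7)
    obs <- tabulate(d + 1L, 3L)
    expected <- c((1 - eaf)^2, 2 * eaf * (1 - eaf), eaf^2)
    chi <- sum((obs - 1e4 * expected)^2 / (1e4 * expected))
    expect_lt(chi, qchisq(1 - 0.001, df = 2))
  }

  # symmetric at eaf = 0.5
  d <- simulateGenotypes(0.5, 5e4, seed = 1)
  expect_equal(as.vector(table(d) / 5e4), c(0.25, 0.5, 0.25),
               tolerance = 0.02)
})

test_that("cohort simulation is deterministic and respects ranges", {
  panel <- bundledPanel()
  a <- simulateCohort(smallSpec(), panel)
  b <- simulateCohort(smallSpec(), panel)
  expect_identical(a$donors, b$donors)
  expect_identical(a$methylation, b$methylation)
  expect_identical(a$aei, b$aei)
  expect_identical(a$expression, b$expression)
  expect_identical(lapply(a$peaks$samples, peaks),
                   lapply(b$peaks$samples, peaks))

  m <- a$methylation
  expect_true(all(m$rep1 >= 0 & m$rep1 <= 100))
  expect_true(all(m$rep2 >= 0 & m$rep2 <= 100))
  # measured mean betas can reach the scale ends when replicates truncate
  expect_true(all(m$mean_beta[m$qc_pass] >= 0 & m$mean_beta[m$qc_pass] <= 1))
  expect_true(all(a$aei$cdna1 > 0 & a$aei$cdna1 < 100))

  # a different seed changes the data
  c2 <- simulateCohort(smallSpec(seed = 4), panel)
  expect_false(identical(a$methylation, c2$methylation))

  # fetal/aged age ranges
  expect_true(all(a$donors$age[a$donors$tissue == "FL"] >= 32 &
                  a$donors$age[a$donors$tissue == "FL"] <= 84))
  expect_true(all(a$donors$age[a$donors$tissue == "AC"] >= 25 &
                  a$donors$age[a$donors$tissue == "AC"] <= 91))
})

test_that("noise and dropout knobs behave at their extremes", {
  panel <- bundledPanel()
  spec0 <- smallSpec(replicateSd = 0, dropoutRate = 0)
  donors <- simulateDonors(spec0, panel)
  m <- simulateMethylation(spec0, donors, panel)
  expect_identical(nrow(m), nrow(donors) * 39L)
  expect_equal(m$rep1, m$rep2)
  expect_true(all(m$qc_pass))

  spec1 <- smallSpec(dropoutRate = 1)
  m1 <- simulateMethylation(spec1, simulateDonors(spec1, panel), panel)
  expect_identical(nrow(m1), 0L)
})

test_that("AEI simulation uses heterozygotes only and respects the null", {
  panel <- bundledPanel()
  eff <- cohortSpec()@effects
  eff$aei_log2_mean <- 0
  eff$meqtl_slope <- 0
  spec <- cohortSpec(seed = 5, nPerTissue = c(FL = 0L, FC = 80L, AC = 0L),
                     effects = eff, triplicateSd = 0.3, dropoutRate = 0)
  co <- simulateCohort(spec, panel)
  het <- co$donors$donor_id[co$donors$dosage.1 == 1L]
  got <- unique(co$aei$donor_id[co$aei$locus == 1])
  expect_true(all(got %in% het))
  rec <- aeiRecords(co$aei)
  # null structure: mean normalized ratio near 1
  expect_equal(mean(rec$ratio[rec$qc_pass]), 1, tolerance = 0.02)

  # no heterozygotes -> empty collection
  d2 <- co$donors
  for (l in 1:7) d2[[paste0("dosage.", l)]] <- 0L
  expect_identical(nrow(simulateAEI(spec, d2, co$methylation, panel)), 0L)
})

test_that("planted peak regions are recovered exactly without noise", {
  spec <- smallSpec(peakSim = list(contig = "chrT", genomeLength = 1e6,
                                   nShared = 20L, nFetalOnly = 8L,
                                   nAgedOnly = 9L, width = 300L,
                                   presenceProb = 1, jitter = 0L))
  sim <- simulatePeakSets(spec)
  grp <- vapply(sim$samples, function(s) s@group, "")
  cons <- lapply(c(FH = "FH", FK = "FK", AH = "AH", AK = "AK"), function(g)
    consensusPeaks(sim$samples[grp == g],
                   if (g %in% c("FH", "FK")) 4L else 3L))
  cls <- classifySharedUnique(cons$FH, cons$FK, cons$AH, cons$AK)
  expect_identical(unname(cls$counts[c("all_four", "fetal_unique",
                                       "aged_unique")]),
                   c(20L, 8L, 9L))
  expect_identical(unname(cls$counts["other"]), 0L)

  # zero planted regions -> empty everywhere
  spec0 <- smallSpec(peakSim = list(contig = "chrT", genomeLength = 1e6,
                                    nShared = 0L, nFetalOnly = 0L,
                                    nAgedOnly = 0L, width = 300L,
                                    presenceProb = 1, jitter = 0L))
  sim0 <- simulatePeakSets(spec0)
  expect_true(all(vapply(sim0$samples,
                         function(s) length(peaks(s)) == 0L, TRUE)))
})

test_that("planted peak counts are recovered under realistic dropout", {
  # presence probability 0.9 over 6/6/5/5 samples with the 4-of-6 (fetal)
  # and 3-of-5 (aged) occupancy rule: a planted region survives its
  # group's consensus with P(Binom(6,.9) >= 4) ~ 0.984 / P(Binom(5,.9)
  # >= 3) ~ 0.991, so planted class counts are recovered within a few
  # percent
  spec <- smallSpec(seed = 9,
                    peakSim = list(contig = "chrT", genomeLength = 5e6,
                                   nShared = 120L, nFetalOnly = 77L,
                                   nAgedOnly = 97L, width = 400L,
                                   presenceProb = 0.9, jitter = 10L))
  sim <- simulatePeakSets(spec)
  grp <- vapply(sim$samples, function(s) s@group, "")
  cons <- lapply(c(FH = "FH", FK = "FK", AH = "AH", AK = "AK"), function(g)
    consensusPeaks(sim$samples[grp == g],
                   if (g %in% c("FH", "FK")) 4L else 3L))
  cls <- classifySharedUnique(cons$FH, cons$FK, cons$AH, cons$AK)
  expect_equal(unname(cls$counts["all_four"]), 120, tolerance = 0.08)
  expect_equal(unname(cls$counts["fetal_unique"]), 77, tolerance = 0.08)
  expect_equal(unname(cls$counts["aged_unique"]), 97, tolerance = 0.08)
})

test_that("marker expression reflects the configured Ct shift", {
  panel <- bundledPanel()
  spec <- smallSpec(markerDeltaCt = -2)
  donors <- simulateDonors(spec, panel)
  ct <- simulateMarkerExpression(spec, donors, ctSd = 0)
  med <- function(tis, g) median(ct$ct[ct$tissue == tis & ct$gene == g])
  # 2^-dCt ratio FC/FL = 2^2 = 4 for markers
  hk <- c("18S", "HPRT1", "GAPDH")
  exprFor <- function(tis) {
    target <- med(tis, "COL2A1")
    deltaCtExpression(target, vapply(hk, med, 1, tis = tis))
  }
  expect_equal(exprFor("FC") / exprFor("FL"), 4, tolerance = 1e-9)

  # zero shift -> equal medians
  spec0 <- smallSpec(markerDeltaCt = 0)
  ct0 <- simulateMarkerExpression(spec0, donors, ctSd = 0)
  expect_equal(median(ct0$ct[ct0$tissue == "FC" & ct0$gene == "COL2A1"]),
               median(ct0$ct[ct0$tissue == "FL" & ct0$gene == "COL2A1"]))

  # empty donor table -> empty output
  expect_identical(nrow(simulateMarkerExpression(spec, donors[0, ])), 0L)
})
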