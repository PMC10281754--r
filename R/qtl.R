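## qtl module: genotype-stratified methylation regression (mQTL) with
## genotypic-effect summaries, methylation-expression regression (meQTL),
## multiple-testing control

#' Genotypic effect on the percentage scale
#'
#' The genotypic effect (GE) summarizes the methylation difference, in
#' percentage points, attributable to carrying effect alleles. When both
#' homozygote classes have at least two samples it is the absolute
#' difference between their mean methylation percentages; otherwise it is
#' twice the absolute OLS slope of methylation (\%) on dosage, i.e. the
#' extrapolated two-allele effect.
#'
#' @param meanBetas numeric vector of mean betas (proportions).
#' @param dosages integer vector of effect-allele dosages (0/1/2), same
#'   length.
#' @return list with \code{ge} (percentage points, >= 0) and
#'   \code{ge_sign} (+1 if the effect allele associates with higher
#'   methylation, -1 otherwise, 0 if flat).
#' @examples
#' genotypicEffect(c(.2, .2, .35, .35, .5, .5), c(0, 0, 1, 1, 2, 2))
#' @export
genotypicEffect <- function(meanBetas, dosages) {
  .checkQtlInput(meanBetas, dosages)
  pct <- 100 * meanBetas
  n0 <- sum(dosages == 0L); n2 <- sum(dosages == 2L)
  if (n0 >= 2L && n2 >= 2L) {
    d <- mean(pct[dosages == 2L]) - mean(pct[dosages == 0L])
  } else {
    d <- 2 * unname(coef(lm(pct ~ dosages))[2L])
  }
  list(ge = abs(d), ge_sign = sign(d))
}

.checkQtlInput <- function(meanBetas, dosages) {
  if (length(meanBetas) != length(dosages))
    .stopf("meanBetas and dosages must have equal length",
           class = "devmqtl_domain_error")
  if (length(meanBetas) < 5L)
    .stopf("need >= 5 observations, got %d", length(meanBetas),
           class = "devmqtl_insufficient_data")
  if (!all(dosages %in% 0:2))
    .stopf("dosages must be 0, 1 or 2", class = "devmqtl_domain_error")
  if (length(unique(dosages)) < 2L)
    .stopf("monomorphic dosages: mQTL not estimable",
           class = "devmqtl_not_estimable")
  invisible(TRUE)
}

#' Fit a methylation QTL at one CpG
#'
#' Ordinary least squares of methylation M-values on effect-allele dosage
#' (additive coding). The p-value is the two-sided t-test on the slope;
#' the genotypic effect is computed on the percentage scale by
#' [genotypicEffect()]. Panel-level adjustment is applied by
#' [mqtlPanel()].
#'
#' @param meanBetas numeric vector of QC-passing mean betas.
#' @param dosages integer vector of dosages (0/1/2), same length, at
#'   least two distinct values.
#' @return one-row data.frame: \code{n0}, \code{n1}, \code{n2},
#'   \code{slope_m} (M-units per effect allele), \code{p}, \code{ge},
#'   \code{ge_sign}.
#' @export
fitMQTL <- function(meanBetas, dosages) {
  .checkQtlInput(meanBetas, dosages)
  fit <- lm(betaToM(meanBetas) ~ dosages)
  sm <- summary(fit)$coefficients
  geres <- genotypicEffect(meanBetas, dosages)
  data.frame(n0 = sum(dosages == 0L), n1 = sum(dosages == 1L),
             n2 = sum(dosages == 2L),
             slope_m = unname(sm["dosages", "Estimate"]),
             p = unname(sm["dosages", "Pr(>|t|)"]),
             ge = geres$ge, ge_sign = geres$ge_sign)
}

#' Fit a methylation-expression QTL
#'
#' Ordinary least squares of methylation M-values on log2 allelic
#' expression ratios from QC-passing heterozygotes. Reports slope,
#' squared Pearson correlation and the slope's two-sided p-value.
#' Bonferroni adjustment over a CpG x gene panel is applied by
#' [meqtlPanel()].
#'
#' @param mValues numeric vector of M-values.
#' @param log2Ratios numeric vector of log2 allelic ratios, same length,
#'   at least 4 pairs (sample dropout below that leaves the regression
#'   unreliable).
#' @return one-row data.frame: \code{n}, \code{slope} (M-units per
#'   log2-ratio unit), \code{r2}, \code{p}.
#' @export
fitMeQTL <- function(mValues, log2Ratios) {
  if (length(mValues) != length(log2Ratios))
    .stopf("mValues and log2Ratios must have equal length",
           class = "devmqtl_domain_error")
  keep <- is.finite(mValues) & is.finite(log2Ratios)
  mValues <- mValues[keep]; log2Ratios <- log2Ratios[keep]
  if (length(mValues) < 4L)
    .stopf("need >= 4 complete pairs for meQTL regression, got %d",
           length(mValues), class = "devmqtl_insufficient_data")
  fit <- lm(mValues ~ log2Ratios)
  sm <- summary(fit)$coefficients
  r <- cor(mValues, log2Ratios)
  data.frame(n = length(mValues),
             slope = unname(sm["log2Ratios", "Estimate"]),
             r2 = r^2,
             p = if (nrow(sm) > 1L) unname(sm["log2Ratios", "Pr(>|t|)"])
                 else NA_real_)
}

#' Adjust p-values for multiple testing
#'
#' \code{bonferroni}: \code{min(1, p * m)} with \code{m} the number of
#' tests. \code{bh}: Benjamini-Hochberg step-up with monotonicity
#' enforcement. Input order is preserved.
#'
#' @param p numeric vector of p-values in [0,1].
#' @param method \code{"bonferroni"} or \code{"bh"}.
#' @return adjusted p-values, same order and length.
#' @examples
#' adjustPvalues(c(0.01, 0.02), "bonferroni")  # 0.02 0.04
#' @export
adjustPvalues <- function(p, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    .stopf("p-values must lie in [0,1]", class = "devmqtl_domain_error")
  p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' mQTL scan over a methylation panel
#'
#' Fits [fitMQTL()] at every CpG within each tissue, pairing each donor's
#' QC-passing mean beta with the donor's dosage at the CpG's locus, and
#' applies Benjamini-Hochberg adjustment per tissue across the panel.
#' CpGs that are not estimable (monomorphic genotypes, insufficient n)
#' are reported with \code{NA} statistics and excluded from adjustment.
#'
#' @param methylation long methylation table (see
#'   [differentialMethylationPanel()]).
#' @param donors donor table with \code{donor_id} and per-locus
#'   \code{dosage.<locus>} columns.
#' @param alpha significance level on adjusted p.
#' @return data.frame keyed by (\code{tissue}, \code{locus},
#'   \code{cpg_index}) with mQTL statistics, \code{p_adj} and
#'   \code{significant}.
#' @export
mqtlPanel <- function(methylation, donors, alpha = 0.05) {
  meth <- methylation[methylation$qc_pass, ]
  out <- list()
  for (tis in unique(meth$tissue)) {
    sub <- meth[meth$tissue == tis, ]
    key <- unique(sub[, c("locus", "cpg_index")])
    key <- key[order(key$locus, key$cpg_index), , drop = FALSE]
    rows <- lapply(seq_len(nrow(key)), function(i) {
      s <- sub[sub$locus == key$locus[i] &
               sub$cpg_index == key$cpg_index[i], ]
      dos <- donors[[paste0("dosage.", key$locus[i])]][
        match(s$donor_id, donors$donor_id)]
      res <- tryCatch(fitMQTL(s$mean_beta, dos), error = function(e)
        data.frame(n0 = NA_integer_, n1 = NA_integer_, n2 = NA_integer_,
                   slope_m = NA_real_, p = NA_real_, ge = NA_real_,
                   ge_sign = NA_real_))
      cbind(data.frame(tissue = tis), key[i, , drop = FALSE], res)
    })
    block <- do.call(rbind, rows)
    block$p_adj <- NA_real_
    ok <- !is.na(block$p)
    block$p_adj[ok] <- adjustPvalues(block$p[ok], method = "bh")
    out[[tis]] <- block
  }
  res <- do.call(rbind, out)
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  rownames(res) <- NULL
  res
}

#' meQTL scan over a CpG x gene panel
#'
#' Regresses each CpG's M-values on each same-locus gene's log2 allelic
#' ratios across QC-passing heterozygous donors of one tissue, applying
#' Bonferroni adjustment per gene across its CpGs.
#'
#' @param methylation long methylation table.
#' @param aeiRecords per-record AEI table as returned by
#'   [aeiRecords()] (QC-passing rows are used).
#' @param alpha significance level on adjusted p.
#' @return data.frame keyed by (\code{tissue}, \code{gene}, \code{locus},
#'   \code{cpg_index}) with \code{n}, \code{slope}, \code{r2}, \code{p},
#'   \code{p_adj}, \code{significant}.
#' @export
meqtlPanel <- function(methylation, aeiRecords, alpha = 0.05) {
  meth <- methylation[methylation$qc_pass, ]
  aei <- aeiRecords[aeiRecords$qc_pass, ]
  out <- list()
  for (tis in unique(aei$tissue)) {
    asub <- aei[aei$tissue == tis, ]
    for (gene in unique(asub$gene)) {
      g <- asub[asub$gene == gene, ]
      loc <- g$locus[1L]
      msub <- meth[meth$tissue == tis & meth$locus == loc, ]
      cpgs <- sort(unique(msub$cpg_index))
      rows <- lapply(cpgs, function(ci) {
        m <- msub[msub$cpg_index == ci, ]
        idx <- match(g$donor_id, m$donor_id)
        res <- tryCatch(
          fitMeQTL(betaToM(m$mean_beta[idx]), g$log2_ratio),
          error = function(e)
            data.frame(n = sum(!is.na(idx)), slope = NA_real_,
                       r2 = NA_real_, p = NA_real_))
        cbind(data.frame(tissue = tis, gene = gene, locus = loc,
                         cpg_index = ci), res)
      })
      if (!length(rows)) next
      block <- do.call(rbind, rows)
      block$p_adj <- NA_real_
      ok <- !is.na(block$p)
      block$p_adj[ok] <- adjustPvalues(block$p[ok], method = "bonferroni")
      out[[paste(tis, gene)]] <- block
    }
  }
  if (!length(out))
    return(data.frame(tissue = character(0), gene = character(0),
                      locus = integer(0), cpg_index = integer(0),
                      n = integer(0), slope = numeric(0), r2 = numeric(0),
                      p = numeric(0), p_adj = numeric(0),
                      significant = logical(0)))
  res <- do.call(rbind, out)
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  rownames(res) <- NULL
  res
}
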