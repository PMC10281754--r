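## measurements module: replicate QC, beta/M transforms, differential
## methylation, 2^-dCt expression normalization

#' Replicate quality control
#'
#' A pyrosequencing measurement passes QC when its technical replicates
#' agree: the range (max - min) of the replicate percentages must not
#' exceed \code{qcThreshold}. A single replicate passes vacuously. The
#' mean is reported only on pass.
#'
#' @param values numeric vector of 1-3 replicate percentages in [0,100].
#' @param qcThreshold maximum allowed replicate range in percentage
#'   points (default 5).
#' @return list with \code{qc_pass} (logical) and \code{mean} (numeric,
#'   \code{NA} on failure).
#' @examples
#' replicateQC(c(80, 83))   # pass, mean 81.5
#' replicateQC(c(80, 86))   # fail, range 6 > 5
#' @export
replicateQC <- function(values, qcThreshold = 5) {
  if (length(values) < 1L || length(values) > 3L)
    .stopf("expected 1-3 replicate values, got %d", length(values),
           class = "devmqtl_domain_error")
  if (any(!is.finite(values)) || any(values < 0) || any(values > 100))
    .stopf("replicate values must lie in [0,100]",
           class = "devmqtl_domain_error")
  pass <- (max(values) - min(values)) <= qcThreshold
  list(qc_pass = pass, mean = if (pass) mean(values) else NA_real_)
}

#' Beta to M-value transform
#'
#' \code{M = log2(beta / (1 - beta))} with beta clamped to
#' \code{[eps, 1-eps]} so fully (un)methylated sites stay finite. The
#' M scale is closer to homoscedastic and is the regression scale used
#' throughout the package.
#'
#' @param beta methylation proportion(s) in [0,1].
#' @param eps clamp constant (default 1e-6).
#' @return M-value(s).
#' @examples
#' betaToM(c(0.5, 0.8))   # 0, 2
#' @export
betaToM <- function(beta, eps = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    .stopf("beta must lie in [0,1]", class = "devmqtl_domain_error")
  b <- .clamp(beta, eps, 1 - eps)
  log2(b / (1 - b))
}

#' M-value to beta transform
#'
#' Exact inverse of [betaToM()] away from the clamp region.
#'
#' @param m M-value(s).
#' @return methylation proportion(s).
#' @examples
#' mToBeta(2)   # 0.8
#' @export
mToBeta <- function(m) {
  1 / (1 + 2^(-m))
}

#' Differential methylation between two groups
#'
#' Tests one CpG between two tissue/age groups. The p-value comes from a
#' Welch two-sample t-test on M-values (closer to homoscedastic); the
#' effect size and its 95\% confidence interval are computed on the
#' percentage scale (difference of group means, Welch-Satterthwaite
#' degrees of freedom), matching how methylation differences are
#' conventionally reported. Panel-level multiple-testing adjustment is
#' applied by [differentialMethylationPanel()].
#'
#' @param groupA,groupB numeric vectors of QC-passing mean betas
#'   (proportions), length >= 3 each.
#' @param alpha significance level carried into the result (default
#'   0.05).
#' @return one-row data.frame: \code{mean_diff} (percentage points,
#'   A - B), \code{ci_lo}, \code{ci_hi}, \code{p}, \code{n_a},
#'   \code{n_b}.
#' @export
differentialMethylation <- function(groupA, groupB, alpha = 0.05) {
  groupA <- groupA[is.finite(groupA)]; groupB <- groupB[is.finite(groupB)]
  if (length(groupA) < 3L || length(groupB) < 3L)
    .stopf("each group needs >= 3 QC-passing values (got %d and %d)",
           length(groupA), length(groupB),
           class = "devmqtl_insufficient_data")
  tm <- t.test(betaToM(groupA), betaToM(groupB))
  tp <- t.test(100 * groupA, 100 * groupB, conf.level = 1 - alpha)
  data.frame(mean_diff = unname(diff(rev(tp$estimate))),
             ci_lo = tp$conf.int[1L], ci_hi = tp$conf.int[2L],
             p = tm$p.value, n_a = length(groupA), n_b = length(groupB))
}

#' Differential methylation across a CpG panel
#'
#' Runs [differentialMethylation()] at every CpG of a long methylation
#' table between two tissues and applies Benjamini-Hochberg adjustment
#' across the panel. CpGs with insufficient QC-passing data in either
#' group are reported with \code{NA} statistics and excluded from the
#' adjustment.
#'
#' @param methylation long table with columns \code{tissue},
#'   \code{locus}, \code{cpg_index}, \code{qc_pass}, \code{mean_beta}
#'   (as produced by [simulateMethylation()] or read from file).
#' @param tissueA,tissueB group labels to compare (A - B).
#' @param alpha significance level for the \code{significant} flag,
#'   applied to adjusted p.
#' @return data.frame, one row per CpG, with effect, CI, \code{p},
#'   \code{p_adj} and \code{significant}.
#' @export
differentialMethylationPanel <- function(methylation, tissueA, tissueB,
                                         alpha = 0.05) {
  meth <- methylation[methylation$qc_pass, ]
  key <- unique(meth[, c("locus", "cpg_index")])
  key <- key[order(key$locus, key$cpg_index), , drop = FALSE]
  rows <- lapply(seq_len(nrow(key)), function(i) {
    sub <- meth[meth$locus == key$locus[i] &
                meth$cpg_index == key$cpg_index[i], ]
    a <- sub$mean_beta[sub$tissue == tissueA]
    b <- sub$mean_beta[sub$tissue == tissueB]
    res <- tryCatch(differentialMethylation(a, b, alpha),
                    devmqtl_insufficient_data = function(e)
                      data.frame(mean_diff = NA_real_, ci_lo = NA_real_,
                                 ci_hi = NA_real_, p = NA_real_,
                                 n_a = length(a), n_b = length(b)))
    cbind(key[i, , drop = FALSE], res)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  out$p_adj[ok] <- adjustPvalues(out$p[ok], method = "bh")
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Relative expression by the 2^-dCt method
#'
#' \code{dCt = ct_target - mean(ct_housekeepers)}; relative expression is
#' \code{2^(-dCt)}, i.e. expression normalized to the housekeeping genes.
#'
#' @param ctTarget Ct of the gene of interest (cycles, finite, > 0).
#' @param ctHousekeepers numeric vector of housekeeping-gene Cts.
#' @return relative expression (numeric scalar).
#' @examples
#' deltaCtExpression(25, c(20, 20, 20))   # 2^-5 = 0.03125
#' @export
deltaCtExpression <- function(ctTarget, ctHousekeepers) {
  if (!length(ctHousekeepers))
    .stopf("housekeeper Ct list must be non-empty",
           class = "devmqtl_domain_error")
  if (any(!is.finite(c(ctTarget, ctHousekeepers))) ||
      any(c(ctTarget, ctHousekeepers) <= 0))
    .stopf("Ct values must be finite and > 0",
           class = "devmqtl_domain_error")
  2^(-(ctTarget - mean(ctHousekeepers)))
}
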