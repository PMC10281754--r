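## comethylation module: pairwise CpG correlation and hierarchical
## clustering of the panel

#' Pairwise-complete CpG correlation matrix
#'
#' Computes Pearson correlations of mean beta values between every CpG
#' pair using pairwise-complete observations, together with the number of
#' complete pairs behind each coefficient. Pairs with fewer than
#' \code{minPairs} complete observations are set to \code{NA} (flagged
#' missing, never fabricated).
#'
#' @param betaMatrix numeric matrix, donors x CpGs, possibly with
#'   \code{NA}; column names label the CpGs.
#' @param minPairs minimum complete pairs per coefficient (default 3).
#' @return a [CpGCorrelation-class].
#' @export
correlationMatrix <- function(betaMatrix, minPairs = 3L) {
  betaMatrix <- as.matrix(betaMatrix)
  if (is.null(colnames(betaMatrix)))
    colnames(betaMatrix) <- paste0("cpg", seq_len(ncol(betaMatrix)))
  r <- suppressWarnings(cor(betaMatrix, use = "pairwise.complete.obs"))
  present <- !is.na(betaMatrix)
  nPairs <- crossprod(present)
  storage.mode(nPairs) <- "integer"
  r[nPairs < minPairs] <- NA_real_
  diag(r) <- ifelse(diag(nPairs) > 0, 1, NA_real_)
  new("CpGCorrelation", labels = colnames(betaMatrix), r = r,
      nPairs = nPairs, minPairs = as.integer(minPairs))
}

#' Long methylation table to a donor x CpG beta matrix
#'
#' Pivots QC-passing mean betas into the wide matrix consumed by
#' [correlationMatrix()]; column names are \code{"<locus>.<cpg_index>"}.
#'
#' @param methylation long methylation table.
#' @param tissue optional tissue filter; default uses all samples.
#' @return numeric matrix, donors x CpGs.
#' @export
betaMatrix <- function(methylation, tissue = NULL) {
  meth <- methylation[methylation$qc_pass, ]
  if (!is.null(tissue)) meth <- meth[meth$tissue %in% tissue, ]
  lab <- sprintf("%d.%d", meth$locus, meth$cpg_index)
  labs <- unique(lab[order(meth$locus, meth$cpg_index)])
  donors <- unique(meth$donor_id)
  m <- matrix(NA_real_, length(donors), length(labs),
              dimnames = list(donors, labs))
  m[cbind(match(meth$donor_id, donors), match(lab, labs))] <- meth$mean_beta
  m
}

#' Hierarchical ordering of a CpG correlation matrix
#'
#' Agglomerative clustering on the signed distance \code{d = 1 - r}
#' (so anti-correlated CpG groups separate) with average linkage.
#' Columns are pre-sorted lexicographically by label so that equal-height
#' merges resolve deterministically. Any \code{NA} correlations must be
#' resolved (e.g. by more data) before ordering.
#'
#' @param corr a [CpGCorrelation-class].
#' @param  linkage linkage method passed to [stats::hclust()] (default
#'   \code{"average"}).
#' @return list: \code{order} (leaf order as labels), \code{merge},
#'   \code{height} (the \code{hclust} merge tree), \code{hclust} (the
#'   full object).
#' @export
hierarchicalOrder <- function(corr, linkage = "average") {
  stopifnot(is(corr, "CpGCorrelation"))
  r <- corr@r
  if (anyNA(r))
    .stopf("correlation matrix has unresolved NA entries; clustering needs a complete matrix",
           class = "devmqtl_domain_error")
  ord <- order(corr@labels)
  r <- r[ord, ord, drop = FALSE]
  d <- as.dist(1 - r)
  hc <- hclust(d, method = linkage)
  list(order = hc$labels[hc$order], merge = hc$merge,
       height = hc$height, hclust = hc)
}

#' Flat clusters from the merge tree
#'
#' Cuts the average-linkage tree at a distance threshold: CpGs are
#' co-clustered iff they merge below \code{cutHeight} on the
#' \code{d = 1 - r} scale (0 = perfectly correlated, 1 = uncorrelated,
#' 2 = perfectly anti-correlated).
#'
#' @param corr a [CpGCorrelation-class].
#' @param cutHeight cut distance in [0, 2].
#' @return named integer vector of cluster ids per CpG label.
#' @export
clusterBlocks <- function(corr, cutHeight) {
  stopifnot(is(corr, "CpGCorrelation"))
  if (cutHeight < 0 || cutHeight > 2)
    .stopf("cutHeight must lie in [0,2]", class = "devmqtl_domain_error")
  hc <- hierarchicalOrder(corr)$hclust
  cutree(hc, h = cutHeight)
}

#' Dendrogram as a nested merge list
#'
#' Serializes the merge tree to a JSON-ready nested list (leaves are
#' labels, internal nodes carry their merge height) for the report
#' bundle.
#'
#' @param hc an \code{hclust} object (e.g.
#'   \code{hierarchicalOrder(corr)$hclust}).
#' @return nested list mirroring the dendrogram.
#' @export
dendrogramJSON <- function(hc) {
  build <- function(i) {
    if (i < 0) return(hc$labels[-i])
    list(height = hc$height[i],
         left = build(hc$merge[i, 1L]),
         right = build(hc$merge[i, 2L]))
  }
  if (length(hc$height) == 0L) return(as.list(hc$labels))
  build(length(hc$height))
}

#' @describeIn CpGCorrelation-class compact console summary
#' @param object a \code{CpGCorrelation}.
#' @export
setMethod("show", "CpGCorrelation", function(object) {
  k <- length(object@labels)
  off <- object@r[upper.tri(object@r)]
  cat(sprintf("CpGCorrelation: %d CpGs, %d pairs (%d NA)\n",
              k, length(off), sum(is.na(off))))
  if (any(!is.na(off)))
    cat(sprintf("  r range: [%.3f, %.3f], median n per pair: %d\n",
                min(off, na.rm = TRUE), max(off, na.rm = TRUE),
                as.integer(median(object@nPairs[upper.tri(object@nPairs)]))))
})
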