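#' Network activity score from a gene signature
#'
#' Quantifies the activity of a regulatory program that cannot be measured
#' directly (e.g. an unannotated lncRNA absent from a hybrid-capture panel)
#' through the expression of its network genes: each signature gene is
#' z-scored across samples (sample standard deviation, n - 1), the z-scores
#' are summed per sample, and the sums are standardized again to mean 0 and
#' standard deviation 1.
#'
#' Signature genes absent from the matrix are dropped with a warning --
#' partial panel overlap is the expected case -- as are zero-variance genes.
#'
#' @param expr numeric matrix, genes in rows (named), samples in columns.
#' @param signature character vector of signature gene names.
#' @return Named numeric vector of standardized per-sample scores.
#' @examples
#' expr <- rbind(g1 = c(1, 2, 3), g2 = c(2, 4, 6))
#' colnames(expr) <- paste0("s", 1:3)
#' network_activity_score(expr, c("g1", "g2"))  # -1 0 1
#' @export
network_activity_score <- function(expr, signature) {
  expr <- as.matrix(expr)
  if (anyNA(expr)) stop("expression matrix contains missing values")
  if (ncol(expr) < 3) stop("need at least 3 samples")
  present <- intersect(signature, rownames(expr))
  absent <- setdiff(signature, rownames(expr))
  if (length(absent)) {
    warning(length(absent), " signature gene(s) absent from the matrix: ",
            paste(head(absent, 5), collapse = ", "),
            if (length(absent) > 5) ", ...")
  }
  if (length(present) == 0) stop("no signature gene present in the matrix")
  sub <- expr[present, , drop = FALSE]
  sds <- apply(sub, 1, sd)
  zero_var <- sds == 0
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance signature gene(s) dropped: ",
            paste(head(present[zero_var], 5), collapse = ", "))
    sub <- sub[!zero_var, , drop = FALSE]
  }
  if (nrow(sub) == 0) stop("all signature genes have zero variance")
  z <- t(scale(t(sub)))  # per-gene z-scores across samples
  composite <- colSums(z)
  out <- as.vector(scale(composite))
  setNames(out, colnames(expr))
}

#' Weighted-mean pathway activity
#'
#' Per-sample pathway activity as the weighted mean of gene z-scores:
#' \code{sum_g w_g z_g(sample) / sum_g |w_g|} over the gene-set members
#' present in the matrix. With unit weights this is the arithmetic mean of
#' z-scores; signed weights let repressed members pull the score down.
#'
#' @param expr numeric matrix, genes in rows (named), samples in columns.
#' @param geneset character vector of member gene names.
#' @param weights numeric vector along \code{geneset} (default unit
#'   weights).
#' @return Named numeric vector of per-sample scores.
#' @export
pathway_activity_wmean <- function(expr, geneset,
                                   weights = rep(1, length(geneset))) {
  expr <- as.matrix(expr)
  if (length(weights) != length(geneset)) {
    stop("weights must align with geneset")
  }
  keep <- geneset %in% rownames(expr)
  if (!any(keep)) stop("no gene-set member present in the matrix")
  geneset <- geneset[keep]
  weights <- weights[keep]
  if (sum(abs(weights)) == 0) stop("all weights are zero")
  sub <- expr[geneset, , drop = FALSE]
  sds <- apply(sub, 1, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) dropped from the set")
    sub <- sub[sds > 0, , drop = FALSE]
    weights <- weights[sds > 0]
    if (nrow(sub) == 0) stop("all gene-set members have zero variance")
  }
  z <- t(scale(t(sub)))
  out <- as.vector(crossprod(z, weights)) / sum(abs(weights))
  setNames(out, colnames(expr))
}
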