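# FPKM transforms, expression clustering and tissue-enrichment calls.

#' Log2 transform of an FPKM matrix
#'
#' @param mat non-negative numeric matrix (genes x samples).
#' @param pseudocount added before taking log2.
#' @return transformed matrix of the same shape.
#' @export
log_transform <- function(mat, pseudocount = 1) {
  if (any(mat < 0)) stop("FPKM values must be non-negative")
  log2(mat + pseudocount)
}

#' Hierarchical clustering of genes by expression profile
#'
#' Average-linkage agglomerative clustering on correlation distance
#' (1 - Pearson r across samples), cut to exactly `k` clusters.
#' Constant-profile genes (zero variance, for which correlation is
#' undefined) are assigned afterwards to the cluster with the nearest
#' Euclidean centroid. Rows are ordered by gene id before clustering, so
#' the assignment is invariant to the input row order; ties in the
#' centroid fallback go to the lowest cluster label.
#'
#' @param mat numeric matrix (genes x samples), typically log-transformed.
#' @param k number of clusters (>= 2).
#' @param distance `"correlation"` (default) or `"euclidean"`.
#' @return list: `assignment` (named integer vector in 1..k) and `hclust`
#'   (the dendrogram over non-constant genes).
#' @export
hierarchical_cluster_genes <- function(mat, k = 10L,
                                       distance = c("correlation",
                                                    "euclidean")) {
  distance <- match.arg(distance)
  if (k < 2L) stop("k must be at least 2")
  stopifnot(!is.null(rownames(mat)))
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  constant <- apply(mat, 1L, function(x) sd(x) == 0 || !is.finite(sd(x)))
  core <- mat[!constant, , drop = FALSE]
  if (nrow(core) < k)
    stop(sprintf("need at least k = %d genes with non-constant profiles",
                 k))
  d <- if (distance == "correlation") as.dist(1 - cor(t(core)))
       else stats::dist(core)
  hc <- hclust(d, method = "average")
  assignment <- cutree(hc, k = k)
  if (any(constant)) {
    centroids <- t(vapply(seq_len(k), function(cl) {
      colMeans(core[assignment == cl, , drop = FALSE])
    }, numeric(ncol(core))))
    extra <- vapply(rownames(mat)[constant], function(g) {
      dist2 <- rowSums((centroids - matrix(mat[g, ], k, ncol(mat),
                                           byrow = TRUE))^2)
      which.min(dist2)  # ties -> lowest cluster label
    }, integer(1))
    assignment <- c(assignment, extra)
  }
  list(assignment = assignment[order(names(assignment))], hclust = hc)
}

per_tissue_means <- function(mat, sample_map) {
  stopifnot(all(colnames(mat) %in% sample_map$sample))
  tissues <- unique(sample_map$tissue)
  out <- vapply(tissues, function(tt) {
    cols <- sample_map$sample[sample_map$tissue == tt]
    rowMeans(mat[, colnames(mat) %in% cols, drop = FALSE])
  }, numeric(nrow(mat)))
  if (nrow(mat) == 1L) out <- matrix(out, nrow = 1L,
                                     dimnames = list(rownames(mat),
                                                     tissues))
  out
}

#' Call tissue-enriched (and silent) genes
#'
#' A gene is `anther_enriched` (for the default tissue) when its mean FPKM
#' over the tissue's samples is at least `min_fpkm` and at least `fold`
#' times the largest mean of any other tissue. Genes below `max_fpkm` in
#' every sample are `not_expressed`; everything else is `other`. The three
#' statuses are mutually exclusive, with `not_expressed` taking precedence.
#'
#' @param mat raw FPKM matrix (genes x samples).
#' @param sample_map data frame with columns `sample`, `tissue` (and
#'   optionally `stage`).
#' @param tissue focal tissue; must appear in the map.
#' @param min_fpkm minimum focal-tissue mean.
#' @param fold minimum ratio over the best other tissue.
#' @param max_fpkm per-sample ceiling below which a gene counts as not
#'   expressed.
#' @return data frame: gene, status, tissue_mean, max_other_mean,
#'   fold_change.
#' @export
call_tissue_enriched <- function(mat, sample_map, tissue = "anther",
                                 min_fpkm = 2, fold = 4, max_fpkm = 0.5) {
  if (!(tissue %in% sample_map$tissue))
    stop(sprintf("tissue '%s' not present in the sample map", tissue))
  means <- per_tissue_means(mat, sample_map)
  tmean <- means[, tissue]
  others <- means[, setdiff(colnames(means), tissue), drop = FALSE]
  max_other <- apply(others, 1L, max)
  silent <- apply(mat, 1L, function(x) all(x < max_fpkm))
  enriched <- !silent & tmean >= min_fpkm & tmean >= fold * max_other
  data.frame(
    gene = rownames(mat),
    status = ifelse(silent, "not_expressed",
                    ifelse(enriched, "anther_enriched", "other")),
    tissue_mean = unname(tmean),
    max_other_mean = unname(max_other),
    fold_change = unname(ifelse(max_other > 0, tmean / max_other, Inf)),
    stringsAsFactors = FALSE)
}

#' Genes with no detectable expression
#'
#' @param mat raw FPKM matrix.
#' @param max_fpkm threshold: every sample must be strictly below it.
#' @return character vector of gene ids.
#' @export
call_not_expressed <- function(mat, max_fpkm = 0.5) {
  rownames(mat)[apply(mat, 1L, function(x) all(x < max_fpkm))]
}
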