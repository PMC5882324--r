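#' Variance-stabilizing transformation for NB counts
#'
#' Closed-form VST under the dispersion trend `alpha(mu) = a0 + a1/mu`:
#' with `q` the size-factor-normalized count,
#' `vst(q) = log2( (1 + a1 + 2*a0*q + 2*sqrt(a0*q*(1 + a1 + a0*q))) / (4*a0) )`.
#' The transform is strictly increasing in `q` and parallels `log2(q)` for
#' large `q`, while flattening the variance of low and mid counts. With
#' `a0 = 0` (no asymptotic overdispersion) it falls back to `log2(q + 1)`,
#' with a message.
#'
#' @param counts a `count_matrix` or integer matrix.
#' @param sf size factors (computed when `NULL`).
#' @param dispersion a `dispersion_model`, or numeric `c(a0, a1)`.
#' @return numeric matrix (genes x samples) with attributes `a0`, `a1`.
#' @export
vst_transform <- function(counts, sf = NULL, dispersion = NULL) {
  k <- counts_matrix_of(counts)
  sf <- sf %ifnull% size_factors(k)
  if (is.null(dispersion)) {
    cond <- if (inherits(counts, "count_matrix")) counts$samples$condition
            else rep("all", ncol(k))
    dispersion <- estimate_dispersions(k, sf = sf, condition = cond)
  }
  if (inherits(dispersion, "dispersion_model")) {
    a0 <- dispersion$a0; a1 <- dispersion$a1
  } else {
    a0 <- dispersion[1]; a1 <- dispersion[2] %||% 0
  }
  if (a1 < 0 || a0 < 0) abort("trend parameters must satisfy a0 >= 0, a1 >= 0.")
  q <- sweep(k, 2, sf, "/")
  if (a0 == 0) {
    inform("a0 = 0: falling back to log2(q + 1).")
    out <- log2(q + 1)
  } else {
    out <- log2((1 + a1 + 2 * a0 * q +
                   2 * sqrt(a0 * q * (1 + a1 + a0 * q))) / (4 * a0))
  }
  attr(out, "a0") <- a0
  attr(out, "a1") <- a1
  out
}

#' Top expressed genes
#'
#' The `n` genes with the highest mean transformed expression across the
#' selected samples (the conventional input to sample-level PCA, e.g. "the
#' 1,000 most expressed genes"). Ties break deterministically by gene id;
#' selection is invariant to sample order.
#'
#' @param mat transformed matrix (genes x samples).
#' @param n number of genes; when `n` exceeds the gene count all genes are
#'   returned with a warning.
#' @return character vector of gene ids, in decreasing mean order.
#' @export
top_expressed <- function(mat, n = 1000) {
  if (n > nrow(mat)) {
    warn(sprintf("n = %d exceeds the %d genes available; taking all.",
                 n, nrow(mat)))
    n <- nrow(mat)
  }
  m <- rowMeans(mat)
  ord <- order(-m, rownames(mat))
  rownames(mat)[ord][seq_len(n)]
}

#' Principal component analysis of samples
#'
#' Genes are centered (no unit-variance scaling); the centered matrix is
#' decomposed by SVD and sample scores are returned with the fraction of
#' variance explained per component. A constant matrix yields all-zero
#' scores.
#'
#' @param mat transformed matrix (genes x samples), typically restricted to
#'   [top_expressed()] genes.
#' @param n_pc number of components to return.
#' @return a `sample_pca`: list with `scores` (tibble `sample`, `PC1`, ...)
#'   and `var_explained`.
#' @export
pca_samples <- function(mat, n_pc = min(4L, ncol(mat) - 1L)) {
  if (ncol(mat) < 2) abort("need >= 2 samples.")
  x <- t(mat - rowMeans(mat))        # samples x genes, gene-centered
  sv <- svd(x)
  d2 <- sv$d^2
  total <- sum(d2)
  n_pc <- max(1L, min(n_pc, length(sv$d)))
  scores <- sv$u[, seq_len(n_pc), drop = FALSE] %*%
    diag(sv$d[seq_len(n_pc)], n_pc)
  colnames(scores) <- paste0("PC", seq_len(n_pc))
  ve <- if (total > 0) d2[seq_len(n_pc)] / total else rep(0, n_pc)
  if (total == 0) scores[] <- 0
  structure(
    list(scores = bind_cols(tibble(sample = colnames(mat)),
                            as_tibble(scores)),
         var_explained = setNames(ve, paste0("PC", seq_len(n_pc)))),
    class = "sample_pca")
}

#' @export
print.sample_pca <- function(x, ...) {
  cat(sprintf("<sample_pca> %d samples; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), 100 * x$var_explained[1],
              100 * (x$var_explained[2] %||% 0)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sample_pca <- function(x, ...) x$scores

#' @exportS3Method generics::glance
glance.sample_pca <- function(x, ...) {
  as_tibble(as.list(x$var_explained))
}

#' Hierarchical clustering order of samples or genes
#'
#' Agglomerative clustering with Euclidean distance and complete linkage
#' (the heatmap convention). Merge heights are nondecreasing; base R's
#' agglomeration resolves ties deterministically for a fixed input order.
#'
#' @param mat transformed matrix (genes x samples).
#' @param items cluster `"samples"` (columns) or `"genes"` (rows).
#' @return list with `hclust` (the [stats::hclust] tree) and `order`
#'   (leaf labels in dendrogram order).
#' @export
hclust_order <- function(mat, items = c("samples", "genes")) {
  items <- match.arg(items)
  x <- if (items == "samples") t(mat) else mat
  if (nrow(x) < 2) abort("need >= 2 items to cluster.")
  hc <- hclust(dist(x, method = "euclidean"), method = "complete")
  list(hclust = hc, order = rownames(x)[hc$order])
}
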