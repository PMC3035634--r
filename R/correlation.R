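#' Remove group means from each gene
#'
#' Subtracts, per gene, the group-specific (case / control) mean, leaving
#' residuals in which true group separation cannot masquerade as gene-gene
#' correlation. This is the preprocessing step for the within-set correlation
#' estimate feeding [gene_correlation_eigen()].
#'
#' @param x Numeric matrix, genes x samples (typically a gene set submatrix).
#' @param metadata Metadata data frame aligned to `colnames(x)` (see
#'   [validate_metadata()]).
#' @return Matrix of the same dimensions with zero group means per gene.
#' @export
center_by_group <- function(x, metadata) {
  metadata <- validate_metadata(metadata, samples = colnames(x))
  out <- x
  for (g in unique(metadata$group)) {
    idx <- which(metadata$group == g)
    if (length(idx) < 2L) {
      stop(sprintf("group '%s' has fewer than 2 samples", g), call. = FALSE)
    }
    out[, idx] <- x[, idx, drop = FALSE] - rowMeans(x[, idx, drop = FALSE])
  }
  out
}

#' Eigendecomposition of the within-set gene-gene correlation matrix
#'
#' Computes the Pearson correlation matrix of the gene rows of `residuals`
#' and returns its leading eigenpairs. The returned loadings are the
#' orthonormal per-gene designs of the factor-analytic random effects in the
#' set-level mixed model: component k contributes a per-sample random
#' coefficient whose gene loading is the k-th eigenvector.
#'
#' @param residuals Numeric matrix, genes x samples, usually group-mean
#'   centered (see [center_by_group()]). Every row must have nonzero
#'   variance.
#' @param K_max Maximum number of components to return; the result keeps
#'   `K = min(K_max, rank)` components.
#' @return A list of class `eigen_basis` with elements `loadings`
#'   (genes x K, orthonormal columns), `eigenvalues` (length K,
#'   non-increasing), `all_eigenvalues` (full spectrum, clipped at zero),
#'   `rank`, and `trace` (= number of genes).
#' @export
gene_correlation_eigen <- function(residuals, K_max) {
  if (!is.matrix(residuals) || nrow(residuals) < 2L) {
    stop("need a matrix with at least 2 gene rows", call. = FALSE)
  }
  if (K_max < 1L) stop("K_max must be >= 1", call. = FALSE)
  v <- apply(residuals, 1L, stats::var)
  if (any(v <= 0)) {
    nm <- rownames(residuals)
    if (is.null(nm)) nm <- as.character(seq_len(nrow(residuals)))
    stop("zero-variance gene row(s): ",
         paste(nm[v <= 0], collapse = ", "), call. = FALSE)
  }
  C <- stats::cor(t(residuals))
  ev <- eigen(C, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  G <- nrow(C)
  rank <- sum(vals > G * max(vals, 1) * 1e-12)
  K <- min(as.integer(K_max), rank)
  structure(list(
    loadings = ev$vectors[, seq_len(K), drop = FALSE],
    eigenvalues = vals[seq_len(K)],
    all_eigenvalues = vals,
    rank = rank,
    trace = G
  ), class = "eigen_basis")
}

#' @export
print.eigen_basis <- function(x, ...) {
  cat(sprintf("eigen_basis: %d gene(s), %d component(s), rank %d\n",
              nrow(x$loadings), ncol(x$loadings), x$rank))
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  invisible(x)
}
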