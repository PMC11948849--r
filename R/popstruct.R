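#' Genetic covariance matrix
#'
#' Genotypes are centered by twice the sample allele frequency and scaled
#' by \code{sqrt(2 p (1 - p))} per site; missing calls are set to zero
#' after centering (their imputed value is the site mean, which is
#' unbiased under missingness at random). The covariance is the
#' cross-product divided by the number of sites.
#'
#' @param geno a filtered \code{\link{genotype_table}} with no
#'   monomorphic sites.
#' @return symmetric individuals x individuals matrix.
#' @export
genetic_covariance <- function(geno) {
  p <- allele_freq(geno)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("monomorphic site(s) present; apply a MAF filter first")
  }
  x <- geno$calls
  storage.mode(x) <- "double"
  z <- sweep(x, 2L, 2 * p, "-")
  z <- sweep(z, 2L, sqrt(2 * p * (1 - p)), "/")
  z[is.na(z)] <- 0
  tcrossprod(z) / length(p)
}

#' PCA of a genetic covariance matrix
#'
#' Eigendecomposition of the covariance; scores are eigenvectors scaled by
#' the square root of their eigenvalues, and the explained percentage is
#' each eigenvalue over the trace. For a deterministic output each
#' component is oriented so its largest-magnitude loading is positive.
#'
#' @param cov symmetric covariance matrix (from
#'   \code{\link{genetic_covariance}}).
#' @param n_components number of components to return (default all).
#' @return An object of class \code{pca_result}: \code{scores},
#'   \code{eigenvalues} (descending), \code{explained_pct},
#'   \code{loadings}.
#' @export
pca_genotypes <- function(cov, n_components = NULL) {
  if (!is.matrix(cov) || nrow(cov) != ncol(cov) ||
      max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov)))) {
    stop("cov must be a symmetric matrix")
  }
  e <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
  vals <- e$values
  vecs <- e$vectors
  for (j in seq_len(ncol(vecs))) {
    k <- which.max(abs(vecs[, j]))
    if (vecs[k, j] < 0) vecs[, j] <- -vecs[, j]
  }
  if (is.null(n_components)) n_components <- length(vals)
  n_components <- min(n_components, length(vals))
  scores <- vecs %*% diag(sqrt(pmax(vals, 0)), length(vals))
  rownames(scores) <- rownames(cov)
  colnames(scores) <- sprintf("PC%d", seq_along(vals))
  structure(
    list(scores = scores[, seq_len(n_components), drop = FALSE],
         eigenvalues = vals,
         explained_pct = vals / sum(vals) * 100,
         loadings = vecs[, seq_len(n_components), drop = FALSE]),
    class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(5L, length(x$explained_pct))
  cat("PCA on genetic covariance:", nrow(x$scores), "individuals\n")
  cat("  explained % (first", k, "PCs):",
      paste(sprintf("%.2f", x$explained_pct[seq_len(k)]), collapse = ", "),
      "\n")
  invisible(x)
}
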