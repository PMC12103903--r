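## Expression pre-processing: conditional log2, sparse-gene filter,
## size-factor normalization, highly variable gene selection.

#' Conditionally log2-transform an expression matrix
#'
#' If the value range (max - min) exceeds \code{threshold}, returns
#' \code{log2(x + 1)}; otherwise the matrix is returned unchanged.
#'
#' @param x Nonnegative genes x cells matrix.
#' @param threshold Range above which the log transform is applied
#'   (default 100).
#' @return The (possibly transformed) matrix, with attribute
#'   \code{"appliedLog"} set to TRUE/FALSE.
#' @examples
#' m <- matrix(c(0, 1023), 1, 2, dimnames = list("G1", c("c1", "c2")))
#' conditionalLog2(m)  # range > 100, so log2(x + 1)
#' @export
conditionalLog2 <- function(x, threshold = 100) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (any(x < 0)) stop("expression values must be nonnegative")
  applied <- length(x) > 0 && (max(x) - min(x)) > threshold
  out <- if (applied) log2(x + 1) else x
  attr(out, "appliedLog") <- applied
  out
}

#' Remove genes expressed in too few cells
#'
#' A gene is removed when its fraction of zero-valued cells is strictly
#' greater than \code{maxZeroFrac} (default 0.95: zero in more than 95\% of
#' cells). A gene zero in exactly 95\% of cells is kept.
#'
#' @param x Genes x cells matrix with dimnames.
#' @param maxZeroFrac Maximum tolerated zero fraction, in (0, 1].
#' @return List with \code{matrix} (filtered genes x cells) and
#'   \code{removed} (integer indices of dropped genes in the input order).
#' @export
filterSparseGenes <- function(x, maxZeroFrac = 0.95) {
  stopifnot(is.matrix(x), maxZeroFrac > 0, maxZeroFrac <= 1)
  zeroFrac <- rowMeans(x == 0)
  removed <- which(unname(zeroFrac > maxZeroFrac))
  if (length(removed) == nrow(x))
    stop("all ", nrow(x), " genes exceed the zero-fraction threshold of ",
         maxZeroFrac)
  kept <- if (length(removed)) x[-removed, , drop = FALSE] else x
  list(matrix = kept, removed = removed)
}

#' Normalize cells by median-scaled size factors
#'
#' The library size s_i of cell i is its column sum; the size factor is
#' s_i / s_m with s_m the median library size, and column i is divided by
#' its factor. After normalization every cell's library size equals the
#' median of the original sizes.
#'
#' @param x Genes x cells matrix (typically after the conditional log
#'   step, so library sizes are totals of the log-scale values).
#' @return List with \code{matrix} (normalized) and \code{sizeFactors}
#'   (per-cell positive scalars).
#' @examples
#' m <- matrix(c(100, 200, 300), 1, 3,
#'             dimnames = list("G1", paste0("c", 1:3)))
#' sizeFactorNormalize(m)$sizeFactors  # 0.5 1.0 1.5
#' @export
sizeFactorNormalize <- function(x) {
  stopifnot(is.matrix(x))
  libSize <- colSums(x)
  zero <- which(libSize <= 0)
  if (length(zero))
    stop("cell(s) with zero library size: ",
         paste(colnames(x)[zero], collapse = ", "))
  sm <- stats::median(libSize)
  sf <- libSize / sm
  list(matrix = sweep(x, 2L, sf, "/"), sizeFactors = sf)
}

#' Select highly variable genes
#'
#' Genes are ranked by a variability score of the normalized expression
#' values, descending; the top \code{nTop} are retained in their original
#' matrix order. Ties are broken by ascending gene index.
#'
#' @param x Normalized genes x cells matrix.
#' @param nTop Number of genes to keep (default 2000); if the matrix has
#'   fewer genes, all are kept.
#' @param method Variability score: \code{"variance"} (default) or
#'   \code{"dispersion"} (variance / mean, with zero-mean genes scored 0).
#' @return List with \code{matrix} (subset, original gene order) and
#'   \code{indices} (the retained gene indices, ascending).
#' @export
selectHVG <- function(x, nTop = 2000, method = c("variance", "dispersion")) {
  method <- match.arg(method)
  stopifnot(is.matrix(x), nTop >= 1)
  v <- apply(x, 1L, stats::var)
  score <- if (method == "variance") v else {
    mu <- rowMeans(x)
    ifelse(mu > 0, v / mu, 0)
  }
  nKeep <- min(nTop, nrow(x))
  ranked <- order(-score, seq_along(score))[seq_len(nKeep)]
  indices <- sort(ranked)
  list(matrix = x[indices, , drop = FALSE], indices = indices)
}

#' Run the full pre-processing pipeline
#'
#' Applies, in order: conditional log2 transform, sparse-gene filtering,
#' size-factor normalization and highly variable gene selection. The
#' result is View 1 of the multi-view construction.
#'
#' @param x Raw genes x cells expression matrix with dimnames.
#' @param maxZeroFrac Zero-fraction threshold for gene filtering
#'   (default 0.95).
#' @param nHVG Number of highly variable genes to keep (default 2000).
#' @param logRangeThreshold Range threshold for the conditional log
#'   (default 100).
#' @param hvgMethod Variability score for [selectHVG()].
#' @return List with \code{matrix} (the HVG-filtered normalized matrix),
#'   \code{normalized} (the full normalized matrix before HVG selection,
#'   used for pathway scoring so gene-set coverage is preserved), and
#'   \code{report}: \code{appliedLog}, \code{genesRemovedSparse},
#'   \code{sizeFactors}, \code{hvgIndices} (indices into the
#'   sparse-filtered matrix).
#' @export
preprocessPipeline <- function(x, maxZeroFrac = 0.95, nHVG = 2000,
                               logRangeThreshold = 100,
                               hvgMethod = c("variance", "dispersion")) {
  hvgMethod <- match.arg(hvgMethod)
  validateExpression(x)
  logged <- conditionalLog2(x, threshold = logRangeThreshold)
  appliedLog <- attr(logged, "appliedLog")
  filt <- filterSparseGenes(logged, maxZeroFrac = maxZeroFrac)
  norm <- sizeFactorNormalize(filt$matrix)
  hvg <- selectHVG(norm$matrix, nTop = nHVG, method = hvgMethod)
  list(matrix = hvg$matrix,
       normalized = norm$matrix,
       report = list(appliedLog = appliedLog,
                     genesRemovedSparse = length(filt$removed),
                     removedIndices = filt$removed,
                     sizeFactors = norm$sizeFactors,
                     hvgIndices = hvg$indices))
}
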