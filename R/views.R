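## Multi-view construction: intrinsic dimensionality, PCA features,
## diffusion-map features, AUCell-style pathway activity scores.

# Deterministic sign convention for spectral embeddings: for each column,
# the entry of largest magnitude is made positive.
fixSigns <- function(m) {
  for (j in seq_len(ncol(m))) {
    i <- which.max(abs(m[, j]))
    if (m[i, j] < 0) m[, j] <- -m[, j]
  }
  m
}

#' Maximum-likelihood intrinsic dimension estimate
#'
#' Levina-Bickel estimator: for each point x and neighborhood size k,
#' \deqn{\hat m_k(x) = \left[\frac{1}{k-1}\sum_{j=1}^{k-1}
#'   \log\frac{T_k(x)}{T_j(x)}\right]^{-1}}
#' with T_j(x) the Euclidean distance from x to its j-th nearest
#' neighbor. The estimate is averaged over all points and over k in
#' \code{[kMin, kMax]}, then rounded to the nearest positive integer and
#' clipped to \code{[1, min(d, n - 1)]}.
#'
#' @param x Features x cells matrix (cells are the points).
#' @param kMin,kMax Neighborhood size range (defaults 6 and 12).
#' @return Integer dimension estimate.
#' @export
estimateIntrinsicDim <- function(x, kMin = 6, kMax = 12) {
  stopifnot(is.matrix(x), kMin >= 2, kMax >= kMin)
  n <- ncol(x)
  if (n < kMax + 1)
    stop("need at least kMax + 1 = ", kMax + 1, " points, got ", n)
  d2 <- pairwiseSqDist(t(x))
  eps <- sqrt(.Machine$double.eps)
  estimates <- numeric(0L)
  sawDuplicates <- FALSE
  for (i in seq_len(n)) {
    di <- sqrt(sort(d2[i, -i]))[seq_len(kMax)]
    if (any(di < eps)) {
      sawDuplicates <- TRUE
      di <- pmax(di, eps)
    }
    logT <- log(di)
    mk <- vapply(kMin:kMax, function(k) {
      (k - 1) / sum(logT[k] - logT[seq_len(k - 1L)])
    }, numeric(1L))
    estimates <- c(estimates, mean(mk))
  }
  if (sawDuplicates)
    warning("duplicate or near-duplicate points; ",
            "flooring neighbor distances at machine epsilon scale")
  est <- round(mean(estimates))
  max(1L, min(as.integer(est), nrow(x), n - 1L))
}

#' PCA feature view
#'
#' Centers each gene (row) and projects cells onto the top-d principal
#' axes via singular value decomposition. A deterministic sign convention
#' makes the largest-magnitude loading of each axis positive.
#'
#' @param x Genes x cells matrix.
#' @param d Number of components; truncated (with a warning) if it
#'   exceeds the rank of the centered matrix.
#' @return d x n matrix of principal-component coordinates.
#' @export
pcaView <- function(x, d) {
  stopifnot(is.matrix(x), d >= 1, d <= min(dim(x)))
  xc <- x - rowMeans(x)
  sv <- svd(xc)
  tol <- max(dim(xc)) * .Machine$double.eps * max(sv$d, 0)
  rank <- sum(sv$d > tol)
  if (d > rank) {
    warning("requested ", d, " components but rank is ", rank,
            "; truncating")
    d <- max(rank, 1L)
  }
  u <- fixSigns(sv$u[, seq_len(d), drop = FALSE])
  scores <- t(u) %*% xc
  rownames(scores) <- paste0("PC", seq_len(d))
  colnames(scores) <- colnames(x)
  scores
}

#' Diffusion-map feature view
#'
#' Builds a Gaussian kernel K_ij = exp(-||x_i - x_j||^2 / (2 sigma^2)),
#' normalizes it to a Markov transition matrix P = D^-1 K, and embeds
#' cells with the top-d nontrivial right eigenvectors of P scaled by
#' their eigenvalues to the power t (the constant eigenvector of
#' eigenvalue 1 is skipped).
#'
#' @param x Genes x cells matrix.
#' @param d Number of diffusion coordinates (d <= n - 1).
#' @param sigma Kernel bandwidth; \code{"auto"} (default) uses the median
#'   pairwise Euclidean distance.
#' @param t Diffusion time (default 1).
#' @return d x n matrix of diffusion coordinates.
#' @export
diffusionMapView <- function(x, d, sigma = "auto", t = 1) {
  stopifnot(is.matrix(x), d >= 1, t >= 1)
  n <- ncol(x)
  if (d > n - 1) stop("d must be at most n - 1")
  d2 <- pairwiseSqDist(t(x))
  if (identical(sigma, "auto")) {
    sigma <- stats::median(sqrt(d2[upper.tri(d2)]))
    if (!is.finite(sigma) || sigma <= 0)
      stop("degenerate kernel: all cells coincide")
  }
  stopifnot(is.numeric(sigma), sigma > 0)
  K <- exp(-d2 / (2 * sigma^2))
  if (n > 1 && max(K[upper.tri(K)]) < 1e-300)
    stop("degenerate kernel: off-diagonal similarities underflow to zero; ",
         "increase sigma")
  deg <- rowSums(K)
  # P = D^-1 K shares eigenvalues with the symmetric D^-1/2 K D^-1/2
  dInvSqrt <- 1 / sqrt(deg)
  A <- K * tcrossprod(dInvSqrt)
  eig <- eigen(A, symmetric = TRUE)
  # right eigenvectors of P; first (constant, eigenvalue 1) is skipped
  psi <- dInvSqrt * eig$vectors
  idx <- 1L + seq_len(d)
  coords <- t(fixSigns(psi[, idx, drop = FALSE])) *
    (eig$values[idx] ^ t)
  rownames(coords) <- paste0("DC", seq_len(d))
  colnames(coords) <- colnames(x)
  coords
}

#' AUCell-style gene-set activity scores
#'
#' For each cell, genes are ranked by expression, descending, with ties
#' broken by the original gene order. The recovery curve of a gene set is
#' the cumulative count of its members among the top ranks; the score is
#' the area under this curve over ranks 1..ceil(topFrac * G), normalized
#' by the maximum achievable area, so scores lie in [0, 1]. Genes of a
#' set absent from the matrix are ignored; a set with no overlap at all
#' scores 0 in every cell, with a warning.
#'
#' @param x Genes x cells matrix (raw or normalized; rows named by gene).
#' @param geneSets A [PathwayCollection-class].
#' @param topFrac Fraction of top-ranked genes over which the recovery
#'   curve is integrated (default 0.05).
#' @return nSets x nCells matrix of activity scores in [0, 1].
#' @export
aucellView <- function(x, geneSets, topFrac = 0.05) {
  stopifnot(is.matrix(x), is(geneSets, "PathwayCollection"),
            topFrac > 0, topFrac < 1)
  sets <- geneSets(geneSets)
  G <- nrow(x)
  n <- ncol(x)
  L <- ceiling(topFrac * G)
  memberIdx <- lapply(sets, function(g) which(rownames(x) %in% g))
  empty <- which(lengths(memberIdx) == 0L)
  if (length(empty))
    warning("gene set(s) with no genes in the matrix score 0: ",
            paste(names(sets)[empty], collapse = ", "))
  scores <- matrix(0, length(sets), n,
                   dimnames = list(names(sets), colnames(x)))
  member <- matrix(FALSE, G, length(sets))
  for (s in seq_along(sets)) member[memberIdx[[s]], s] <- TRUE
  for (j in seq_len(n)) {
    ord <- order(-x[, j], seq_len(G))[seq_len(L)]
    inTop <- member[ord, , drop = FALSE]      # L x nSets indicator
    # area under the recovery step curve = sum over ranks of cum. counts
    cum <- apply(inTop, 2L, cumsum)
    if (L == 1L) cum <- matrix(cum, 1L)
    auc <- colSums(cum)
    M <- pmin(lengths(memberIdx), L)
    maxAuc <- vapply(M, function(m) {
      if (m == 0L) return(1)  # avoid 0/0; score stays 0
      sum(pmin(seq_len(L), m))
    }, numeric(1L))
    scores[, j] <- auc / maxAuc
  }
  scores
}

#' Assemble the multi-view representation of an expression matrix
#'
#' Builds up to four views over the same cells, in the fixed order
#' expression, pathway, pca, dm:
#' \enumerate{
#'   \item \strong{expression} - the pre-processed (HVG-filtered,
#'     normalized) matrix;
#'   \item \strong{pathway} - AUCell activity scores computed on the
#'     normalized matrix before HVG filtering (so gene-set coverage is
#'     preserved), or on raw counts if \code{pathwayOnRaw = TRUE};
#'   \item \strong{pca} - principal-component coordinates of the
#'     pre-processed matrix;
#'   \item \strong{dm} - diffusion-map coordinates of the pre-processed
#'     matrix.
#' }
#' The PCA/diffusion dimensionality defaults to the maximum-likelihood
#' intrinsic dimension estimate of the pre-processed data.
#'
#' @param preprocessed Output of [preprocessPipeline()] (or a genes x
#'   cells matrix, in which case the pipeline is run first).
#' @param geneSets A [PathwayCollection-class]; required when the pathway
#'   view is included.
#' @param include Character subset of
#'   \code{c("expression", "pathway", "pca", "dm")} (default all four).
#'   Dropping one view reproduces the ablation variants (e.g. omitting
#'   "pathway" gives the no-pathway variant).
#' @param pcaDim,dmDim Dimensionality overrides for the PCA / diffusion
#'   views (\code{NULL} = intrinsic-dimension estimate).
#' @param dmSigma,dmT Diffusion kernel bandwidth and diffusion time
#'   (see [diffusionMapView()]).
#' @param aucellTopFrac Top-rank fraction for [aucellView()].
#' @param idKmin,idKmax Neighborhood range for [estimateIntrinsicDim()].
#' @param pathwayOnRaw Score pathways on the raw matrix instead of the
#'   normalized one.
#' @param raw Raw matrix (only needed with \code{pathwayOnRaw = TRUE}
#'   when \code{preprocessed} is already a pipeline result).
#' @return A [ViewSet-class].
#' @export
buildViews <- function(preprocessed, geneSets = NULL,
                       include = c("expression", "pathway", "pca", "dm"),
                       pcaDim = NULL, dmDim = NULL, dmSigma = "auto",
                       dmT = 1, aucellTopFrac = 0.05,
                       idKmin = 6, idKmax = 12,
                       pathwayOnRaw = FALSE, raw = NULL) {
  include <- match.arg(include,
                       c("expression", "pathway", "pca", "dm"),
                       several.ok = TRUE)
  if (!length(include)) stop("at least one view must be included")
  if (is.matrix(preprocessed)) {
    raw <- preprocessed
    preprocessed <- preprocessPipeline(preprocessed)
  }
  xPre <- preprocessed$matrix
  views <- list()
  if ("expression" %in% include)
    views$expression <- xPre
  if ("pathway" %in% include) {
    if (is.null(geneSets))
      stop("the pathway view requires a gene-set collection")
    xScore <- if (pathwayOnRaw) {
      if (is.null(raw)) stop("pathwayOnRaw = TRUE requires the raw matrix")
      raw
    } else preprocessed$normalized
    views$pathway <- aucellView(xScore, geneSets, topFrac = aucellTopFrac)
  }
  needDim <- is.null(pcaDim) && "pca" %in% include ||
    is.null(dmDim) && "dm" %in% include
  if (needDim)
    dHat <- estimateIntrinsicDim(xPre, kMin = idKmin, kMax = idKmax)
  if ("pca" %in% include) {
    d <- if (is.null(pcaDim)) dHat else pcaDim
    views$pca <- pcaView(xPre, min(d, min(dim(xPre))))
  }
  if ("dm" %in% include) {
    d <- if (is.null(dmDim)) dHat else dmDim
    views$dm <- diffusionMapView(xPre, min(d, ncol(xPre) - 1L),
                                 sigma = dmSigma, t = dmT)
  }
  # fixed view order; cells aligned by id across views
  order <- intersect(c("expression", "pathway", "pca", "dm"), names(views))
  views <- views[order]
  ids <- colnames(views[[1L]])
  for (nm in names(views))
    if (!identical(colnames(views[[nm]]), ids))
      stop("cell order mismatch between views ('", nm, "')")
  ViewSet(views, cellIds = ids)
}
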