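#' Cluster an expression matrix end to end
#'
#' Convenience wrapper running the full pipeline: pre-processing
#' ([preprocessPipeline()]), multi-view construction ([buildViews()]) and
#' the graph fusion clustering ([runSCMCGF()]).
#'
#' @param x Raw genes x cells expression matrix with dimnames.
#' @param c Target number of clusters.
#' @param geneSets A [PathwayCollection-class]; required when the pathway
#'   view is among \code{include}.
#' @param include Views to build, subset of
#'   \code{c("expression", "pathway", "pca", "dm")}.
#' @param k Neighbor count or \code{"auto"}.
#' @param nHVG,maxZeroFrac,logRangeThreshold,hvgMethod Pre-processing
#'   parameters, see [preprocessPipeline()].
#' @param maxIter,seed Optimization parameters, see [runSCMCGF()].
#' @param ... Further arguments passed to [buildViews()].
#' @return A [SCMCGFFit-class].
#' @examples
#' sim <- generateSynthetic(nCells = 90, nGenes = 200, nClusters = 3,
#'                          effect = 8, dropout = 0, seed = 1)
#' fit <- scMCGF(sim$expression, c = 3, geneSets = sim$geneSets)
#' ari(clusterLabels(fit), sim$labels)
#' @export
scMCGF <- function(x, c, geneSets = NULL,
                   include = c("expression", "pathway", "pca", "dm"),
                   k = "auto", nHVG = 2000, maxZeroFrac = 0.95,
                   logRangeThreshold = 100,
                   hvgMethod = c("variance", "dispersion"),
                   maxIter = 50, seed = 0, ...) {
  hvgMethod <- match.arg(hvgMethod)
  pre <- preprocessPipeline(x, maxZeroFrac = maxZeroFrac, nHVG = nHVG,
                            logRangeThreshold = logRangeThreshold,
                            hvgMethod = hvgMethod)
  views <- buildViews(pre, geneSets = geneSets, include = include,
                      raw = x, ...)
  runSCMCGF(views, c = c, k = k, maxIter = maxIter, seed = seed)
}
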