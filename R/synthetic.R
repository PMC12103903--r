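## Synthetic clustered scRNA-seq data with matching gene sets.

# Evaluate expr with a locally seeded RNG, restoring global state after.
withLocalSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) oldSeed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", oldSeed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic clustered expression matrix with gene sets
#'
#' Emulates a clustered scRNA-seq count matrix: every gene has a baseline
#' mean (log-normal across genes); each cluster owns a disjoint random set
#' of marker genes whose mean is multiplied by \code{effect} in cells of
#' that cluster; counts are drawn from a Poisson (or negative binomial)
#' model and then thinned by independent dropout. A matching pathway
#' collection is generated: a fraction of sets is enriched for one
#' cluster's markers, the rest sample genes at random. Everything is
#' reproducible from \code{seed} and the caller's RNG state is untouched.
#'
#' @param nCells Number of cells (default 300).
#' @param nGenes Number of genes (default 1000).
#' @param nClusters Number of clusters c >= 2 (default 3).
#' @param effect Fold change applied to a cluster's marker genes
#'   (default 8; \code{effect = 1} makes clusters indistinguishable).
#' @param dropout Independent zeroing probability in [0, 1) (default 0.3).
#' @param nPathways Number of gene sets to generate (default 50).
#' @param seed Integer seed (default 1).
#' @param markersPerCluster Marker genes per cluster (default 50); the
#'   marker pools of different clusters are disjoint.
#' @param model Count model, \code{"poisson"} (default) or \code{"nb"}.
#' @param dispersion Negative binomial size parameter (only for
#'   \code{model = "nb"}; default 2).
#' @param proportions Either \code{"equal"} (default) or a numeric vector
#'   of c cluster proportions; \code{sizeAlpha} draws them instead.
#' @param sizeAlpha Optional Dirichlet concentration for random imbalanced
#'   cluster proportions.
#' @param setSize Genes per pathway set (default 20).
#' @param enrichedFrac Fraction of sets enriched for one cluster's markers
#'   (default 0.5).
#' @param baselineMeanlog,baselineSdlog Log-normal parameters of per-gene
#'   baseline means (defaults log(1.5), 0.5).
#' @return A list with components \code{expression} (genes x cells count
#'   matrix), \code{geneSets} (a [PathwayCollection-class]), \code{labels}
#'   (integer vector in 1..c named by cell id) and \code{params}.
#' @examples
#' sim <- generateSynthetic(nCells = 60, nGenes = 100, nClusters = 2,
#'                          seed = 7)
#' table(sim$labels)
#' @export
generateSynthetic <- function(nCells = 300, nGenes = 1000, nClusters = 3,
                              effect = 8, dropout = 0.3, nPathways = 50,
                              seed = 1, markersPerCluster = 50,
                              model = c("poisson", "nb"), dispersion = 2,
                              proportions = "equal", sizeAlpha = NULL,
                              setSize = 20, enrichedFrac = 0.5,
                              baselineMeanlog = log(1.5),
                              baselineSdlog = 0.5) {
  model <- match.arg(model)
  if (nClusters < 2) stop("nClusters must be >= 2")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (effect <= 0) stop("effect must be positive")
  if (markersPerCluster * nClusters > nGenes)
    stop("infeasible marker allocation: ", markersPerCluster * nClusters,
         " markers requested but only ", nGenes, " genes available")

  withLocalSeed(seed, {
    geneIds <- sprintf("G%04d", seq_len(nGenes))
    cellIds <- sprintf("cell%04d", seq_len(nCells))

    sizes <- clusterSizes(nCells, nClusters, proportions, sizeAlpha)
    labels <- rep(seq_len(nClusters), times = sizes)
    names(labels) <- cellIds

    # disjoint marker pools, one per cluster
    markerPool <- sample.int(nGenes, markersPerCluster * nClusters)
    markers <- split(markerPool,
                     rep(seq_len(nClusters), each = markersPerCluster))

    baseMean <- stats::rlnorm(nGenes, baselineMeanlog, baselineSdlog)
    meanMat <- matrix(baseMean, nGenes, nClusters)
    for (cl in seq_len(nClusters))
      meanMat[markers[[cl]], cl] <- meanMat[markers[[cl]], cl] * effect

    mu <- meanMat[, labels, drop = FALSE]
    counts <- if (model == "poisson") {
      matrix(stats::rpois(length(mu), mu), nGenes, nCells)
    } else {
      matrix(stats::rnbinom(length(mu), size = dispersion, mu = mu),
             nGenes, nCells)
    }
    if (dropout > 0) {
      keep <- matrix(stats::rbinom(length(counts), 1L, 1 - dropout),
                     nGenes, nCells)
      counts <- counts * keep
    }
    dimnames(counts) <- list(geneIds, cellIds)

    gs <- syntheticGeneSets(geneIds, markers, nPathways, setSize,
                            enrichedFrac, nClusters)

    list(expression = counts,
         geneSets = gs,
         labels = stats::setNames(as.integer(labels), cellIds),
         params = list(nCells = nCells, nGenes = nGenes,
                       nClusters = nClusters, effect = effect,
                       dropout = dropout, nPathways = nPathways,
                       seed = seed, model = model,
                       markersPerCluster = markersPerCluster))
  })
}

clusterSizes <- function(nCells, nClusters, proportions, sizeAlpha) {
  if (!is.null(sizeAlpha)) {
    g <- stats::rgamma(nClusters, shape = sizeAlpha)
    proportions <- g / sum(g)
  } else if (identical(proportions, "equal")) {
    proportions <- rep(1 / nClusters, nClusters)
  }
  if (length(proportions) != nClusters || any(proportions <= 0))
    stop("proportions must be ", nClusters, " positive values")
  proportions <- proportions / sum(proportions)
  # largest-remainder rounding so sizes sum exactly to nCells
  raw <- proportions * nCells
  sizes <- floor(raw)
  rem <- nCells - sum(sizes)
  if (rem > 0) {
    top <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[top] <- sizes[top] + 1L
  }
  if (any(sizes == 0))
    stop("cluster proportions leave an empty cluster; increase nCells")
  as.integer(sizes)
}

syntheticGeneSets <- function(geneIds, markers, nPathways, setSize,
                              enrichedFrac, nClusters) {
  if (nPathways == 0L)
    return(PathwayCollection(list()))
  nGenes <- length(geneIds)
  nEnriched <- round(enrichedFrac * nPathways)
  sets <- vector("list", nPathways)
  descs <- character(nPathways)
  for (p in seq_len(nPathways)) {
    if (p <= nEnriched) {
      cl <- ((p - 1L) %% nClusters) + 1L
      pool <- markers[[cl]]
      nFromPool <- min(length(pool), ceiling(0.7 * setSize))
      chosen <- sample(pool, nFromPool)
      rest <- sample(setdiff(seq_len(nGenes), chosen),
                     setSize - nFromPool)
      sets[[p]] <- geneIds[c(chosen, rest)]
      descs[p] <- sprintf("enriched_cluster%d", cl)
    } else {
      sets[[p]] <- geneIds[sample.int(nGenes, min(setSize, nGenes))]
      descs[p] <- "random"
    }
  }
  names(sets) <- sprintf("PW%03d", seq_len(nPathways))
  PathwayCollection(sets, descs)
}
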