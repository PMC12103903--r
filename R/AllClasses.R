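#' @import methods
#' @importFrom utils head
NULL

#' PathwayCollection: a named collection of gene sets
#'
#' Lightweight container for pathway gene sets as read from a GMT file or
#' produced by the synthetic generator. Each set is a character vector of
#' gene identifiers; set names are unique and every set is non-empty.
#'
#' @slot sets Named list of character vectors (gene identifiers per set).
#' @slot descriptions Character vector of per-set descriptions, parallel to
#'   \code{sets} (may be empty strings).
#'
#' @seealso [readGeneSets()], [writeGeneSets()], [aucellView()]
#' @export
setClass("PathwayCollection",
  representation(sets = "list", descriptions = "character"))

setValidity("PathwayCollection", function(object) {
  msg <- character()
  s <- object@sets
  if (length(s) > 0L) {
    if (is.null(names(s)) || anyNA(names(s)) || any(names(s) == ""))
      msg <- c(msg, "every gene set must be named")
    if (anyDuplicated(names(s)))
      msg <- c(msg, "gene set names must be unique")
    if (!all(vapply(s, is.character, logical(1L))))
      msg <- c(msg, "gene sets must be character vectors")
    if (any(lengths(s) == 0L))
      msg <- c(msg, "every gene set must be non-empty")
  }
  if (length(object@descriptions) != length(s))
    msg <- c(msg, "descriptions must be parallel to sets")
  if (length(msg)) msg else TRUE
})

#' Construct a PathwayCollection
#'
#' @param sets Named list of character vectors of gene identifiers.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return A [PathwayCollection-class] object.
#' @examples
#' pc <- PathwayCollection(list(P1 = c("G1", "G2"), P2 = c("G3")))
#' lengths(geneSets(pc))
#' @export
PathwayCollection <- function(sets, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  new("PathwayCollection", sets = sets,
      descriptions = as.character(descriptions))
}

#' ViewSet: an ordered collection of feature matrices over the same cells
#'
#' Each view is a numeric matrix with features in rows and cells in columns
#' (d_v x n). All views share the same cells in the same order.
#'
#' @slot views Named list of numeric matrices, each d_v x n.
#' @slot cellIds Character vector of cell identifiers (length n).
#'
#' @seealso [buildViews()], [runSCMCGF()]
#' @export
setClass("ViewSet", representation(views = "list", cellIds = "character"))

setValidity("ViewSet", function(object) {
  msg <- character()
  v <- object@views
  if (length(v) < 1L) msg <- c(msg, "at least one view is required")
  if (is.null(names(v)) || anyDuplicated(names(v)))
    msg <- c(msg, "views must have unique names")
  n <- length(object@cellIds)
  for (nm in names(v)) {
    m <- v[[nm]]
    if (!is.matrix(m) || !is.numeric(m)) {
      msg <- c(msg, sprintf("view '%s' is not a numeric matrix", nm))
      next
    }
    if (ncol(m) != n)
      msg <- c(msg, sprintf("view '%s' has %d columns, expected %d cells",
                            nm, ncol(m), n))
    if (any(!is.finite(m)))
      msg <- c(msg, sprintf("view '%s' contains non-finite entries", nm))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ViewSet
#'
#' @param views Named list of numeric matrices (features x cells), all with
#'   the same number of columns in the same cell order.
#' @param cellIds Character vector of cell identifiers; defaults to the
#'   column names of the first view.
#' @return A [ViewSet-class] object.
#' @export
ViewSet <- function(views, cellIds = NULL) {
  views <- lapply(views, as.matrix)
  if (is.null(cellIds)) {
    cellIds <- colnames(views[[1L]])
    if (is.null(cellIds)) cellIds <- paste0("cell", seq_len(ncol(views[[1L]])))
  }
  new("ViewSet", views = views, cellIds = as.character(cellIds))
}

#' SCMCGFFit: the state of a multi-view graph fusion run
#'
#' Holds every optimizer variable of one run: the per-view similarity
#' graphs S^v, the view weights w, the unified graph U with its spectral
#' embedding F, the rank-constraint regularizer lambda, the final cluster
#' labels and the per-iteration history.
#'
#' @slot graphs List of n x n per-view similarity matrices S^v (row-stochastic,
#'   k-sparse, zero diagonal).
#' @slot gammas List of per-row regularization scalars (one numeric vector
#'   per view) realizing the sparsity-controlling gamma of the graph model.
#' @slot weights Numeric vector of view weights w_v (positive).
#' @slot unified n x n unified graph matrix U (row-stochastic, nonnegative).
#' @slot embedding n x c matrix F with orthonormal columns (eigenvectors of
#'   the c smallest eigenvalues of the Laplacian of U).
#' @slot eigenvalues The c smallest Laplacian eigenvalues at termination.
#' @slot lambda Final value of the rank-constraint regularizer.
#' @slot labels Integer cluster labels (1..c) per cell.
#' @slot k Neighbor count used for the similarity graphs.
#' @slot nClusters Requested number of clusters c.
#' @slot iterations Number of alternating-optimization iterations executed.
#' @slot converged TRUE if the unified graph reached exactly c connected
#'   components.
#' @slot fallbackUsed TRUE if labels came from the seeded k-means fallback
#'   on the embedding rather than from graph components.
#' @slot history data.frame with one row per iteration: objective value,
#'   lambda, number of near-zero Laplacian eigenvalues, component count and
#'   view weights.
#'
#' @seealso [runSCMCGF()], [clusterLabels()], [unifiedGraph()]
#' @export
setClass("SCMCGFFit",
  representation(graphs = "list", gammas = "list", weights = "numeric",
                 unified = "matrix", embedding = "matrix",
                 eigenvalues = "numeric", lambda = "numeric",
                 labels = "integer", k = "integer", nClusters = "integer",
                 iterations = "integer", converged = "logical",
                 fallbackUsed = "logical", history = "data.frame"))

setValidity("SCMCGFFit", function(object) {
  msg <- character()
  n <- nrow(object@unified)
  if (ncol(object@unified) != n)
    msg <- c(msg, "unified graph must be square")
  for (S in object@graphs)
    if (!all(dim(S) == c(n, n)))
      msg <- c(msg, "per-view graphs must match the unified graph dimensions")
  if (length(object@weights) != length(object@graphs))
    msg <- c(msg, "one weight per view required")
  if (length(object@labels) && length(object@labels) != n)
    msg <- c(msg, "one label per cell required")
  if (nrow(object@embedding) != n)
    msg <- c(msg, "embedding rows must match cell count")
  if (length(object@lambda) != 1L || object@lambda <= 0)
    msg <- c(msg, "lambda must be a positive scalar")
  if (length(msg)) msg else TRUE
})
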