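#' Accessor generics
#'
#' Accessors for the package's S4 containers: gene sets of a
#' [PathwayCollection-class], views and dimensions of a [ViewSet-class],
#' and the components of a fitted [SCMCGFFit-class].
#'
#' @param object An object of the documented class.
#' @param name For [getView()], the view name or index.
#' @return The corresponding component (see the method descriptions).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))

#' @rdname accessors
#' @export
setGeneric("nViews", function(object) standardGeneric("nViews"))

#' @rdname accessors
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))

#' @rdname accessors
#' @export
setGeneric("viewNames", function(object) standardGeneric("viewNames"))

#' @rdname accessors
#' @export
setGeneric("getView", function(object, name) standardGeneric("getView"))

#' @rdname accessors
#' @export
setGeneric("cellIds", function(object) standardGeneric("cellIds"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("unifiedGraph", function(object) standardGeneric("unifiedGraph"))

#' @rdname accessors
#' @export
setGeneric("viewWeights", function(object) standardGeneric("viewWeights"))

#' @rdname accessors
#' @export
setGeneric("similarityGraphs",
           function(object) standardGeneric("similarityGraphs"))

#' @rdname accessors
#' @export
setGeneric("embedding", function(object) standardGeneric("embedding"))

#' @rdname accessors
#' @export
setGeneric("convergenceHistory",
           function(object) standardGeneric("convergenceHistory"))

## ---- PathwayCollection ----

#' @rdname accessors
#' @export
setMethod("geneSets", "PathwayCollection", function(object) object@sets)

#' @describeIn accessors Number of gene sets.
#' @export
setMethod("length", "PathwayCollection", function(x) length(x@sets))

#' @describeIn accessors Gene set names.
#' @param x A PathwayCollection.
#' @export
setMethod("names", "PathwayCollection", function(x) names(x@sets))

setMethod("show", "PathwayCollection", function(object) {
  cat("PathwayCollection with", length(object@sets), "gene sets\n")
  if (length(object@sets)) {
    sz <- lengths(object@sets)
    cat("  set sizes: min", min(sz), "median", stats::median(sz),
        "max", max(sz), "\n")
    cat("  names:", paste(head(names(object@sets), 5L), collapse = ", "),
        if (length(object@sets) > 5L) "..." else "", "\n")
  }
})

## ---- ViewSet ----

#' @rdname accessors
#' @export
setMethod("nViews", "ViewSet", function(object) length(object@views))

#' @rdname accessors
#' @export
setMethod("nCells", "ViewSet", function(object) length(object@cellIds))

#' @rdname accessors
#' @export
setMethod("viewNames", "ViewSet", function(object) names(object@views))

#' @rdname accessors
#' @export
setMethod("getView", "ViewSet", function(object, name) object@views[[name]])

#' @rdname accessors
#' @export
setMethod("cellIds", "ViewSet", function(object) object@cellIds)

setMethod("show", "ViewSet", function(object) {
  cat("ViewSet:", length(object@views), "view(s) over",
      length(object@cellIds), "cells\n")
  for (nm in names(object@views))
    cat(sprintf("  %-12s %d x %d\n", nm, nrow(object@views[[nm]]),
                ncol(object@views[[nm]])))
})

## ---- SCMCGFFit ----

#' @rdname accessors
#' @export
setMethod("clusterLabels", "SCMCGFFit", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("unifiedGraph", "SCMCGFFit", function(object) object@unified)

#' @rdname accessors
#' @export
setMethod("viewWeights", "SCMCGFFit", function(object) object@weights)

#' @rdname accessors
#' @export
setMethod("similarityGraphs", "SCMCGFFit", function(object) object@graphs)

#' @rdname accessors
#' @export
setMethod("embedding", "SCMCGFFit", function(object) object@embedding)

#' @rdname accessors
#' @export
setMethod("convergenceHistory", "SCMCGFFit", function(object) object@history)

setMethod("show", "SCMCGFFit", function(object) {
  n <- nrow(object@unified)
  cat("SCMCGFFit:", n, "cells,", length(object@graphs), "view(s),",
      object@nClusters, "clusters requested\n")
  cat("  iterations:", object@iterations,
      "| converged:", object@converged,
      "| fallback k-means:", object@fallbackUsed, "\n")
  cat("  lambda:", format(object@lambda, digits = 4),
      "| view weights:",
      paste(format(object@weights, digits = 3), collapse = " "), "\n")
  if (length(object@labels))
    cat("  cluster sizes:",
        paste(tabulate(object@labels), collapse = " "), "\n")
})
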