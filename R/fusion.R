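## Constrained-Laplacian-rank fusion core: the unified graph U, its
## spectral embedding F, the rank-constraint regularizer lambda, and the
## alternating optimization that couples them with the per-view graphs.

#' Graph Laplacian of the unified graph
#'
#' L_U = D_U - (U' + U)/2, where the degree matrix D_U has i-th diagonal
#' element sum_j (u_ij + u_ji)/2. L_U is symmetric positive semi-definite
#' with zero row sums.
#'
#' @param U n x n nonnegative matrix.
#' @return List with \code{L} (the Laplacian) and \code{W} (the
#'   symmetrized adjacency (U' + U)/2).
#' @export
laplacianU <- function(U) {
  W <- (U + t(U)) / 2
  L <- diag(rowSums(W)) - W
  list(L = L, W = W)
}

#' Spectral embedding from the c smallest Laplacian eigenvectors
#'
#' Solves min Tr(F' L F) subject to F'F = I: the columns of F are the
#' eigenvectors of the c smallest eigenvalues of the symmetric Laplacian
#' (Ky Fan). A deterministic sign convention makes the largest-magnitude
#' entry of each column positive.
#'
#' @param L Symmetric Laplacian matrix.
#' @param c Number of embedding dimensions (target cluster count).
#' @return List with \code{F} (n x c orthonormal), \code{values} (the c
#'   smallest eigenvalues, ascending) and \code{allValues} (the full
#'   ascending spectrum).
#' @export
updateEmbedding <- function(L, c) {
  n <- nrow(L)
  stopifnot(c >= 1, c <= n)
  eig <- eigen((L + t(L)) / 2, symmetric = TRUE)
  vals <- rev(eig$values)                      # ascending
  idx <- n:(n - c + 1L)                        # c smallest
  F <- fixSigns(eig$vectors[, idx, drop = FALSE])
  list(F = F, values = vals[seq_len(c)], allValues = vals)
}

#' Euclidean projection onto the probability simplex
#'
#' Projects p onto \{u : u >= 0, 1'u = 1\}. The projection is
#' u_j = (p_j - phi)_+ where phi is the root of
#' \deqn{f(\varphi) = \frac{1}{n}\sum_j (\varphi - p_j)_+ - \varphi}
#' (after centering p onto the hyperplane 1'p = 1, which leaves the
#' projection unchanged). The root is found by Newton iteration with a
#' bisection safeguard, to |f| < 1e-12 or 100 iterations.
#'
#' @param p Finite numeric vector.
#' @param tol Root tolerance (default 1e-12).
#' @param maxIter Iteration cap (default 100).
#' @return The projected vector (nonnegative, summing to 1).
#' @examples
#' simplexProject(c(0.5, 0.3, 0.4))   # 0.4333 0.2333 0.3333
#' simplexProject(c(1.2, -0.1, 0.1))  # 1 0 0
#' @export
simplexProject <- function(p, tol = 1e-12, maxIter = 100L) {
  if (any(!is.finite(p))) stop("non-finite input to simplex projection")
  n <- length(p)
  if (n == 1L) return(1)
  # shift along 1 onto the sum-to-one hyperplane (projection-invariant)
  p <- p + (1 - sum(p)) / n
  f <- function(phi) sum(pmax(phi - p, 0)) / n - phi
  lo <- min(p) - 1           # f(lo) = -lo - ? > 0 region bound
  hi <- max(p)               # f(hi) >= ... sign change bracket
  phi <- 0
  for (it in seq_len(maxIter)) {
    fv <- f(phi)
    if (abs(fv) < tol) break
    if (fv > 0) lo <- phi else hi <- phi   # f is decreasing in phi
    m <- sum(p < phi)
    fp <- m / n - 1
    step <- if (fp < 0) phi - fv / fp else NA_real_
    phi <- if (is.finite(step) && step > lo && step < hi) step
           else (lo + hi) / 2
  }
  pmax(p - phi, 0)
}

#' Update the unified graph row by row
#'
#' For each cell i, with d_ij = ||f_i - f_j||^2 the squared embedding
#' distances, forms q^v = s_i^v - (lambda / (2 m w_v)) d_i per view and
#' sets u_i to the Euclidean projection of the mean of \{q^v\} onto the
#' probability simplex.
#'
#' @param graphs List of per-view similarity matrices S^v.
#' @param weights Positive view weights w_v.
#' @param F n x c embedding matrix.
#' @param lam Rank-constraint regularizer lambda > 0.
#' @return n x n row-stochastic unified graph U.
#' @export
updateUnified <- function(graphs, weights, F, lam) {
  stopifnot(length(graphs) == length(weights), lam > 0,
            all(weights > 0))
  m <- length(graphs)
  n <- nrow(graphs[[1L]])
  Df <- pairwiseSqDist(F)
  Qbar <- matrix(0, n, n)
  for (v in seq_len(m))
    Qbar <- Qbar + graphs[[v]] - (lam / (2 * m * weights[v])) * Df
  Qbar <- Qbar / m
  U <- matrix(0, n, n, dimnames = dimnames(graphs[[1L]]))
  for (i in seq_len(n)) U[i, ] <- simplexProject(Qbar[i, ])
  U
}

# Connected components of a symmetric adjacency by traversal.
graphComponentLabels <- function(A) {
  n <- nrow(A)
  labels <- integer(n)
  comp <- 0L
  for (start in seq_len(n)) {
    if (labels[start]) next
    comp <- comp + 1L
    queue <- start
    labels[start] <- comp
    while (length(queue)) {
      i <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(A[i, ] & labels == 0L)
      labels[nb] <- comp
      queue <- c(queue, nb)
    }
  }
  labels
}

#' Count connected components of the unified graph
#'
#' Components are computed two ways: by traversal of the undirected graph
#' with adjacency (U + U')/2 thresholded at \code{edgeTol}, and as the
#' multiplicity of near-zero eigenvalues (< \code{eigTol}) of the
#' Laplacian. The two counts are compared and a mismatch emits a warning
#' diagnostic (the traversal count is returned either way).
#'
#' @param U n x n nonnegative matrix.
#' @param edgeTol Edge threshold on the symmetrized adjacency
#'   (default 1e-8).
#' @param eigTol Near-zero eigenvalue tolerance (default 1e-10 * n).
#' @param checkEigen Set FALSE to skip the eigen cross-check.
#' @return List with \code{count}, \code{labels} (component label per
#'   cell) and, when checked, \code{eigenCount}.
#' @export
countComponents <- function(U, edgeTol = 1e-8, eigTol = NULL,
                            checkEigen = TRUE) {
  n <- nrow(U)
  if (is.null(eigTol)) eigTol <- 1e-10 * n
  A <- (U + t(U)) / 2 > edgeTol
  diag(A) <- FALSE
  labels <- graphComponentLabels(A)
  count <- max(labels)
  out <- list(count = count, labels = labels)
  if (checkEigen) {
    vals <- eigen(laplacianU(U)$L, symmetric = TRUE, only.values = TRUE)$values
    eigenCount <- sum(abs(vals) < eigTol)
    if (eigenCount != count)
      warning("component count mismatch: traversal finds ", count,
              " components but the Laplacian has ", eigenCount,
              " near-zero eigenvalues")
    out$eigenCount <- eigenCount
  }
  out
}

#' Adapt the rank-constraint regularizer
#'
#' Standard constrained-Laplacian-rank practice: with z the number of
#' near-zero Laplacian eigenvalues, lambda is doubled when z < c (the
#' graph is still too connected), halved when z > c (over-segmented; the
#' caller should redo the last unified-graph update), and left unchanged
#' with convergence flagged when z = c.
#'
#' @param lam Current lambda.
#' @param z Number of near-zero Laplacian eigenvalues.
#' @param c Target cluster count.
#' @return List with \code{lambda}, \code{converged} and \code{recompute}
#'   (TRUE when the unified graph should be re-updated with the smaller
#'   lambda).
#' @export
adaptLambda <- function(lam, z, c) {
  if (z < c)      list(lambda = lam * 2, converged = FALSE, recompute = FALSE)
  else if (z > c) list(lambda = lam / 2, converged = FALSE, recompute = TRUE)
  else            list(lambda = lam,     converged = TRUE,  recompute = FALSE)
}

#' Value of the fusion objective
#'
#' Evaluates the full objective at the given state:
#' \deqn{\sum_v \sum_{ij} e^v_{ij} s^v_{ij} + \sum_v \sum_i \gamma^v_i
#'   \lVert s^v_i \rVert^2 + \sum_v w_v \lVert U - S^v \rVert_F^2 +
#'   2\lambda\, \mathrm{Tr}(F' L_U F)}
#' with e^v the squared distances of view v. The gamma and w arguments
#' are taken as given, so the value is comparable across states evaluated
#' with the same (gamma, w, lambda).
#'
#' @param dists List of per-view squared-distance matrices.
#' @param graphs List of per-view similarity matrices.
#' @param gammas List of per-row gamma vectors (one per view).
#' @param weights View weights.
#' @param U Unified graph.
#' @param F Embedding matrix.
#' @param lam Lambda.
#' @return Scalar objective value.
#' @export
fusionObjective <- function(dists, graphs, gammas, weights, U, F, lam) {
  m <- length(graphs)
  val <- 0
  for (v in seq_len(m)) {
    S <- graphs[[v]]
    val <- val + sum(dists[[v]] * S)
    val <- val + sum(gammas[[v]] * rowSums(S^2))
    val <- val + weights[v] * sum((U - S)^2)
  }
  L <- laplacianU(U)$L
  val + 2 * lam * sum(diag(t(F) %*% L %*% F))
}

#' Run the multi-view graph fusion clustering
#'
#' The full alternating optimization: per-view similarity graphs are
#' initialized by the adaptive-neighbor closed form and the view weights
#' uniformly; the unified graph U starts as the simplex-projected
#' weighted mean of the initial graphs, and F as the bottom
#' eigenvectors of its Laplacian. Each iteration then updates, in order,
#' the per-view graphs, the view weights, the unified graph and the
#' embedding, and finally adapts lambda against the near-zero eigenvalue
#' count of L_U. The loop stops when U has exactly c connected
#' components (clusters = components) or after \code{maxIter}
#' iterations, in which case a seeded k-means on the rows of F supplies
#' the labels and the fit is flagged as a fallback.
#'
#' @param views A [ViewSet-class] (see [buildViews()]).
#' @param c Target number of clusters (>= 2).
#' @param k Neighbor count, or \code{"auto"} (5 below 3000 cells, 15
#'   otherwise).
#' @param maxIter Maximum number of alternating iterations (default 50).
#' @param lambdaInit Initial lambda, or \code{"auto"} (mean of the
#'   initialization's per-row gamma over views and rows).
#' @param eigTol Near-zero eigenvalue tolerance (default 1e-10 * n).
#' @param edgeTol Edge threshold for component extraction (default 1e-8).
#' @param fallback \code{"kmeans_F"} (default) or \code{"error"}:
#'   behavior when the rank constraint is never met.
#' @param seed Seed for the k-means fallback (default 0).
#' @param ordering Candidate ranking rule for the graph updates, see
#'   [updateSimilarityGraph()].
#' @return A [SCMCGFFit-class]; cluster labels via [clusterLabels()].
#' @export
runSCMCGF <- function(views, c, k = "auto", maxIter = 50,
                      lambdaInit = "auto", eigTol = NULL, edgeTol = 1e-8,
                      fallback = c("kmeans_F", "error"), seed = 0,
                      ordering = c("combined", "distance")) {
  fallback <- match.arg(fallback)
  ordering <- match.arg(ordering)
  stopifnot(is(views, "ViewSet"), c >= 2)
  n <- nCells(views)
  m <- nViews(views)
  if (c > n) stop("more clusters requested than cells")
  if (identical(k, "auto")) k <- defaultK(n)
  k <- as.integer(k)
  if (k < 1 || k > n - 2) stop("k must be in [1, n - 2]")
  if (is.null(eigTol)) eigTol <- 1e-10 * n

  dists <- lapply(views@views, function(X) pairwiseSqDist(t(X)))
  init <- lapply(dists, initSimilarityGraph, k = k)
  graphs <- lapply(init, `[[`, "S")
  gammas <- lapply(init, `[[`, "gamma")
  w <- initWeights(m)

  U <- Reduce(`+`, Map(`*`, graphs, w))
  for (i in seq_len(n)) U[i, ] <- simplexProject(U[i, ])
  dimnames(U) <- list(cellIds(views), cellIds(views))

  lam <- if (identical(lambdaInit, "auto")) {
    mean(unlist(gammas))
  } else as.numeric(lambdaInit)
  if (!is.finite(lam) || lam <= 0) lam <- 1

  emb <- updateEmbedding(laplacianU(U)$L, c)
  history <- vector("list", maxIter)
  converged <- FALSE
  iter <- 0L

  for (iter in seq_len(maxIter)) {
    upd <- Map(function(D, wv) updateSimilarityGraph(D, U, wv, k,
                                                     ordering = ordering),
               dists, as.list(w))
    graphs <- lapply(upd, `[[`, "S")
    gammas <- lapply(upd, `[[`, "gamma")
    w <- updateViewWeights(U, graphs)
    U <- updateUnified(graphs, w, emb$F, lam)
    emb <- updateEmbedding(laplacianU(U)$L, c)
    if (any(!is.finite(U)) || any(!is.finite(emb$F)))
      stop("non-finite optimizer state at iteration ", iter)
    z <- sum(abs(emb$allValues) < eigTol)
    comp <- countComponents(U, edgeTol = edgeTol, checkEigen = FALSE)
    ad <- adaptLambda(lam, z, c)
    if (ad$recompute) {
      lam <- ad$lambda
      U <- updateUnified(graphs, w, emb$F, lam)
      emb <- updateEmbedding(laplacianU(U)$L, c)
      z <- sum(abs(emb$allValues) < eigTol)
      comp <- countComponents(U, edgeTol = edgeTol, checkEigen = FALSE)
    } else {
      lam <- ad$lambda
    }
    simplexErr <- max(vapply(c(graphs, list(U)),
                             function(S) max(abs(rowSums(S) - 1)),
                             numeric(1L)))
    minEntry <- min(vapply(c(graphs, list(U)), min, numeric(1L)))
    history[[iter]] <- cbind(
      data.frame(
        iteration = iter,
        objective = fusionObjective(dists, graphs, gammas, w, U, emb$F, lam),
        lambda = lam,
        zeroEigs = z,
        components = comp$count,
        maxRowSumErr = simplexErr,
        minEntry = minEntry,
        row.names = NULL),
      as.data.frame(as.list(
        stats::setNames(w, paste0("w_", viewNames(views))))))
    if (comp$count == c) { converged <- TRUE; break }
  }
  history <- do.call(rbind, history[!vapply(history, is.null, logical(1L))])

  comp <- countComponents(U, edgeTol = edgeTol, eigTol = eigTol,
                          checkEigen = FALSE)
  fallbackUsed <- FALSE
  if (comp$count == c) {
    labels <- as.integer(comp$labels)
  } else if (fallback == "kmeans_F") {
    labels <- withLocalSeed(seed, {
      as.integer(stats::kmeans(emb$F, centers = c, nstart = 10L)$cluster)
    })
    fallbackUsed <- TRUE
  } else {
    stop("rank constraint not met: unified graph has ", comp$count,
         " components after ", iter, " iterations")
  }
  names(labels) <- cellIds(views)

  new("SCMCGFFit",
      graphs = graphs, gammas = gammas, weights = w, unified = U,
      embedding = emb$F, eigenvalues = emb$values, lambda = lam,
      labels = labels, k = k, nClusters = as.integer(c),
      iterations = iter, converged = converged,
      fallbackUsed = fallbackUsed,
      history = if (is.null(history)) data.frame() else history)
}
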