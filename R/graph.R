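## Per-view similarity graphs with adaptive neighbors, and view weights.
##
## Each row of a similarity graph solves a simplex-constrained problem:
## minimize sum_j dist_ij * s_ij + gamma_i ||s_i||^2 (plus, during
## updates, a coupling to the unified graph), with s_ii = 0, s_ij >= 0,
## sum_j s_ij = 1. The per-row gamma_i is set to the closed-form value
## that makes the minimizer exactly k-sparse.

#' Pairwise squared Euclidean distances
#'
#' @param x n x d matrix of points in rows.
#' @return Symmetric n x n matrix of squared Euclidean distances with a
#'   zero diagonal; round-off negatives are clamped to 0.
#' @export
pairwiseSqDist <- function(x) {
  x <- as.matrix(x)
  sq <- rowSums(x^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  # enforce exact symmetry against round-off
  (d2 + t(d2)) / 2
}

# Neighbor-count policy: 5 below 3000 cells, 15 at or above.
#' Default neighbor count for a data set
#'
#' @param n Number of cells.
#' @return 5 if n < 3000, else 15.
#' @export
defaultK <- function(n) if (n < 3000) 5L else 15L

# Shared row solver: given candidate costs (ascending order already
# chosen), weights for the k nearest, uniform fallback on degeneracy.
sparseRowWeights <- function(costSorted, k) {
  num <- costSorted[k + 1L] - costSorted[seq_len(k)]
  den <- k * costSorted[k + 1L] - sum(costSorted[seq_len(k)])
  if (abs(den) < .Machine$double.eps * max(1, abs(costSorted[k + 1L]))) {
    rep(1 / k, k)                       # k nearest equidistant with (k+1)-th
  } else {
    w <- num / den
    if (any(w < 0)) {                   # numerical guard; clamp + renorm
      w[w < 0] <- 0
      w <- w / sum(w)
    }
    w
  }
}

#' Initialize a similarity graph from a distance matrix
#'
#' Closed-form adaptive-neighbor construction: for each row i, with
#' b_i(1) <= b_i(2) <= ... the ascending squared distances to the other
#' points (self excluded, ties broken by ascending index),
#' \deqn{s_{ij} = \frac{b_{i,k+1} - b_{ij}}{k\, b_{i,k+1} -
#'   \sum_{h=1}^k b_{ih}}}
#' for the k nearest neighbors and 0 elsewhere. Each row lies on the
#' probability simplex and has exactly k nonzero entries; the implied
#' per-row regularizer gamma_i = (k/2) b_{i,k+1} - (1/2) sum_{h<=k} b_{ih}
#' is recorded. If the k nearest are all equidistant with the (k+1)-th,
#' the row falls back to uniform 1/k weights.
#'
#' @param D n x n squared-distance matrix (see [pairwiseSqDist()]).
#' @param k Neighbor count, 1 <= k <= n - 2.
#' @return List with \code{S} (n x n similarity matrix) and \code{gamma}
#'   (per-row regularization scalars).
#' @export
initSimilarityGraph <- function(D, k) {
  n <- nrow(D)
  stopifnot(ncol(D) == n, k >= 1, k <= n - 2)
  S <- matrix(0, n, n, dimnames = dimnames(D))
  gamma <- numeric(n)
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    ord <- cand[order(D[i, cand], cand)]
    b <- D[i, ord]
    S[i, ord[seq_len(k)]] <- sparseRowWeights(b, k)
    gamma[i] <- (k / 2) * b[k + 1L] - 0.5 * sum(b[seq_len(k)])
  }
  list(S = S, gamma = gamma)
}

#' Update a similarity graph given the unified graph
#'
#' Re-solves each row's simplex problem with the coupling term
#' w_v ||u_i - s_i||^2 added: candidates j are ranked by the effective
#' cost \eqn{\hat e_{ij} = e_{ij} - 2 w_v u_{ij}} ascending (e = squared
#' distance in the view), and the first k receive weights
#' \deqn{s_{ij} = \frac{e_{i,k+1} - e_{ij} + 2 w_v u_{ij}
#'   - 2 w_v u_{i,k+1}}{k e_{i,k+1} - \sum_{h=1}^k e_{ih}
#'   - 2 k w_v u_{i,k+1} + 2 w_v \sum_{h=1}^k u_{ih}}}
#' where the subscript (k+1) indexes position k+1 of the effective-cost
#' ordering (\code{ordering = "combined"}, the default, which makes the
#' formula the exact k-sparse minimizer; \code{ordering = "distance"}
#' ranks by e alone, with negative weights clamped and the row
#' renormalized). At w_v = 0 the update reduces exactly to
#' [initSimilarityGraph()].
#'
#' @param D n x n squared-distance matrix of the view.
#' @param U Unified graph (row-stochastic n x n matrix).
#' @param wv View weight (nonnegative scalar).
#' @param k Neighbor count.
#' @param ordering Candidate ranking rule, \code{"combined"} or
#'   \code{"distance"}.
#' @return List with \code{S} and \code{gamma} as in
#'   [initSimilarityGraph()] (gamma here is the effective per-row value
#'   gamma_i + w_v implied by the k-sparse solution, minus w_v).
#' @export
updateSimilarityGraph <- function(D, U, wv, k,
                                  ordering = c("combined", "distance")) {
  ordering <- match.arg(ordering)
  n <- nrow(D)
  stopifnot(ncol(D) == n, all(dim(U) == n), wv >= 0, k >= 1, k <= n - 2)
  S <- matrix(0, n, n, dimnames = dimnames(D))
  gamma <- numeric(n)
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    eHat <- D[i, cand] - 2 * wv * U[i, cand]
    ord <- if (ordering == "combined") {
      cand[order(eHat, cand)]
    } else {
      cand[order(D[i, cand], cand)]
    }
    ehat <- D[i, ord] - 2 * wv * U[i, ord]
    num <- ehat[k + 1L] - ehat[seq_len(k)]
    den <- k * ehat[k + 1L] - sum(ehat[seq_len(k)])
    if (abs(den) < .Machine$double.eps * max(1, abs(ehat[k + 1L]))) {
      w <- rep(1 / k, k)
      warning("degenerate denominator in row ", i,
              "; uniform neighbor weights used")
    } else {
      w <- num / den
      if (any(w < 0)) {
        w[w < 0] <- 0
        sw <- sum(w)
        if (sw <= 0) {
          w <- rep(1 / k, k)
          warning("all-clamped row ", i, "; uniform neighbor weights used")
        } else w <- w / sw
      }
    }
    S[i, ord[seq_len(k)]] <- w
    gamma[i] <- (k / 2) * ehat[k + 1L] - 0.5 * sum(ehat[seq_len(k)]) - wv
  }
  list(S = S, gamma = gamma)
}

#' Initialize view weights
#'
#' @param m Number of views.
#' @return Uniform weight vector 1/m of length m.
#' @export
initWeights <- function(m) {
  stopifnot(m >= 1)
  rep(1 / m, m)
}

#' Update view weights from residuals to the unified graph
#'
#' \deqn{w_v = \frac{1}{2\,\lVert U - S^v\rVert_F}}
#' The Frobenius norm is floored at 1e-10 so a view identical to U gets a
#' large finite weight. The view closest to U always receives the
#' largest weight.
#'
#' @param U Unified graph matrix.
#' @param graphs List of per-view similarity matrices S^v.
#' @param floor Lower bound on the Frobenius norm (default 1e-10).
#' @return Numeric vector of positive view weights.
#' @export
updateViewWeights <- function(U, graphs, floor = 1e-10) {
  vapply(graphs, function(S) {
    nrm <- sqrt(sum((U - S)^2))
    1 / (2 * max(nrm, floor))
  }, numeric(1L))
}
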