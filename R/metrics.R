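## Clustering agreement metrics: clustering accuracy (optimal label
## matching), normalized mutual information, adjusted Rand index.

# Min-cost linear assignment by shortest augmenting paths (O(n^2 m)).
# cost: n x m matrix, n <= m. Returns, per row, the assigned column.
solveAssignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  vcol <- m + 1L                      # virtual start column
  u <- numeric(n)
  v <- numeric(vcol)
  p <- integer(vcol)                  # row matched to each column (0 = none)
  way <- integer(vcol)
  for (i in seq_len(n)) {
    p[vcol] <- i
    j0 <- vcol
    minv <- rep(Inf, m)
    used <- rep(FALSE, vcol)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(m)) {
        if (used[j]) next
        cur <- cost[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(vcol)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {                           # unwind the augmenting path
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == vcol) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0L) assign[p[j]] <- j
  assign
}

contingency <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) > 0)
  table(factor(pred), factor(truth))
}

#' Clustering accuracy under optimal label matching
#'
#' The maximum fraction of agreeing cells over all one-to-one matchings
#' of predicted to true clusters, found by optimal assignment on the
#' contingency table (unequal cluster counts are padded with empty
#' clusters). Invariant to label permutation; in [0, 1].
#'
#' @param pred,truth Cluster label vectors of equal length.
#' @return Scalar accuracy in [0, 1].
#' @examples
#' clusteringAccuracy(c(0, 0, 1, 1), c(1, 1, 0, 0))  # 1: relabeling
#' clusteringAccuracy(c(0, 0, 1, 1), c(0, 1, 0, 1))  # 0.5
#' @export
clusteringAccuracy <- function(pred, truth) {
  tab <- unclass(contingency(pred, truth))
  r <- nrow(tab); s <- ncol(tab)
  d <- max(r, s)
  padded <- matrix(0, d, d)
  padded[seq_len(r), seq_len(s)] <- tab
  cost <- max(padded) - padded         # maximize matches
  assign <- solveAssignment(cost)
  matched <- sum(padded[cbind(seq_len(d), assign)])
  matched / length(pred)
}

#' Normalized mutual information between two partitions
#'
#' Mutual information of the two partitions normalized, by default, by
#' the arithmetic mean of their entropies. Degenerate cases where either
#' partition has a single cluster (zero entropy) return 0.
#'
#' @param pred,truth Cluster label vectors of equal length.
#' @param normalization \code{"arithmetic"} (default), \code{"sqrt"}
#'   (geometric mean) or \code{"max"}.
#' @return Scalar in [0, 1].
#' @export
nmi <- function(pred, truth,
                normalization = c("arithmetic", "sqrt", "max")) {
  normalization <- match.arg(normalization)
  tab <- unclass(contingency(pred, truth))
  n <- sum(tab)
  pij <- tab / n
  pi <- rowSums(pij)
  pj <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi, pj)[nz]))
  hi <- -sum(pi[pi > 0] * log(pi[pi > 0]))
  hj <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  denom <- switch(normalization,
                  arithmetic = (hi + hj) / 2,
                  sqrt = sqrt(hi * hj),
                  max = max(hi, hj))
  if (denom <= 0) return(0)
  max(0, min(1, mi / denom))
}

#' Adjusted Rand index
#'
#' Pair-counting Rand index corrected for chance agreement; ranges from
#' -1 to 1, with 1 for identical partitions and about 0 for independent
#' ones.
#'
#' @param pred,truth Cluster label vectors of equal length.
#' @return Scalar in [-1, 1].
#' @export
ari <- function(pred, truth) {
  tab <- unclass(contingency(pred, truth))
  n <- sum(tab)
  choose2 <- function(x) x * (x - 1) / 2
  sumIJ <- sum(choose2(tab))
  sumI <- sum(choose2(rowSums(tab)))
  sumJ <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  expected <- sumI * sumJ / total
  maxIndex <- (sumI + sumJ) / 2
  if (maxIndex == expected) return(0)   # both partitions trivial
  (sumIJ - expected) / (maxIndex - expected)
}

#' Evaluate a predicted partition against ground truth
#'
#' @param pred,truth Cluster label vectors of equal length.
#' @return Named list with \code{CA}, \code{NMI} and \code{ARI}.
#' @export
evaluateClustering <- function(pred, truth) {
  list(CA = clusteringAccuracy(pred, truth),
       NMI = nmi(pred, truth),
       ARI = ari(pred, truth))
}
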