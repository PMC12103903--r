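# Independent oracles used across tests.

# Sorting-based closed form for the Euclidean projection onto the
# probability simplex (independent of the package's Newton root-finder).
sortSimplexProject <- function(p) {
  n <- length(p)
  u <- sort(p, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_len(n) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(p - theta, 0)
}

# Generic constrained QP on the simplex (dual active-set solver):
# minimize 0.5 x'Hx + q'x  s.t.  sum(x) = 1, x >= 0.
qpSimplexOracle <- function(H, q) {
  n <- length(q)
  Amat <- cbind(rep(1, n), diag(n))
  bvec <- c(1, rep(0, n))
  quadprog::solve.QP(H, -q, Amat, bvec, meq = 1)$solution
}

# Row minimizer of the per-view graph problem
#   min_s sum_j e_j s_j + gamma ||s||^2 + wv ||u - s||^2
#   s.t. s on the simplex, s_self = 0
# solved by the generic QP oracle on the non-self coordinates.
graphRowOracle <- function(e, uRow, gamma, wv, self) {
  idx <- setdiff(seq_along(e), self)
  a <- gamma + wv
  H <- diag(2 * a, length(idx))
  q <- e[idx] - 2 * wv * uRow[idx]
  s <- numeric(length(e))
  s[idx] <- qpSimplexOracle(H, q)
  s
}

# Brute-force clustering accuracy: maximize agreement over all
# permutations of predicted cluster ids (small cluster counts only).
bruteForceCA <- function(pred, truth) {
  pu <- unique(pred)
  tu <- unique(truth)
  d <- max(length(pu), length(tu))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  target <- c(tu, rep(NA, d - length(tu)))
  best <- 0
  for (perm in perms(seq_len(d))) {
    mapped <- target[perm[match(pred, pu)]]
    best <- max(best, sum(!is.na(mapped) & mapped == truth))
  }
  best / length(pred)
}

# O(n^2) pair-counting adjusted Rand index, built purely from pair loops.
bruteForceARI <- function(pred, truth) {
  n <- length(pred)
  both <- sameP <- sameT <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- pred[i] == pred[j]
    t <- truth[i] == truth[j]
    if (p && t) both <- both + 1
    if (p) sameP <- sameP + 1
    if (t) sameT <- sameT + 1
  }
  total <- n * (n - 1) / 2
  expd <- sameP * sameT / total
  maxI <- (sameP + sameT) / 2
  if (maxI == expd) return(0)
  (both - expd) / (maxI - expd)
}

# Direct NMI from first principles (arithmetic-mean normalization).
directNMI <- function(pred, truth) {
  n <- length(pred)
  tab <- table(pred, truth)
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    nij <- tab[i, j]
    if (nij == 0) next
    mi <- mi + (nij / n) * log((nij * n) / (sum(tab[i, ]) * sum(tab[, j])))
  }
  ent <- function(counts) {
    p <- counts[counts > 0] / n
    -sum(p * log(p))
  }
  hp <- ent(rowSums(tab)); ht <- ent(colSums(tab))
  if ((hp + ht) / 2 <= 0) return(0)
  mi / ((hp + ht) / 2)
}

# Random row-stochastic matrix (all entries positive).
randomStochastic <- function(n) {
  U <- matrix(stats::runif(n * n, 0.01, 1), n, n)
  U / rowSums(U)
}

# Random block-diagonal row-stochastic matrix; returns the matrix and
# the block label of each node.
randomBlockDiagonal <- function(sizes) {
  n <- sum(sizes)
  U <- matrix(0, n, n)
  labels <- rep(seq_along(sizes), times = sizes)
  at <- 1L
  for (s in sizes) {
    idx <- at:(at + s - 1L)
    U[idx, idx] <- randomStochastic(s)
    at <- at + s
  }
  list(U = U, labels = labels)
}
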