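test_that("Laplacian of the unified graph is PSD with zero row sums", {
  # 2-cycle: u_12 = u_21 = 1 -> eigenvalues {0, 2}
  U <- matrix(c(0, 1, 1, 0), 2, 2)
  L <- laplacianU(U)$L
  expect_equal(sort(eigen(L, symmetric = TRUE)$values), c(0, 2))

  set.seed(51)
  for (trial in 1:5) {
    Ur <- randomStochastic(12)
    Lr <- laplacianU(Ur)$L
    expect_equal(Lr, t(Lr))
    expect_equal(unname(rowSums(Lr)), rep(0, 12), tolerance = 1e-12)
    expect_gt(min(eigen(Lr, symmetric = TRUE)$values), -1e-10)
  }
})

test_that("embedding solves the Ky Fan trace minimization", {
  set.seed(52)
  # block-diagonal U with 2 components -> trace value 0 at c = 2
  bd <- randomBlockDiagonal(c(4, 5))
  L <- laplacianU(bd$U)$L
  emb <- updateEmbedding(L, 2)
  expect_lt(sum(diag(t(emb$F) %*% L %*% emb$F)), 1e-10)

  # orthonormal columns; trace equals sum of the c smallest eigenvalues
  Ur <- randomStochastic(15)
  Lr <- laplacianU(Ur)$L
  for (c in c(2, 4)) {
    e <- updateEmbedding(Lr, c)
    expect_lt(max(abs(t(e$F) %*% e$F - diag(c))), 1e-10)
    tr <- sum(diag(t(e$F) %*% Lr %*% e$F))
    eigs <- sort(eigen(Lr, symmetric = TRUE, only.values = TRUE)$values)
    expect_equal(tr, sum(eigs[seq_len(c)]), tolerance = 1e-10)
    expect_equal(e$values, eigs[seq_len(c)], tolerance = 1e-10)
  }
})

test_that("simplex projection matches oracles and is idempotent", {
  expect_equal(simplexProject(c(0.5, 0.3, 0.4)),
               c(13, 7, 10) / 30, tolerance = 1e-10)
  expect_equal(simplexProject(c(1.2, -0.1, 0.1)), c(1, 0, 0),
               tolerance = 1e-10)

  # already on the simplex -> unchanged
  p <- c(0.2, 0.5, 0.3)
  expect_equal(simplexProject(p), p, tolerance = 1e-12)

  set.seed(53)
  for (trial in 1:50) {
    p <- rnorm(sample(2:20, 1), sd = runif(1, 0.1, 10))
    u <- simplexProject(p)
    expect_gte(min(u), 0)
    expect_equal(sum(u), 1, tolerance = 1e-10)
    # sorting-based closed form
    expect_lt(max(abs(u - sortSimplexProject(p))), 1e-9)
  }
  # generic QP oracle: projection = argmin ||u - p||^2 on the simplex
  for (trial in 1:5) {
    p <- rnorm(8)
    oracle <- qpSimplexOracle(diag(2, 8), -2 * p)
    expect_lt(max(abs(simplexProject(p) - oracle)), 1e-6)
  }
  expect_error(simplexProject(c(1, NA)), "non-finite")
})

test_that("unified-graph update matches its closed form and the QP oracle", {
  set.seed(54)
  n <- 10; m <- 3
  x <- lapply(1:m, function(v) matrix(rnorm(n * 3), n, 3))
  dists <- lapply(x, pairwiseSqDist)
  graphs <- lapply(dists, function(D) initSimilarityGraph(D, 3)$S)
  w <- runif(m, 0.2, 1)
  F <- updateEmbedding(laplacianU(randomStochastic(n))$L, 3)$F
  lam <- 0.7
  U <- updateUnified(graphs, w, F, lam)
  expect_true(all(U >= 0))
  expect_equal(rowSums(U), rep(1, n), tolerance = 1e-8)

  Df <- pairwiseSqDist(F)
  for (i in seq_len(n)) {
    q <- Reduce(`+`, lapply(seq_len(m), function(v)
      graphs[[v]][i, ] - lam / (2 * m * w[v]) * Df[i, ])) / m
    # row minimizer of sum_v ||u - q^v||^2 = projection of mean(q^v),
    # checked against the generic QP
    oracle <- qpSimplexOracle(diag(2, n), -2 * q)
    expect_lt(max(abs(U[i, ] - oracle)), 1e-6)
  }

  # lambda -> 0 with all views identical: U recovers S^1
  same <- list(graphs[[1]], graphs[[1]])
  U0 <- updateUnified(same, c(1, 1), F, lam = 1e-14)
  expect_equal(U0, graphs[[1]], tolerance = 1e-8)
})

test_that("component counting agrees between traversal and spectrum", {
  U4 <- matrix(0, 4, 4)
  U4[1, 2] <- U4[2, 1] <- 1
  U4[3, 4] <- U4[4, 3] <- 1
  res <- countComponents(U4)
  expect_identical(res$count, 2L)
  expect_identical(res$eigenCount, 2L)
  expect_identical(res$labels, c(1L, 1L, 2L, 2L))

  set.seed(55)
  x <- matrix(rnorm(30 * 2), 30, 2)
  S <- initSimilarityGraph(pairwiseSqDist(x), 6)$S
  expect_identical(countComponents(S)$count, 1L)

  for (trial in 1:20) {
    sizes <- sample(2:6, sample(2:4, 1), replace = TRUE)
    bd <- randomBlockDiagonal(sizes)
    res <- countComponents(bd$U)
    expect_identical(res$count, length(sizes))
    expect_identical(res$eigenCount, length(sizes))
    expect_identical(unname(res$labels), bd$labels)
  }
})

test_that("lambda adaptation doubles, halves and flags convergence", {
  expect_equal(adaptLambda(1, z = 3, c = 3),
               list(lambda = 1, converged = TRUE, recompute = FALSE))
  expect_equal(adaptLambda(1, z = 0, c = 3)$lambda, 2)
  # two consecutive z = 0 steps quadruple lambda
  lam <- 1
  for (i in 1:2) lam <- adaptLambda(lam, z = 0, c = 3)$lambda
  expect_equal(lam, 4)
  half <- adaptLambda(8, z = 5, c = 3)
  expect_equal(half$lambda, 4)
  expect_true(half$recompute)
})

test_that("full run recovers well-separated synthetic clusters exactly", {
  sim <- generateSynthetic(nCells = 150, nGenes = 400, nClusters = 3,
                           effect = 8, dropout = 0.3, seed = 61,
                           markersPerCluster = 40)
  fit <- suppressWarnings(scMCGF(sim$expression, c = 3,
                                 geneSets = sim$geneSets))
  expect_s4_class(fit, "SCMCGFFit")
  expect_true(fit@converged)
  expect_identical(max(clusterLabels(fit)), 3L)
  expect_equal(ari(clusterLabels(fit), sim$labels), 1.0)
  # simplex invariants on the final state
  expect_equal(rowSums(unifiedGraph(fit)), rep(1, 150),
               tolerance = 1e-8, ignore_attr = TRUE)
  for (S in similarityGraphs(fit)) {
    expect_true(all(S >= -1e-12))
    expect_equal(rowSums(S), rep(1, 150), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  expect_lt(max(abs(t(fit@embedding) %*% fit@embedding - diag(3))), 1e-8)
  expect_gt(fit@lambda, 0)
})

test_that("single-view run degrades to single-view CLR and still converges", {
  sim <- generateSynthetic(nCells = 120, nGenes = 300, nClusters = 3,
                           effect = 8, dropout = 0.2, seed = 62,
                           markersPerCluster = 40)
  vs <- buildViews(sim$expression, include = "expression")
  fit <- suppressWarnings(runSCMCGF(vs, c = 3, k = 5))
  expect_identical(nViews(vs), 1L)
  expect_identical(countComponents(unifiedGraph(fit),
                                   checkEigen = FALSE)$count, 3L)
  expect_gt(ari(clusterLabels(fit), sim$labels), 0.95)
})

test_that("identical views keep equal weights at every iteration", {
  set.seed(63)
  x <- matrix(rnorm(10 * 60), 10, 60)
  x[, 31:60] <- x[, 31:60] + 6
  colnames(x) <- paste0("c", 1:60)
  vs <- ViewSet(list(a = x, b = x, c = x))
  fit <- suppressWarnings(runSCMCGF(vs, c = 2, k = 5))
  h <- convergenceHistory(fit)
  wcols <- grep("^w_", names(h))
  for (r in seq_len(nrow(h)))
    expect_lt(diff(range(as.numeric(h[r, wcols]))), 1e-8)
})

test_that("objective is non-increasing over a full update sweep", {
  set.seed(64)
  for (trial in 1:20) {
    n <- 30; m <- 3; k <- 5; cc <- 3
    views <- lapply(1:m, function(v) matrix(rnorm(5 * n), 5, n))
    dists <- lapply(views, function(X) pairwiseSqDist(t(X)))
    init <- lapply(dists, initSimilarityGraph, k = k)
    S0 <- lapply(init, `[[`, "S")
    g0 <- lapply(init, `[[`, "gamma")
    U0 <- randomStochastic(n)
    emb0 <- updateEmbedding(laplacianU(U0)$L, cc)
    w0 <- updateViewWeights(U0, S0)
    lam <- mean(unlist(g0))
    before <- fusionObjective(dists, S0, g0, w0, U0, emb0$F, lam)
    upd <- suppressWarnings(
      Map(function(D, wv) updateSimilarityGraph(D, U0, wv, k),
          dists, as.list(w0)))
    S1 <- lapply(upd, `[[`, "S")
    w1 <- updateViewWeights(U0, S1)
    U1 <- updateUnified(S1, w1, emb0$F, lam)
    emb1 <- updateEmbedding(laplacianU(U1)$L, cc)
    # evaluated with gamma and w frozen at their pre-sweep values, so the
    # same function is compared at the two states
    after <- fusionObjective(dists, S1, g0, w0, U1, emb1$F, lam)
    expect_lte(after, before + 1e-8 * abs(before))
  }
})

test_that("run aborts cleanly on invalid cluster or neighbor counts", {
  set.seed(65)
  x <- matrix(rnorm(4 * 20), 4, 20, dimnames = list(NULL, paste0("c", 1:20)))
  vs <- ViewSet(list(a = x))
  expect_error(runSCMCGF(vs, c = 1), "c >= 2")
  expect_error(runSCMCGF(vs, c = 2, k = 40), "k must be")
  expect_error(runSCMCGF(vs, c = 30), "more clusters")
})
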