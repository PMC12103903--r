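test_that("intrinsic dimension estimator recovers manifold dimension", {
  set.seed(21)
  # 200 points on a noiseless line embedded in 10-D
  t <- sort(runif(200))
  dir <- rnorm(10)
  line <- t(outer(t, dir))                     # 10 x 200
  expect_identical(estimateIntrinsicDim(line), 1L)

  # 500 points uniform in a 3-D cube embedded in 20-D
  cube <- matrix(runif(500 * 3), 500, 3)
  basis <- qr.Q(qr(matrix(rnorm(20 * 3), 20, 3)))
  emb <- basis %*% t(cube)                     # 20 x 500
  est <- estimateIntrinsicDim(emb)
  expect_true(abs(est - 3L) <= 1L)

  expect_error(estimateIntrinsicDim(line[, 1:10, drop = FALSE]),
               "at least")
  dup <- cbind(line[, 1:30], line[, 1:5])
  expect_warning(estimateIntrinsicDim(dup), "duplicate")
})

test_that("PCA view captures variance and preserves geometry", {
  set.seed(22)
  # variance along a single axis
  one <- matrix(0, 5, 40,
                dimnames = list(NULL, paste0("c", 1:40)))
  one[2, ] <- rnorm(40, sd = 3)
  p1 <- pcaView(one, 1)
  expect_equal(sum(apply(p1, 1, var)), var(one[2, ]))

  # full-rank projection is an isometry: pairwise distances preserved
  x <- matrix(rnorm(6 * 20), 6, 20, dimnames = list(NULL, paste0("c", 1:20)))
  full <- pcaView(x, 6)
  expect_equal(pairwiseSqDist(t(full)), pairwiseSqDist(t(x)),
               tolerance = 1e-10, ignore_attr = TRUE)

  # full-rank reconstruction error is 0 (orthonormal basis)
  xc <- x - rowMeans(x)
  sv <- svd(xc)
  recon <- sv$u %*% t(sv$u) %*% xc
  expect_equal(recon, xc)

  # deterministic under the sign convention
  expect_identical(pcaView(x, 3), pcaView(x, 3))
  expect_warning(pcaView(one, 4), "rank")
})

test_that("diffusion map has a stochastic spectrum and splits blobs", {
  set.seed(23)
  blob1 <- matrix(rnorm(5 * 20, mean = 0), 5, 20)
  blob2 <- matrix(rnorm(5 * 20, mean = 10), 5, 20)
  x <- cbind(blob1, blob2)
  colnames(x) <- paste0("c", 1:40)

  # transition-matrix spectrum lies in [-1, 1] with top eigenvalue 1
  d2 <- pairwiseSqDist(t(x))
  sigma <- median(sqrt(d2[upper.tri(d2)]))
  K <- exp(-d2 / (2 * sigma^2))
  P <- K / rowSums(K)
  ev <- eigen(P)$values
  expect_true(all(abs(Re(ev)) <= 1 + 1e-10))
  expect_equal(max(Re(ev)), 1)

  # first nontrivial coordinate separates the blobs with opposite signs
  dm <- diffusionMapView(x, 2)
  side <- sign(dm[1, ])
  expect_true(all(side[1:20] == side[1]))
  expect_true(all(side[21:40] == -side[1]))

  # doubling t rescales each coordinate by its eigenvalue exactly
  dm1 <- diffusionMapView(x, 3, t = 1)
  dm2 <- diffusionMapView(x, 3, t = 2)
  ratio <- dm2 / dm1
  for (l in 1:3)
    expect_lt(diff(range(ratio[l, ])), 1e-8)

  same <- matrix(1, 3, 10, dimnames = list(NULL, paste0("c", 1:10)))
  expect_error(diffusionMapView(same, 1), "degenerate|coincide")
})

test_that("AUCell scores hit the closed-form extremes", {
  set.seed(24)
  G <- 200; n <- 3
  x <- matrix(runif(G * n), G, n,
              dimnames = list(sprintf("g%03d", 1:G), paste0("c", 1:n)))
  L <- ceiling(0.05 * G)                      # = 10
  topGenes <- rownames(x)[order(-x[, 1], seq_len(G))[1:L]]
  bottomGenes <- rownames(x)[order(x[, 1])[1:L]]
  gs <- PathwayCollection(list(top = topGenes, bottom = bottomGenes))
  sc <- aucellView(x, gs, topFrac = 0.05)
  expect_equal(unname(sc["top", "c1"]), 1)
  expect_equal(unname(sc["bottom", "c1"]), 0)
  expect_true(all(sc >= 0 & sc <= 1))
})

test_that("AUCell null matches the uniform-ranking expectation", {
  set.seed(25)
  G <- 200; n <- 1500; M <- 40
  x <- matrix(runif(G * n), G, n,
              dimnames = list(sprintf("g%03d", 1:G), paste0("c", 1:n)))
  gs <- PathwayCollection(list(rand = sample(rownames(x), M)))
  sc <- aucellView(x, gs, topFrac = 0.05)
  # with set size M >= L, E[score] = M / G under uniform ranking;
  # the tolerance is ~4 standard errors of the Monte-Carlo mean
  expect_lt(abs(mean(sc) - M / G), 0.015)
})

test_that("AUCell warns on zero-overlap sets and drops missing genes", {
  x <- matrix(1:20, 10, 2,
              dimnames = list(paste0("g", 1:10), c("c1", "c2")))
  gs <- PathwayCollection(list(gone = c("nope1", "nope2"),
                               part = c("g1", "nope3")))
  expect_warning(sc <- aucellView(x, gs, topFrac = 0.2), "gone")
  expect_equal(unname(sc["gone", ]), c(0, 0))
  expect_true(all(sc["part", ] >= 0))
})

test_that("buildViews assembles aligned views in fixed order", {
  sim <- generateSynthetic(nCells = 80, nGenes = 250, nClusters = 2,
                           effect = 6, dropout = 0.2, seed = 31,
                           markersPerCluster = 30)
  vs <- buildViews(sim$expression, geneSets = sim$geneSets)
  expect_s4_class(vs, "ViewSet")
  expect_identical(nViews(vs), 4L)
  expect_identical(viewNames(vs), c("expression", "pathway", "pca", "dm"))
  expect_identical(nCells(vs), 80L)
  for (nm in viewNames(vs))
    expect_true(all(is.finite(getView(vs, nm))))
  expect_true(all(getView(vs, "pathway") >= 0 &
                  getView(vs, "pathway") <= 1))

  # single-view and ablation subsets
  v1 <- buildViews(sim$expression, include = "expression")
  expect_identical(nViews(v1), 1L)
  noPathway <- buildViews(sim$expression,
                          include = c("expression", "pca", "dm"))
  expect_identical(viewNames(noPathway), c("expression", "pca", "dm"))
  expect_error(buildViews(sim$expression, include = "pathway"),
               "gene-set")
})
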