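# Brute-force reference: explicit double loop over atom pairs.
bruteKernel <- function(A, B, zeta, mode) {
  s <- 0
  for (a in seq_len(nrow(A))) for (b in seq_len(nrow(B)))
    s <- s + atomicKernel(A[a, ], B[b, ], zeta)
  if (mode == "intensive") s / (nrow(A) * nrow(B)) else s
}

test_that("atomic kernel is a normalized dot product raised to zeta", {
  x <- c(0.3, 1.2, 0)
  expect_equal(atomicKernel(x, x, 2), 1)
  expect_equal(atomicKernel(c(1, 0), c(0, 1), 2), 0)
  expect_equal(atomicKernel(c(1, 0), c(1, 1), 2), 0.5)
  expect_error(atomicKernel(c(1, 0), c(1, 0, 0), 2), "length")
  expect_error(atomicKernel(c(0, 0), c(1, 0), 2), "zero")
})

test_that("molecular kernels match the brute-force double loop", {
  molSet <- testMolecules(5)
  desc <- computeDescriptors(molSet)
  for (i in 1:4) for (j in (i + 1):5) {
    A <- desc@descriptors[[i]]; B <- desc@descriptors[[j]]
    expect_equal(intensiveKernel(A, B, 2), bruteKernel(A, B, 2, "intensive"),
                 tolerance = 1e-12)
    expect_equal(extensiveKernel(A, B, 2), bruteKernel(A, B, 2, "extensive"),
                 tolerance = 1e-12)
    # symmetry and the N_A N_B identity linking the two kernels
    expect_equal(intensiveKernel(A, B, 2), intensiveKernel(B, A, 2),
                 tolerance = 1e-12)
    expect_equal(extensiveKernel(A, B, 2),
                 nrow(A) * nrow(B) * intensiveKernel(A, B, 2),
                 tolerance = 1e-10)
  }
})

test_that("identical-environment self kernels hit their degenerate limits", {
  # H2: both atoms share one environment -> K_int = 1, K_ext = N^2
  m <- Molecule("h2", c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)))
  desc <- computeDescriptors(MoleculeSet(list(m)))
  A <- desc@descriptors[[1]]
  expect_equal(intensiveKernel(A, A, 2), 1, tolerance = 1e-12)
  expect_equal(extensiveKernel(A, A, 2), 4, tolerance = 1e-12)
})

test_that("kernel matrices are PSD, symmetric and block-size independent", {
  desc <- cachedDescriptors(2)
  for (mode in c("intensive", "extensive")) {
    K <- molecularKernel(desc, mode)
    m <- kernelMatrix(K)
    expect_lt(max(abs(m - t(m))), 1e-10)
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(ev))
    for (bs in c(3L, 7L, 1000L)) {
      Kb <- molecularKernel(desc, mode, blockSize = bs)
      expect_equal(kernelMatrix(Kb), m, tolerance = 1e-12)
    }
  }
  expect_equal(unname(diag(kernelMatrix(molecularKernel(desc, "intensive")))),
               rep(1, length(desc@descriptors)))
})

test_that("intensive normalization rescales to unit diagonal and keeps PSD", {
  expect_equal(normalizeIntensive(matrix(c(4, 2, 2, 1), 2)),
               matrix(1, 2, 2))
  set.seed(11)
  X <- matrix(rnorm(60), 10)
  K <- tcrossprod(X) + diag(0.1, 10)
  Kn <- normalizeIntensive(K)
  expect_equal(unname(diag(Kn)), rep(1, 10))
  ev <- eigen(Kn, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10 * max(ev))
  expect_error(normalizeIntensive(matrix(c(0, 0, 0, 1), 2)), "diagonal")
  # already-normalized kernel is unchanged
  expect_equal(normalizeIntensive(Kn), Kn, tolerance = 1e-12)
})

test_that("kernel distance obeys its closed forms and the triangle inequality", {
  desc <- cachedDescriptors(3)
  sub <- desc@descriptors[seq_len(20)]
  K <- molecularKernel(new("DescriptorSet", descriptors = sub,
                           params = desc@params), "intensive")
  ids <- rownames(kernelMatrix(K))
  expect_equal(kernelDistance(K, ids[1], ids[1]), 0)
  D <- kernelDistance(K)
  expect_lte(max(D), sqrt(2) + 1e-12)   # normalized intensive bound
  for (i in 1:20) for (j in 1:20) for (k in 1:20)
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-10)
  # arithmetic example: unit diagonal with K_AB = 0.5 -> D = 1
  K2 <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  expect_equal(kernelDistance(K2, "a", "b"), 1)
})

test_that("extensive distances between large molecules exceed small-molecule
          distances at matched normalized similarity", {
  # two environments e1, e2 with fixed overlap; molecules of n copies
  e1 <- c(1, 0, 0); e2 <- c(sqrt(0.5), sqrt(0.5), 0)
  mk <- function(v, n) matrix(rep(v, each = n), nrow = n)
  zeta <- 2
  dSmall <- sqrt(extensiveKernel(mk(e1, 2), mk(e1, 2), zeta) +
                 extensiveKernel(mk(e2, 2), mk(e2, 2), zeta) -
                 2 * extensiveKernel(mk(e1, 2), mk(e2, 2), zeta))
  dLarge <- sqrt(extensiveKernel(mk(e1, 8), mk(e1, 8), zeta) +
                 extensiveKernel(mk(e2, 8), mk(e2, 8), zeta) -
                 2 * extensiveKernel(mk(e1, 8), mk(e2, 8), zeta))
  expect_gt(dLarge, dSmall)
})

test_that("kernel PCA reproduces classical PCA under a linear kernel", {
  set.seed(7)
  X <- matrix(rnorm(15 * 4), 15)
  K <- tcrossprod(X)
  rownames(K) <- colnames(K) <- sprintf("m%02d", seq_len(15))
  proj <- kernelPCA(K, nComponents = 3)
  ref <- prcomp(X, center = TRUE, scale. = FALSE)
  for (j in 1:3) {
    r <- ref$x[, j]
    s <- proj$scores[, j]
    expect_equal(abs(sum(r * s)) / (sqrt(sum(r^2)) * sqrt(sum(s^2))), 1,
                 tolerance = 1e-8)
    expect_equal(sd(s), sd(r), tolerance = 1e-8)
  }
})

test_that("kernel PCA handles duplicates, rank limits and sign convention", {
  set.seed(3)
  X <- matrix(rnorm(8 * 3), 8)
  X[8, ] <- X[1, ]   # duplicate molecule
  K <- tcrossprod(X)
  rownames(K) <- colnames(K) <- letters[1:8]
  proj <- kernelPCA(K, nComponents = 2)
  expect_equal(proj$scores["a", ], proj$scores["h", ], tolerance = 1e-8)
  # deterministic sign: largest-magnitude entry positive
  for (j in 1:2)
    expect_gt(proj$scores[which.max(abs(proj$scores[, j])), j], 0)
  # rank-1 kernel explains all variance with one component
  v <- rnorm(6)
  K1 <- outer(v, v)
  rownames(K1) <- colnames(K1) <- letters[1:6]
  p1 <- kernelPCA(K1, 1)
  expect_equal(p1$varianceExplained[1], 1, tolerance = 1e-10)
  expect_error(kernelPCA(K1, 5), "positive eigenvalues")
})

test_that("kernel persistence restores matrix and metadata", {
  desc <- cachedDescriptors(2)
  K <- molecularKernel(desc, "extensive")
  path <- withr::local_tempfile(fileext = ".csv")
  writeKernel(K, path)
  K2 <- readKernel(path)
  expect_equal(kernelMatrix(K2), kernelMatrix(K), tolerance = 1e-10)
  expect_identical(kernelMode(K2), "extensive")
  expect_identical(K2@normalized, FALSE)
  expect_equal(K2@zeta, K@zeta)
})
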