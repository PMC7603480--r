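# Exhaustive greedy FPS reference sharing the production tie rule.
bruteFPS <- function(K, n, startIdx) {
  m <- if (is(K, "MolecularKernel")) kernelMatrix(K) else K
  ids <- rownames(m)
  D <- kernelDistance(K)
  sel <- startIdx
  while (length(sel) < n) {
    rest <- setdiff(seq_along(ids), sel)
    minD <- vapply(rest, function(c) min(D[c, sel]), numeric(1))
    best <- rest[minD >= max(minD) - 1e-15 * max(abs(max(minD)), 1)]
    sel <- c(sel, best[order(ids[best])][1])
  }
  ids[sel]
}

test_that("FPS reproduces the greedy max-min sequence on collinear points", {
  x <- c(a = 0, b = 1, c = 10)
  K <- outer(x, x)            # linear kernel: D(i,j) = |x_i - x_j|
  dimnames(K) <- list(names(x), names(x))
  sel <- fpsSelect(K, 3, startRule = "fixed_id", fixedId = "a")
  expect_identical(as.character(sel), c("a", "c", "b"))
})

test_that("FPS agrees with the exhaustive greedy oracle in both modes", {
  desc <- cachedDescriptors(3)
  sub <- new("DescriptorSet", descriptors = desc@descriptors[seq_len(12)],
             params = desc@params)
  for (mode in c("intensive", "extensive")) {
    K <- molecularKernel(sub, mode)
    sel <- fpsSelect(K, 12)
    start <- which(rownames(kernelMatrix(K)) == sel[1])
    expect_identical(as.character(sel), bruteFPS(K, 12, start))
    # selecting everything yields a permutation
    expect_setequal(as.character(sel), rownames(kernelMatrix(K)))
  }
})

test_that("extensive FPS favours large molecules early, intensive does not", {
  fx <- cachedFixture(3)
  desc <- cachedDescriptors(3)
  nAt <- vapply(fx$graphs, nAtoms, integer(1))
  selE <- fpsSelect(molecularKernel(desc, "extensive"), 10)
  selI <- fpsSelect(molecularKernel(desc, "intensive"), 10)
  expect_gt(mean(nAt[as.character(selE)]), mean(nAt))
  expect_lt(mean(nAt[as.character(selI)]), mean(nAt[as.character(selE)]))
})

test_that("random selection is seeded, uniform and bounded", {
  ids <- sprintf("m%02d", 1:20)
  expect_identical(as.character(randomSelect(ids, 5, seed = 3)),
                   as.character(randomSelect(ids, 5, seed = 3)))
  expect_setequal(as.character(randomSelect(ids, 20, seed = 1)), ids)
  expect_error(randomSelect(ids, 21, seed = 1), "exceeds")
  # frequency of each id over many single draws: binomial 4-sigma band
  draws <- table(vapply(seq_len(10000), function(s)
    as.character(randomSelect(ids[1:5], 1, seed = s)), character(1)))
  p <- 1 / 5
  band <- 4 * sqrt(10000 * p * (1 - p))
  expect_true(all(abs(draws - 10000 * p) < band))
})

test_that("KRR dual solve matches the explicit inverse and interpolates", {
  y <- c(3, -1, 2)
  expect_equal(krrFit(diag(3), y, 0), y)
  set.seed(5)
  X <- matrix(rnorm(100), 10)
  K <- tcrossprod(X) + diag(0.5, 10)
  yy <- rnorm(10)
  lam <- 1e-3
  expect_equal(krrFit(K, yy, lam),
               as.numeric(solve(K + diag(lam, 10)) %*% yy),
               tolerance = 1e-10)
  # interpolation limit on a full-rank kernel
  alpha <- krrFit(K, yy, 1e-12)
  expect_lt(max(abs(K %*% alpha - yy)), 1e-6)
})

test_that("predictions recover training data and rescale per-atom targets", {
  fx <- cachedFixture(2)
  molSet <- molecules(fx$network)
  desc <- cachedDescriptors(2)
  ids <- moleculeIds(molSet)
  for (mode in c("intensive", "extensive")) {
    model <- trainKRR(molSet, desc, ids, lambda = 1e-10, kernelMode = mode)
    pred <- predictAE(model, desc)
    ae <- vapply(ids, function(id) molSet[[id]]@eAt, numeric(1))
    expect_lt(evaluateMAE(pred, ae), 1e-5)
  }
  # intensive model predicting AE/N = -2 for a 5-atom molecule gives -10
  ch4 <- molSet[["CH4"]]
  ch4@eAt <- -10
  single <- MoleculeSet(list(ch4))
  sdesc <- computeDescriptors(single, desc@params)
  m1 <- trainKRR(single, sdesc, "CH4", lambda = 1e-14, "intensive")
  expect_equal(m1@alpha, -2, tolerance = 1e-10)   # trained on AE/N
  expect_equal(unname(predictAE(m1, sdesc)), -10, tolerance = 1e-8)
})

test_that("MAE is computed on total AE with id alignment", {
  expect_equal(evaluateMAE(c(a = 1, b = 2), c(b = 2, a = 1)), 0)
  expect_equal(evaluateMAE(c(a = 1.1, b = 2.1), c(a = 1, b = 2)), 0.1,
               tolerance = 1e-12)
  expect_equal(evaluateMAE(c(a = -17.3, b = -4.4, c = -9.0),
                           c(a = -17.2, b = -4.5, c = -8.7)),
               mean(c(0.1, 0.1, 0.3)), tolerance = 1e-12)
  expect_error(evaluateMAE(c(a = 1), c(b = 1)), "align")
})

test_that("hyperparameter grid search picks by validation MAE with tie rules", {
  fx <- cachedFixture(2)
  molSet <- molecules(fx$network)
  desc <- cachedDescriptors(2)
  ids <- moleculeIds(molSet)
  train <- ids[seq(1, length(ids), by = 2)]
  val <- setdiff(ids, train)
  one <- selectHyperparameters(molSet, desc, train, val,
                               lambdaGrid = 1e-6, zetaGrid = 2)
  expect_equal(one$lambda, 1e-6)
  expect_equal(one$zeta, 2)
  # in-sample validation prefers the interpolating lambda
  insample <- suppressWarnings(
    selectHyperparameters(molSet, desc, train, train,
                          lambdaGrid = c(1e-12, 1e3), zetaGrid = 2))
  expect_equal(insample$lambda, 1e-12)
  expect_error(selectHyperparameters(molSet, desc, train, val,
                                     lambdaGrid = numeric(0)), "empty")
})

test_that("label noise drives the selected regularization upward", {
  # kernel-realizable labels: y = K w is fit exactly at tiny lambda, so
  # the noiseless grid search picks the smallest lambda; injected label
  # noise makes it back off to a larger one
  fx <- cachedFixture(3)
  desc <- cachedDescriptors(3)
  ids <- moleculeIds(molecules(fx$network))
  K <- kernelMatrix(molecularKernel(desc, "extensive"))
  set.seed(21)
  y <- as.numeric(K %*% rnorm(length(ids), sd = 0.05))
  withLabels <- function(labels) {
    MoleculeSet(lapply(ids, function(id) {
      m <- molecules(fx$network)[[id]]
      m@eAt <- labels[[match(id, ids)]]
      m
    }))
  }
  train <- as.character(randomSelect(ids, 150, seed = 2))
  val <- setdiff(ids, train)
  grid <- 10^seq(-10, -1, length.out = 10)
  pick0 <- selectHyperparameters(withLabels(y), desc, train, val,
                                 lambdaGrid = grid, kernelMode = "extensive")
  pickN <- selectHyperparameters(withLabels(y + rnorm(length(y), sd = 0.5)),
                                 desc, train, val,
                                 lambdaGrid = grid, kernelMode = "extensive")
  expect_gt(pickN$lambda, pick0$lambda)
})

test_that("learning curves improve with training size on noiseless data", {
  fx <- cachedFixture(3)
  molSet <- molecules(fx$network)
  desc <- cachedDescriptors(3)
  ids <- moleculeIds(molSet)
  # pooled log-log regression over 5 random test splits: negative slope
  # at > 3 sigma, and end-to-end improvement for each split
  rows <- list()
  for (s in 1:5) {
    test <- as.character(randomSelect(ids, 40, seed = 10 + s))
    curve <- learningCurve(molSet, desc, "fps_intensive", "intensive",
                           sizes = c(25, 50, 100, 160), testIds = test,
                           lambda = 1e-2)
    expect_equal(nrow(curve), 4L)
    expect_lt(curve$mae_ae[4], curve$mae_ae[1])
    rows[[s]] <- curve
  }
  all <- do.call(rbind, rows)
  fit <- summary(lm(log(mae_ae) ~ log(n_train), all))$coefficients
  expect_lt(fit["log(n_train)", "Estimate"] +
              3 * fit["log(n_train)", "Std. Error"], 0)
  # FPS prefix property: the size-m model uses the first m picks
  test <- as.character(randomSelect(ids, 40, seed = 11))
  curve <- learningCurve(molSet, desc, "fps_intensive", "intensive",
                         sizes = c(25, 50), testIds = test)
  sel <- attr(curve, "selection")
  K <- molecularKernel(new("DescriptorSet",
                           descriptors = desc@descriptors[setdiff(ids, test)],
                           params = desc@params), "intensive")
  expect_identical(sel[1:25], as.character(fpsSelect(K, 25)))
  expect_error(learningCurve(molSet, desc, "random", "intensive",
                             sizes = 10, testIds = test, poolIds = ids),
               "overlap")
})

test_that("training-target asymmetry: total-AE fits favour large molecules", {
  # same kernel, different target: fitting the total AE weights large
  # molecules (more room for improvement), fitting AE/N weights all
  # molecules equally
  fx <- cachedFixture(3)
  molSet <- molecules(fx$network)
  desc <- cachedDescriptors(3)
  nAt <- vapply(fx$graphs, nAtoms, integer(1))
  ids <- moleculeIds(molSet)
  large <- names(nAt)[nAt >= stats::quantile(nAt, 0.8)]
  train <- as.character(randomSelect(ids, 120, seed = 4))
  testIds <- setdiff(ids, train)
  testDesc <- new("DescriptorSet", descriptors = desc@descriptors[testIds],
                  params = desc@params)
  ae <- vapply(testIds, function(id) molSet[[id]]@eAt, numeric(1))
  n <- vapply(testIds, function(id) nAtoms(molSet[[id]]), numeric(1))
  # extensive kernel: the total-AE target wins on large molecules
  mTot <- trainKRR(molSet, desc, train, 1e-8, "extensive",
                   targetMode = "AE")
  mPer <- trainKRR(molSet, desc, train, 1e-8, "extensive",
                   targetMode = "AE_per_atom")
  pTot <- predictAE(mTot, testDesc); pPer <- predictAE(mPer, testDesc)
  largeTest <- intersect(testIds, large)
  expect_lt(evaluateMAE(pTot[largeTest], ae[largeTest]),
            evaluateMAE(pPer[largeTest], ae[largeTest]))
  # intensive kernel: the per-atom target wins on the per-atom error
  iTot <- predictAE(trainKRR(molSet, desc, train, 1e-8, "intensive",
                             targetMode = "AE"), testDesc)
  iPer <- predictAE(trainKRR(molSet, desc, train, 1e-8, "intensive",
                             targetMode = "AE_per_atom"), testDesc)
  expect_lt(mean(abs(iPer - ae) / n), mean(abs(iTot - ae) / n))
})

test_that("model archives restore bit-exact predictors", {
  fx <- cachedFixture(2)
  molSet <- molecules(fx$network)
  desc <- cachedDescriptors(2)
  model <- trainKRR(molSet, desc, moleculeIds(molSet)[1:10], 1e-6,
                    "intensive")
  path <- withr::local_tempfile(fileext = ".rds")
  saveModel(model, path)
  model2 <- loadModel(path)
  expect_identical(predictAE(model2, desc), predictAE(model, desc))
  expect_error(loadModel(withr::local_tempfile(lines = "x")), ".")
})
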