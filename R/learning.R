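#' @include AllClasses.R kernels.R
NULL

#' Farthest-point sampling under a kernel distance
#'
#' Greedy max-min selection: each new molecule maximizes its minimal
#' kernel distance D(A,B) = sqrt(K(A,A) + K(B,B) - 2K(A,B)) to all
#' previously selected molecules. With the (unnormalized) extensive
#' kernel, self-similarities scale like N^2, so early picks are biased
#' towards large molecules; the normalized intensive kernel selects for
#' chemical diversity irrespective of size.
#'
#' @param K a \linkS4class{MolecularKernel} (or square kernel matrix
#'   with id dimnames).
#' @param n number of molecules to select (<= dataset size).
#' @param startRule \code{"auto"} (max self-kernel for extensive,
#'   lowest id otherwise), \code{"max_self_kernel"}, \code{"lowest_id"}
#'   or \code{"fixed_id"}.
#' @param fixedId starting id when \code{startRule = "fixed_id"}.
#' @return character vector of selected ids in greedy order, with
#'   attributes \code{mode} and \code{startRule}. Ties in the max-min
#'   distance (and in the start rule) are broken by the
#'   lexicographically smallest id.
#' @export
fpsSelect <- function(K, n, startRule = c("auto", "max_self_kernel",
                                          "lowest_id", "fixed_id"),
                      fixedId = NULL) {
  startRule <- match.arg(startRule)
  mode <- if (is(K, "MolecularKernel")) K@mode else "unknown"
  m <- if (is(K, "MolecularKernel")) K@matrix else K
  ids <- rownames(m)
  N <- length(ids)
  if (n > N) stop(sprintf("cannot select %d from %d molecules", n, N))
  if (startRule == "auto")
    startRule <- if (mode == "extensive") "max_self_kernel" else "lowest_id"
  d <- diag(m)
  pickMin <- function(cand) cand[order(ids[cand])][1L]
  start <- switch(startRule,
    max_self_kernel = pickMin(which(d == max(d))),
    lowest_id = which(ids == sort(ids)[1L]),
    fixed_id = {
      if (is.null(fixedId) || !fixedId %in% ids)
        stop("fixed_id start rule needs a valid 'fixedId'")
      which(ids == fixedId)
    })
  selected <- integer(n)
  selected[1L] <- start
  # squared distance to the current selection, maintained incrementally
  minD2 <- d + d[start] - 2 * m[, start]
  minD2[start] <- -Inf
  if (n > 1L) for (k in 2:n) {
    mx <- max(minD2)
    nxt <- pickMin(which(minD2 >= mx - 1e-15 * max(abs(mx), 1)))
    selected[k] <- nxt
    cand <- d + d[nxt] - 2 * m[, nxt]
    minD2 <- pmin(minD2, cand)
    minD2[nxt] <- -Inf
  }
  structure(ids[selected], mode = mode, startRule = startRule)
}

#' Uniform random training-set selection
#'
#' @param ids candidate molecule ids.
#' @param n number to draw without replacement.
#' @param seed RNG seed; the draw is reproducible and does not disturb
#'   the caller's RNG state.
#' @return character vector of selected ids, attribute \code{seed}.
#' @export
randomSelect <- function(ids, n, seed) {
  if (n > length(ids)) stop("n exceeds the number of candidates")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  structure(sample(ids, n), seed = seed)
}

#' Solve the kernel ridge regression dual system
#'
#' alpha = (K + lambda I)^-1 y via a symmetric (Cholesky) solver, with a
#' residual check; lambda = 0 on a rank-deficient kernel is an error.
#'
#' @param K square symmetric PSD training kernel (matrix or
#'   \linkS4class{MolecularKernel}).
#' @param y training targets.
#' @param lambda regularization parameter.
#' @return numeric dual coefficient vector alpha.
#' @export
krrFit <- function(K, y, lambda) {
  m <- if (is(K, "MolecularKernel")) K@matrix else K
  if (!all(is.finite(y))) stop("training targets must be finite")
  A <- m + diag(lambda, nrow(m))
  ch <- tryCatch(chol(A), error = function(e) NULL)
  alpha <- if (!is.null(ch)) backsolve(ch, forwardsolve(t(ch), y))
  else tryCatch(solve(A, y),
                error = function(e) stop("singular KRR system: ",
                                         conditionMessage(e)))
  res <- max(abs(A %*% alpha - y))
  if (res > 1e-8 * max(abs(y), 1))
    warning(sprintf("KRR residual %.3g exceeds tolerance", res))
  as.numeric(alpha)
}

#' Train a KRR atomization-energy model
#'
#' Intensive-kernel models are trained on the atomization energy per
#' atom (the intensive target); extensive-kernel models on the total
#' atomization energy. Targets are taken from the molecules'
#' \code{eAt} slots.
#'
#' @param molSet \linkS4class{MoleculeSet} with atomization energies.
#' @param descSet matching \linkS4class{DescriptorSet}.
#' @param trainIds molecule ids to train on.
#' @param lambda regularization parameter.
#' @param kernelMode \code{"intensive"} or \code{"extensive"}.
#' @param targetMode training target; default \code{"AE_per_atom"} for
#'   intensive, \code{"AE"} for extensive.
#' @param zeta atomic-kernel exponent (default from descriptor params).
#' @return a \linkS4class{KRRModel}.
#' @export
trainKRR <- function(molSet, descSet, trainIds, lambda = 1e-8,
                     kernelMode = c("intensive", "extensive"),
                     targetMode = NULL, zeta = NULL) {
  kernelMode <- match.arg(kernelMode)
  if (is.null(targetMode))
    targetMode <- if (kernelMode == "intensive") "AE_per_atom" else "AE"
  if (is.null(zeta)) zeta <- descSet@params@zeta
  missing <- setdiff(trainIds, names(descSet@descriptors))
  if (length(missing))
    stop(sprintf("no descriptors for: %s", paste(missing, collapse = ", ")))
  trainDesc <- new("DescriptorSet",
                   descriptors = descSet@descriptors[trainIds],
                   params = descSet@params)
  ae <- vapply(trainIds, function(id) molSet@molecules[[id]]@eAt, numeric(1))
  if (any(is.na(ae))) stop("training molecules must carry atomization energies")
  n <- vapply(trainDesc@descriptors, nrow, integer(1))
  y <- if (targetMode == "AE_per_atom") ae / n else ae
  K <- molecularKernel(trainDesc, mode = kernelMode, zeta = zeta)
  alpha <- krrFit(K, y, lambda)
  new("KRRModel", trainIds = trainIds, alpha = alpha, lambda = lambda,
      kernelMode = kernelMode, targetMode = targetMode, zeta = zeta,
      normalized = K@normalized, trainDescriptors = trainDesc)
}

# Cross kernel (rows = test molecules, cols = training molecules) in the
# model's mode and normalization convention.
.crossKernel <- function(descTest, model, blockSize = 200L) {
  dT <- descTest@descriptors
  dS <- model@trainDescriptors@descriptors
  K <- .pairSumMatrix(dT, dS, model@zeta, blockSize)
  if (model@kernelMode == "intensive") {
    nT <- vapply(dT, nrow, integer(1))
    nS <- vapply(dS, nrow, integer(1))
    K <- K / outer(nT, nS)
    if (model@normalized) {
      selfInt <- function(lst) vapply(lst, function(X)
        intensiveKernel(X, X, model@zeta), numeric(1))
      K <- K / outer(sqrt(selfInt(dT)), sqrt(selfInt(dS)))
    }
  }
  dimnames(K) <- list(names(dT), names(dS))
  K
}

#' Predict atomization energies with a KRR model
#'
#' Raw dual prediction K_test,train alpha; models trained on AE/N are
#' rescaled by each test molecule's atom count so the return value is
#' always the total atomization energy in eV.
#'
#' @param model a \linkS4class{KRRModel}.
#' @param descSet \linkS4class{DescriptorSet} of the molecules to
#'   predict (must share parameters with the model).
#' @return named numeric vector of predicted AEs, eV.
#' @export
predictAE <- function(model, descSet) {
  pT <- descSet@params; pM <- model@trainDescriptors@params
  if (!isTRUE(all.equal(c(pT@rCut, pT@sigmaR, pT@nBins),
                        c(pM@rCut, pM@sigmaR, pM@nBins))) ||
      !identical(pT@elements, pM@elements))
    stop("descriptor parameters do not match the model")
  K <- .crossKernel(descSet, model)
  raw <- as.numeric(K %*% model@alpha)
  if (model@targetMode == "AE_per_atom")
    raw <- raw * vapply(descSet@descriptors, nrow, integer(1))
  stats::setNames(raw, names(descSet@descriptors))
}

#' Mean absolute error over total atomization energies
#'
#' Errors are always reported on the total AE (eV), regardless of the
#' training target, so intensive and extensive models are comparable.
#'
#' @param predictions,references named numeric vectors; matched by name.
#' @return mean absolute error, eV.
#' @export
evaluateMAE <- function(predictions, references) {
  if (!is.null(names(predictions)) && !is.null(names(references))) {
    common <- intersect(names(predictions), names(references))
    if (length(common) != length(predictions))
      stop("prediction/reference ids do not align")
    predictions <- predictions[common]
    references <- references[common]
  }
  mean(abs(predictions - references))
}

#' Grid search for regularization and kernel exponent
#'
#' Minimizes validation MAE of the model's native target (AE/N for
#' intensive, AE for extensive) over a lambda x zeta grid; ties are
#' broken towards smaller lambda.
#'
#' @param molSet,descSet data and descriptors.
#' @param trainIds,valIds disjoint training and validation ids.
#' @param lambdaGrid candidate regularization values (default 9 points,
#'   log-spaced 1e-10 .. 1e-2).
#' @param zetaGrid candidate kernel exponents.
#' @param kernelMode \code{"intensive"} or \code{"extensive"}.
#' @return list with \code{lambda}, \code{zeta} and the full \code{grid}
#'   data.frame of validation MAEs.
#' @export
selectHyperparameters <- function(molSet, descSet, trainIds, valIds,
                                  lambdaGrid = 10^seq(-10, -2, length.out = 9),
                                  zetaGrid = 2,
                                  kernelMode = c("intensive", "extensive")) {
  kernelMode <- match.arg(kernelMode)
  if (!length(lambdaGrid) || !length(zetaGrid)) stop("empty hyperparameter grid")
  if (length(intersect(trainIds, valIds)))
    warning("training and validation sets overlap; selection is in-sample")
  valDesc <- new("DescriptorSet", descriptors = descSet@descriptors[valIds],
                 params = descSet@params)
  nVal <- vapply(valDesc@descriptors, nrow, integer(1))
  aeVal <- vapply(valIds, function(id) molSet@molecules[[id]]@eAt, numeric(1))
  rows <- list()
  best <- list(mae = Inf, lambda = NA_real_, zeta = NA_real_)
  for (z in zetaGrid) {
    for (lam in sort(lambdaGrid)) {
      model <- trainKRR(molSet, descSet, trainIds, lambda = lam,
                        kernelMode = kernelMode, zeta = z)
      pred <- predictAE(model, valDesc)
      mae <- if (model@targetMode == "AE_per_atom")
        mean(abs(pred / nVal - aeVal / nVal)) else mean(abs(pred - aeVal))
      rows[[length(rows) + 1L]] <-
        data.frame(lambda = lam, zeta = z, val_mae = mae)
      if (mae < best$mae) best <- list(mae = mae, lambda = lam, zeta = z)
    }
  }
  list(lambda = best$lambda, zeta = best$zeta, grid = do.call(rbind, rows))
}

#' Learning curve of a selection/kernel combination
#'
#' Trains models of increasing size on nested prefixes of one selection
#' sequence (greedy FPS order, or one random permutation) and reports
#' the test-set MAE on total atomization energies per size.
#'
#' @param molSet,descSet data and descriptors.
#' @param selectionMode \code{"fps_intensive"}, \code{"fps_extensive"}
#'   or \code{"random"}.
#' @param kernelMode kernel used for the regression (independent of the
#'   selection mode).
#' @param sizes ascending training-set sizes.
#' @param testIds held-out test ids (disjoint from \code{poolIds}).
#' @param poolIds candidate pool for selection; default all molecules
#'   except \code{testIds}.
#' @param lambda regularization parameter.
#' @param zeta atomic-kernel exponent.
#' @param seed RNG seed (random selection only).
#' @return data.frame with columns \code{n_train} and \code{mae_ae}, and
#'   the full selection order as attribute \code{selection}.
#' @export
learningCurve <- function(molSet, descSet,
                          selectionMode = c("fps_intensive", "fps_extensive",
                                            "random"),
                          kernelMode = c("intensive", "extensive"),
                          sizes, testIds, poolIds = NULL,
                          lambda = 1e-8, zeta = NULL, seed = 1L) {
  selectionMode <- match.arg(selectionMode)
  kernelMode <- match.arg(kernelMode)
  if (is.null(poolIds))
    poolIds <- setdiff(names(descSet@descriptors), testIds)
  if (length(intersect(poolIds, testIds)))
    stop("selection pool and test set overlap")
  if (is.unsorted(sizes)) stop("sizes must be ascending")
  if (max(sizes) > length(poolIds)) stop("largest size exceeds the pool")
  poolDesc <- new("DescriptorSet", descriptors = descSet@descriptors[poolIds],
                  params = descSet@params)
  order <- switch(selectionMode,
    fps_intensive = fpsSelect(
      molecularKernel(poolDesc, "intensive", zeta = zeta), max(sizes)),
    fps_extensive = fpsSelect(
      molecularKernel(poolDesc, "extensive", zeta = zeta), max(sizes)),
    random = randomSelect(poolIds, max(sizes), seed))
  testDesc <- new("DescriptorSet", descriptors = descSet@descriptors[testIds],
                  params = descSet@params)
  aeTest <- vapply(testIds, function(id) molSet@molecules[[id]]@eAt, numeric(1))
  mae <- vapply(sizes, function(s) {
    model <- trainKRR(molSet, descSet, order[seq_len(s)], lambda = lambda,
                      kernelMode = kernelMode, zeta = zeta)
    evaluateMAE(predictAE(model, testDesc), aeTest)
  }, numeric(1))
  structure(data.frame(n_train = sizes, mae_ae = mae),
            selection = as.character(order))
}

setMethod("show", "KRRModel", function(object) {
  cat(sprintf(
    "KRRModel: %d training molecules, %s kernel (zeta = %g), target %s, lambda = %.3g\n",
    length(object@trainIds), object@kernelMode, object@zeta,
    object@targetMode, object@lambda))
})

#' Persist / restore a trained model
#'
#' The archive stores descriptor parameters, kernel mode, target mode,
#' lambda, zeta, training ids, dual coefficients and the training
#' descriptors; a re-loaded model reproduces predictions bit-exactly.
#'
#' @param model a \linkS4class{KRRModel}.
#' @param path archive path (.rds).
#' @return \code{saveModel}: invisibly \code{path}; \code{loadModel}:
#'   the restored model.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(format = "rxnspace-krr-1", model = model), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "rxnspace-krr-1"))
    stop("not a rxnspace model archive")
  validObject(obj$model)
  obj$model
}
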