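#' @include AllClasses.R descriptors.R
NULL

# Unit-normalize descriptor rows; all-zero rows are an error (the
# reference descriptor always sets a one-hot, so this only triggers on
# malformed external input).
.normalizeRows <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0)) stop("all-zero descriptor vector")
  X / nrm
}

#' Atomic kernel between two environment vectors
#'
#' Similarity of two per-atom environments: the dot product of the
#' unit-normalized vectors raised to the power zeta, so k(x, x) = 1 and
#' k is in [0, 1] for non-negative descriptors.
#'
#' @param xa,xb numeric vectors of equal length, not all zero.
#' @param zeta positive integer exponent.
#' @return scalar kernel value.
#' @examples
#' atomicKernel(c(1, 0), c(1, 1), zeta = 2)  # 0.5
#' @export
atomicKernel <- function(xa, xb, zeta = 2) {
  if (length(xa) != length(xb)) stop("descriptor length mismatch")
  na <- sqrt(sum(xa^2)); nb <- sqrt(sum(xb^2))
  if (na == 0 || nb == 0) stop("all-zero descriptor vector")
  (sum(xa * xb) / (na * nb))^zeta
}

#' Intensive (average) molecular kernel of one pair
#'
#' Mean of all atomic kernel values between the atoms of A and B:
#' K(A,B) = (1 / (N_A N_B)) * sum_ab k(x_a, x_b). Size-blind: it
#' measures how similar the atoms are on average, so it pairs with
#' intensive targets (atomization energy per atom).
#'
#' @param A,B descriptor matrices (atoms x features) from identical
#'   parameters.
#' @param zeta atomic-kernel exponent.
#' @return scalar kernel value in (0, 1].
#' @export
intensiveKernel <- function(A, B, zeta = 2) {
  if (ncol(A) != ncol(B)) stop("descriptor dimension mismatch")
  S <- tcrossprod(.normalizeRows(A), .normalizeRows(B))^zeta
  sum(S) / (nrow(A) * nrow(B))
}

#' Extensive (sum) molecular kernel of one pair
#'
#' Sum of all atomic kernel values: K(A,B) = sum_ab k(x_a, x_b). It
#' scales with system size (K(A,A) ~ N_A^2), so it pairs with extensive
#' targets (the total atomization energy). Identity:
#' K_ext = N_A N_B K_int.
#'
#' @inheritParams intensiveKernel
#' @return scalar kernel value.
#' @export
extensiveKernel <- function(A, B, zeta = 2) {
  if (ncol(A) != ncol(B)) stop("descriptor dimension mismatch")
  sum(tcrossprod(.normalizeRows(A), .normalizeRows(B))^zeta)
}

#' Molecular kernel matrix over a descriptor set
#'
#' Assembles the square intensive or extensive kernel over all molecules
#' of \code{descSet}, blockwise over molecule pairs so that at most
#' about \code{blockSize} molecules' atoms are cross-multiplied at once
#' (memory ceiling ~ (blockSize * max atoms)^2 doubles); the result is
#' independent of the block size. Intensive kernels are normalized to a
#' unit diagonal by default (the convention used for distance-based
#' selection); the extensive kernel is never normalized.
#'
#' @param descSet a \linkS4class{DescriptorSet}.
#' @param mode \code{"intensive"} or \code{"extensive"}.
#' @param zeta atomic-kernel exponent; default from the descriptor
#'   parameters.
#' @param normalize logical; normalize the intensive kernel to unit
#'   diagonal (ignored for extensive).
#' @param blockSize molecules per block.
#' @return a \linkS4class{MolecularKernel}.
#' @export
molecularKernel <- function(descSet, mode = c("intensive", "extensive"),
                            zeta = NULL, normalize = NULL, blockSize = 200L) {
  mode <- match.arg(mode)
  if (is.null(zeta)) zeta <- descSet@params@zeta
  if (is.null(normalize)) normalize <- mode == "intensive"
  K <- .pairSumMatrix(descSet@descriptors, descSet@descriptors, zeta,
                      blockSize, symmetric = TRUE)
  ids <- names(descSet@descriptors)
  if (mode == "intensive") {
    n <- vapply(descSet@descriptors, nrow, integer(1))
    K <- K / outer(n, n)
  }
  K <- (K + t(K)) / 2   # exact symmetry against round-off
  dimnames(K) <- list(ids, ids)
  out <- new("MolecularKernel", matrix = K, mode = mode,
             normalized = FALSE, zeta = zeta)
  if (mode == "intensive" && normalize) out <- normalizeIntensive(out)
  out
}

# Sum over atomic kernel entries for every molecule pair, blockwise.
.pairSumMatrix <- function(descA, descB, zeta, blockSize, symmetric = FALSE) {
  nA <- length(descA); nB <- length(descB)
  K <- matrix(0, nA, nB)
  blocksA <- split(seq_len(nA), ceiling(seq_len(nA) / blockSize))
  blocksB <- split(seq_len(nB), ceiling(seq_len(nB) / blockSize))
  normed <- function(lst, idx) .normalizeRows(do.call(rbind, lst[idx]))
  for (bi in seq_along(blocksA)) {
    I <- blocksA[[bi]]
    XI <- normed(descA, I)
    gI <- rep(seq_along(I), vapply(descA[I], nrow, integer(1)))
    for (bj in seq_along(blocksB)) {
      if (symmetric && bj < bi) next
      J <- blocksB[[bj]]
      XJ <- normed(descB, J)
      gJ <- rep(seq_along(J), vapply(descB[J], nrow, integer(1)))
      S <- tcrossprod(XI, XJ)^zeta
      M <- rowsum(S, gI, reorder = TRUE)
      M <- t(rowsum(t(M), gJ, reorder = TRUE))
      K[I, J] <- M
      if (symmetric && bj > bi) K[J, I] <- t(M)
    }
  }
  K
}

#' Normalize an intensive kernel to unit diagonal
#'
#' K'(A,B) = K(A,B) / sqrt(K(A,A) K(B,B)); preserves positive
#' semi-definiteness and makes the induced distance lie in [0, sqrt(2)].
#'
#' @param K a \linkS4class{MolecularKernel} (intensive) or a plain
#'   square matrix with strictly positive diagonal.
#' @return the normalized object of the same type.
#' @export
normalizeIntensive <- function(K) {
  m <- if (is(K, "MolecularKernel")) K@matrix else K
  d <- diag(m)
  if (any(d <= 0)) stop("nonpositive kernel diagonal; cannot normalize")
  s <- 1 / sqrt(d)
  m <- m * outer(s, s)
  diag(m) <- 1
  if (is(K, "MolecularKernel")) {
    if (K@mode != "intensive")
      stop("only intensive kernels are normalized")
    new("MolecularKernel", matrix = m, mode = "intensive",
        normalized = TRUE, zeta = K@zeta)
  } else m
}

#' Kernel-induced distance
#'
#' D(A,B) = sqrt(K(A,A) + K(B,B) - 2 K(A,B)); tiny negative radicands
#' (round-off) are clipped to zero.
#'
#' @param K a \linkS4class{MolecularKernel} or square kernel matrix.
#' @param a,b molecule ids or indices; omit both for the full distance
#'   matrix.
#' @return scalar distance, or the full symmetric distance matrix.
#' @export
kernelDistance <- function(K, a = NULL, b = NULL) {
  m <- if (is(K, "MolecularKernel")) K@matrix else K
  d <- diag(m)
  if (!is.null(a) && !is.null(b)) {
    q <- d[a] + d[b] - 2 * m[a, b]
    if (q < -1e-10) stop("kernel is not a valid similarity (negative squared distance)")
    return(sqrt(max(q, 0)))
  }
  q <- outer(d, d, `+`) - 2 * m
  q[q < 0] <- 0
  sqrt(q)
}

#' Kernel principal component analysis
#'
#' Double-centers the kernel matrix (uniform centering over the full
#' set), eigendecomposes it, and returns the leading component scores
#' scaled by the square root of their eigenvalues. Components with
#' non-positive eigenvalues are rejected. Sign convention: in each
#' component, the entry of largest magnitude is positive.
#'
#' @param K a \linkS4class{MolecularKernel} or square symmetric matrix.
#' @param nComponents number of components to return.
#' @return list with \code{scores} (molecules x components),
#'   \code{eigenvalues} (all positive eigenvalues, descending) and
#'   \code{varianceExplained} (fractions for the returned components).
#' @export
kernelPCA <- function(K, nComponents = 2L) {
  m <- if (is(K, "MolecularKernel")) K@matrix else K
  n <- nrow(m)
  H <- diag(n) - matrix(1 / n, n, n)
  Kc <- H %*% m %*% H
  Kc <- (Kc + t(Kc)) / 2
  eig <- eigen(Kc, symmetric = TRUE)
  pos <- eig$values > max(eig$values) * 1e-12 & eig$values > 0
  if (nComponents > sum(pos))
    stop(sprintf("requested %d components but only %d positive eigenvalues",
                 nComponents, sum(pos)))
  vals <- eig$values[pos]
  vecs <- eig$vectors[, pos, drop = FALSE]
  scores <- sweep(vecs[, seq_len(nComponents), drop = FALSE], 2,
                  sqrt(vals[seq_len(nComponents)]), `*`)
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- rownames(m)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  list(scores = scores, eigenvalues = vals,
       varianceExplained = vals[seq_len(nComponents)] / sum(vals))
}

#' @describeIn kernelMatrix matrix of a MolecularKernel.
#' @export
setMethod("kernelMatrix", "MolecularKernel", function(x) x@matrix)

#' @describeIn kernelMode mode of a MolecularKernel.
#' @export
setMethod("kernelMode", "MolecularKernel", function(x) x@mode)

#' @describeIn kernelMode kernel mode of a KRRModel.
#' @export
setMethod("kernelMode", "KRRModel", function(x) x@kernelMode)

setMethod("show", "MolecularKernel", function(object) {
  cat(sprintf("MolecularKernel (%s%s), %d molecules, zeta = %g\n",
              object@mode, if (object@normalized) ", normalized" else "",
              nrow(object@matrix), object@zeta))
})

#' Persist / restore a molecular kernel matrix
#'
#' Dense CSV with the molecule ids as header; mode, normalization flag
#' and zeta are stored in a leading comment line.
#'
#' @param K a \linkS4class{MolecularKernel}.
#' @param path file path.
#' @return \code{writeKernel}: invisibly \code{path};
#'   \code{readKernel}: the restored \linkS4class{MolecularKernel}.
#' @export
writeKernel <- function(K, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mode=%s normalized=%s zeta=%.12g",
                     K@mode, K@normalized, K@zeta), con)
  utils::write.csv(as.data.frame(K@matrix), con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeKernel
#' @export
readKernel <- function(path) {
  meta <- .parseProps(sub("^#\\s*", "", readLines(path, n = 1L)))
  m <- as.matrix(utils::read.csv(path, skip = 1L, check.names = FALSE))
  rownames(m) <- colnames(m)
  new("MolecularKernel", matrix = m, mode = meta$mode,
      normalized = as.logical(meta$normalized),
      zeta = as.numeric(meta$zeta))
}
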