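#' @include AllClasses.R utils.R
NULL

#' Descriptor parameter constructor
#'
#' Defaults (rCut = 4 Angstrom, sigmaR = 0.3 Angstrom, nBins = 24,
#' zeta = 2) are typical magnitudes for local-environment descriptors of
#' small organic molecules; all are tunable.
#'
#' @param rCut cutoff radius, Angstrom.
#' @param sigmaR Gaussian smearing, Angstrom.
#' @param nBins radial bins per element channel.
#' @param elements ordered element channels.
#' @param zeta atomic-kernel exponent (consumed by the kernel module).
#' @return a \linkS4class{DescriptorParams}.
#' @export
DescriptorParams <- function(rCut = 4.0, sigmaR = 0.3, nBins = 24L,
                             elements = c("C", "H", "O"), zeta = 2) {
  new("DescriptorParams", rCut = rCut, sigmaR = sigmaR,
      nBins = as.integer(nBins), elements = elements, zeta = zeta)
}

#' Per-atom environment descriptor of one molecule
#'
#' Reference descriptor: for each atom, a Gaussian-smeared radial
#' histogram of its neighbours, one block per element channel, windowed
#' by the smooth cutoff f(r) = (cos(pi r / rCut) + 1) / 2, concatenated
#' with a one-hot encoding of the central atom's element. The result is
#' invariant to rigid rotations/translations and to permutation of
#' identical atoms, and atoms beyond rCut contribute exactly zero -- the
#' contract any plug-in descriptor (e.g. an externally computed SOAP
#' power spectrum) must also satisfy.
#'
#' @param molecule a \linkS4class{Molecule}.
#' @param params a \linkS4class{DescriptorParams}.
#' @return numeric matrix, one row per atom (rownames = element symbols),
#'   \code{nBins * length(elements) + length(elements)} columns.
#' @export
computeReferenceDescriptor <- function(molecule, params) {
  el <- molecule@elements
  unknown <- setdiff(unique(el), params@elements)
  if (length(unknown))
    stop(sprintf("molecule '%s': element(s) not in descriptor channels: %s",
                 molecule@id, paste(unknown, collapse = ", ")))
  n <- length(el)
  nb <- params@nBins
  ne <- length(params@elements)
  centers <- params@rCut * seq_len(nb) / nb   # equally spaced on (0, rCut]
  X <- matrix(0, nrow = n, ncol = nb * ne + ne)
  rownames(X) <- el
  dmat <- as.matrix(stats::dist(molecule@coords))
  for (a in seq_len(n)) {
    for (ei in seq_len(ne)) {
      e <- params@elements[ei]
      nb_idx <- which(el == e & seq_len(n) != a & dmat[a, ] < params@rCut)
      if (length(nb_idx)) {
        r <- dmat[a, nb_idx]
        fcut <- 0.5 * (cos(pi * r / params@rCut) + 1)
        # bins x neighbours Gaussian evaluations, summed over neighbours
        g <- exp(-outer(centers, r, `-`)^2 / (2 * params@sigmaR^2))
        X[a, (ei - 1L) * nb + seq_len(nb)] <- as.numeric(g %*% fcut)
      }
    }
    X[a, nb * ne + match(el[a], params@elements)] <- 1
  }
  X
}

#' Descriptors for a whole molecule set
#'
#' Deterministic and order-independent: each molecule's matrix depends
#' only on that molecule and the shared parameters.
#'
#' @param molSet a \linkS4class{MoleculeSet}.
#' @param params shared \linkS4class{DescriptorParams}.
#' @return a \linkS4class{DescriptorSet} indexed by molecule id.
#' @export
computeDescriptors <- function(molSet, params = DescriptorParams()) {
  ds <- lapply(molSet@molecules, function(m) {
    tryCatch(computeReferenceDescriptor(m, params),
             error = function(e) stop(sprintf("molecule '%s': %s",
                                              m@id, conditionMessage(e))))
  })
  new("DescriptorSet", descriptors = ds, params = params)
}

#' Export descriptors as one dense table
#'
#' @param descSet a \linkS4class{DescriptorSet}.
#' @return data.frame with columns molecule_id, atom_index, element and
#'   the feature columns f1..fD, suitable for interchange with external
#'   descriptor codes.
#' @export
exportDescriptorTable <- function(descSet) {
  rows <- lapply(names(descSet@descriptors), function(id) {
    X <- descSet@descriptors[[id]]
    df <- data.frame(molecule_id = id, atom_index = seq_len(nrow(X)),
                     element = rownames(X), stringsAsFactors = FALSE)
    cbind(df, as.data.frame(X, row.names = FALSE))
  })
  out <- do.call(rbind, rows)
  names(out)[-(1:3)] <- paste0("f", seq_len(ncol(out) - 3L))
  rownames(out) <- NULL
  out
}

#' Ingest an externally computed descriptor table
#'
#' Accepts the layout of \code{\link{exportDescriptorTable}} so a true
#' SOAP implementation (or any other per-atom descriptor honouring the
#' invariance contract) can be plugged into the kernel machinery
#' unchanged.
#'
#' @param df data.frame with molecule_id, atom_index, element and
#'   numeric feature columns.
#' @param params the \linkS4class{DescriptorParams} to attach (only
#'   \code{zeta} and \code{elements} are consumed downstream).
#' @return a \linkS4class{DescriptorSet}.
#' @export
importDescriptorTable <- function(df, params = DescriptorParams()) {
  featCols <- setdiff(names(df), c("molecule_id", "atom_index", "element"))
  ds <- lapply(split(df, df$molecule_id), function(sub) {
    sub <- sub[order(sub$atom_index), ]
    X <- as.matrix(sub[, featCols, drop = FALSE])
    rownames(X) <- sub$element
    X
  })
  # preserve first-appearance order of molecule ids
  ds <- ds[unique(df$molecule_id)]
  new("DescriptorSet", descriptors = ds, params = params)
}
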