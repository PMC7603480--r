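#' @import methods
NULL

# Maximum covalent valence per element in the CHO scope.
.MAX_VALENCE <- c(C = 4L, H = 1L, O = 2L)

#' Molecule: geometry, composition and energies
#'
#' A single molecule: element symbols, Cartesian coordinates (Angstrom),
#' an optional SMILES tag carried as opaque metadata, and optional total
#' and atomization energies in eV. A molecule is a node of a reaction
#' network. The atomization energy convention is total energy minus the
#' sum of isolated neutral-atom energies, so bound molecules have
#' negative atomization energies.
#'
#' @slot id character molecule identifier, unique within a set.
#' @slot elements character vector of element symbols, one per atom.
#' @slot coords numeric N x 3 matrix of Cartesian coordinates in Angstrom.
#' @slot smiles optional SMILES string (\code{NA} if absent).
#' @slot eTotal optional total energy, eV (\code{NA} if absent).
#' @slot eAt optional atomization energy, eV (\code{NA} if absent).
#' @slot geometrySource either \code{"reference"} or \code{"approximate"}.
#'
#' @exportClass Molecule
setClass("Molecule",
  representation(
    id = "character",
    elements = "character",
    coords = "matrix",
    smiles = "character",
    eTotal = "numeric",
    eAt = "numeric",
    geometrySource = "character"
  ),
  prototype(
    smiles = NA_character_,
    eTotal = NA_real_,
    eAt = NA_real_,
    geometrySource = "reference"
  )
)

setValidity("Molecule", function(object) {
  msg <- character()
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (!is.numeric(object@coords) || ncol(object@coords) != 3L)
    msg <- c(msg, "'coords' must be a numeric N x 3 matrix")
  if (length(object@elements) != nrow(object@coords))
    msg <- c(msg, "length(elements) must equal nrow(coords)")
  if (length(object@elements) < 1L)
    msg <- c(msg, "a molecule must contain at least one atom")
  if (any(!is.finite(object@coords)))
    msg <- c(msg, "coordinates must be finite")
  if (!object@geometrySource %in% c("reference", "approximate"))
    msg <- c(msg, "'geometrySource' must be 'reference' or 'approximate'")
  if (length(msg)) msg else TRUE
})

#' Set of molecules
#'
#' An id-indexed, ordered collection of \linkS4class{Molecule} objects.
#'
#' @slot molecules named list of \linkS4class{Molecule}; names are the
#'   molecule ids.
#'
#' @exportClass MoleculeSet
setClass("MoleculeSet", representation(molecules = "list"))

setValidity("MoleculeSet", function(object) {
  mols <- object@molecules
  if (!all(vapply(mols, is, logical(1), "Molecule")))
    return("all elements must be Molecule objects")
  ids <- vapply(mols, function(m) m@id, character(1))
  if (anyDuplicated(ids))
    return(sprintf("duplicate molecule ids: %s",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (length(mols) && !identical(names(mols), unname(ids)))
    return("list names must equal molecule ids")
  TRUE
})

#' Reaction: a stoichiometric edge of the network
#'
#' A directed reaction educts -> products with positive integer
#' stoichiometric coefficients and an optional reaction energy (eV).
#' Element balance is validated when the reaction is placed in a
#' \linkS4class{ReactionNetwork}.
#'
#' @slot id character reaction identifier.
#' @slot educts named integer vector: molecule id -> coefficient.
#' @slot products named integer vector: molecule id -> coefficient.
#' @slot eReac optional reaction energy, eV (\code{NA} if absent).
#'
#' @exportClass Reaction
setClass("Reaction",
  representation(
    id = "character",
    educts = "integer",
    products = "integer",
    eReac = "numeric"
  ),
  prototype(eReac = NA_real_)
)

setValidity("Reaction", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@educts) < 1L || length(object@products) < 1L)
    msg <- c(msg, "a reaction needs at least one educt and one product")
  if (is.null(names(object@educts)) || is.null(names(object@products)))
    msg <- c(msg, "educts and products must be named by molecule id")
  if (any(object@educts < 1L) || any(object@products < 1L))
    msg <- c(msg, "stoichiometric coefficients must be positive integers")
  if (anyDuplicated(names(object@educts)) || anyDuplicated(names(object@products)))
    msg <- c(msg, "duplicate species within one side of a reaction")
  if (length(msg)) msg else TRUE
})

#' Reaction network: molecules as nodes, reactions as edges
#'
#' A hypergraph of molecules and stoichiometric reactions. Validity
#' requires that every species referenced by a reaction exists in the
#' molecule set and that every reaction balances element counts exactly.
#'
#' @slot molecules a \linkS4class{MoleculeSet}.
#' @slot reactions named list of \linkS4class{Reaction}.
#'
#' @exportClass ReactionNetwork
setClass("ReactionNetwork",
  representation(molecules = "MoleculeSet", reactions = "list"))

setValidity("ReactionNetwork", function(object) {
  if (!all(vapply(object@reactions, is, logical(1), "Reaction")))
    return("all elements of 'reactions' must be Reaction objects")
  rids <- vapply(object@reactions, function(r) r@id, character(1))
  if (anyDuplicated(rids))
    return("duplicate reaction ids")
  if (length(object@reactions) && !identical(names(object@reactions), unname(rids)))
    return("reaction list names must equal reaction ids")
  mids <- names(object@molecules@molecules)
  for (r in object@reactions) {
    ref <- c(names(r@educts), names(r@products))
    missing <- setdiff(ref, mids)
    if (length(missing))
      return(sprintf("reaction '%s' references unknown molecule id(s): %s",
                     r@id, paste(missing, collapse = ", ")))
    bal <- .reactionElementImbalance(r, object@molecules)
    if (length(bal))
      return(sprintf("reaction '%s' is element-unbalanced (%s)",
                     r@id, paste(bal, collapse = ", ")))
  }
  TRUE
})

#' Descriptor parameters
#'
#' Hyperparameters of the per-atom environment descriptor and of the
#' atomic kernel consuming it.
#'
#' @slot rCut cutoff radius, Angstrom.
#' @slot sigmaR Gaussian smearing width, Angstrom.
#' @slot nBins number of radial bins per element channel.
#' @slot elements ordered element list defining the channel layout.
#' @slot zeta positive integer exponent of the atomic kernel.
#'
#' @exportClass DescriptorParams
setClass("DescriptorParams",
  representation(
    rCut = "numeric",
    sigmaR = "numeric",
    nBins = "integer",
    elements = "character",
    zeta = "numeric"
  ),
  prototype(rCut = 4.0, sigmaR = 0.3, nBins = 24L,
            elements = c("C", "H", "O"), zeta = 2)
)

setValidity("DescriptorParams", function(object) {
  msg <- character()
  if (object@rCut <= 0) msg <- c(msg, "rCut must be > 0")
  if (object@sigmaR <= 0) msg <- c(msg, "sigmaR must be > 0")
  if (object@nBins < 1L) msg <- c(msg, "nBins must be >= 1")
  if (!length(object@elements)) msg <- c(msg, "elements must be non-empty")
  if (object@zeta <= 0 || object@zeta != round(object@zeta))
    msg <- c(msg, "zeta must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Per-dataset descriptor matrices
#'
#' One numeric matrix per molecule (atoms x features), all with the same
#' feature dimension, plus the parameters they were computed with. Row
#' names carry the element symbol of each atom.
#'
#' @slot descriptors named list of numeric matrices, indexed by molecule id.
#' @slot params the \linkS4class{DescriptorParams} used.
#'
#' @exportClass DescriptorSet
setClass("DescriptorSet",
  representation(descriptors = "list", params = "DescriptorParams"))

setValidity("DescriptorSet", function(object) {
  ds <- object@descriptors
  if (!length(ds)) return(TRUE)
  d <- unique(vapply(ds, ncol, integer(1)))
  if (length(d) != 1L)
    return("all descriptor matrices must share one feature dimension")
  if (!all(vapply(ds, function(m) all(is.finite(m)), logical(1))))
    return("descriptor entries must be finite")
  TRUE
})

#' Molecular kernel matrix
#'
#' A square symmetric positive semi-definite similarity matrix over
#' molecule ids, computed in either the intensive (average) or the
#' extensive (sum) mode. An intensive kernel may additionally be
#' normalized so that its diagonal is exactly 1.
#'
#' @slot matrix square numeric matrix with molecule ids as dimnames.
#' @slot mode \code{"intensive"} or \code{"extensive"}.
#' @slot normalized logical; \code{TRUE} only for normalized intensive kernels.
#' @slot zeta atomic kernel exponent used.
#'
#' @exportClass MolecularKernel
setClass("MolecularKernel",
  representation(matrix = "matrix", mode = "character",
                 normalized = "logical", zeta = "numeric"))

setValidity("MolecularKernel", function(object) {
  K <- object@matrix
  msg <- character()
  if (nrow(K) != ncol(K)) msg <- c(msg, "kernel matrix must be square")
  if (is.null(rownames(K)) || !identical(rownames(K), colnames(K)))
    msg <- c(msg, "kernel matrix needs identical row/col molecule ids")
  if (nrow(K) && max(abs(K - t(K))) > 1e-10)
    msg <- c(msg, "kernel matrix must be symmetric to 1e-10")
  if (!object@mode %in% c("intensive", "extensive"))
    msg <- c(msg, "mode must be 'intensive' or 'extensive'")
  if (object@normalized && object@mode == "intensive" && nrow(K) &&
      max(abs(diag(K) - 1)) > 1e-10)
    msg <- c(msg, "normalized intensive kernel must have unit diagonal")
  if (length(msg)) msg else TRUE
})

#' Kernel ridge regression model for atomization energies
#'
#' Dual-form KRR model: training descriptors, dual coefficients alpha
#' solving (K + lambda I) alpha = y, the kernel mode and the training
#' target convention. Intensive-kernel models are trained on the
#' atomization energy per atom (AE/N) and rescale predictions by N;
#' extensive-kernel models are trained on the total AE directly.
#'
#' @slot trainIds character vector of training molecule ids (kernel order).
#' @slot alpha numeric dual coefficient vector, one per training molecule.
#' @slot lambda regularization parameter, > 0 (or tiny for interpolation).
#' @slot kernelMode \code{"intensive"} or \code{"extensive"}.
#' @slot targetMode \code{"AE_per_atom"} or \code{"AE"}.
#' @slot zeta atomic kernel exponent.
#' @slot normalized logical, whether the intensive kernel was normalized.
#' @slot trainDescriptors \linkS4class{DescriptorSet} of the training
#'   molecules, kept so test kernels can be assembled.
#'
#' @exportClass KRRModel
setClass("KRRModel",
  representation(
    trainIds = "character",
    alpha = "numeric",
    lambda = "numeric",
    kernelMode = "character",
    targetMode = "character",
    zeta = "numeric",
    normalized = "logical",
    trainDescriptors = "DescriptorSet"
  )
)

setValidity("KRRModel", function(object) {
  msg <- character()
  if (length(object@alpha) != length(object@trainIds))
    msg <- c(msg, "length(alpha) must equal number of training molecules")
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (!object@kernelMode %in% c("intensive", "extensive"))
    msg <- c(msg, "kernelMode must be 'intensive' or 'extensive'")
  if (!object@targetMode %in% c("AE_per_atom", "AE"))
    msg <- c(msg, "targetMode must be 'AE_per_atom' or 'AE'")
  if (length(msg)) msg else TRUE
})

#' Conditions of a mean-field microkinetic simulation
#'
#' Constant-barrier mass-action kinetics: every reaction shares one
#' activation barrier \code{barrier} (eV) and one prefactor (arbitrary
#' inverse time units); reverse rates follow from detailed balance
#' through the reaction energy, so equilibria are Boltzmann.
#'
#' @slot temperature temperature, K.
#' @slot barrier constant activation barrier Ea0, eV.
#' @slot prefactor rate prefactor A, 1/time (arbitrary units).
#' @slot init named numeric vector of initial concentrations.
#' @slot times increasing positive time grid (a leading 0 is added by
#'   the integrator).
#' @slot barrierRule \code{"constant"} (forward barrier always Ea0) or
#'   \code{"clipped"} (forward barrier max(Ea0, Ea0 + dE)).
#' @slot rtol relative tolerance of the stiff integrator.
#'
#' @exportClass KineticConditions
setClass("KineticConditions",
  representation(
    temperature = "numeric",
    barrier = "numeric",
    prefactor = "numeric",
    init = "numeric",
    times = "numeric",
    barrierRule = "character",
    rtol = "numeric"
  ),
  prototype(temperature = 1000, barrier = 0.5, prefactor = 1,
            barrierRule = "constant", rtol = 1e-8)
)

setValidity("KineticConditions", function(object) {
  msg <- character()
  if (object@temperature <= 0) msg <- c(msg, "temperature must be > 0")
  if (object@barrier < 0) msg <- c(msg, "barrier must be >= 0")
  if (object@prefactor <= 0) msg <- c(msg, "prefactor must be > 0")
  if (is.null(names(object@init)) || !length(object@init))
    msg <- c(msg, "init must be a named concentration vector")
  if (any(object@init < 0)) msg <- c(msg, "initial concentrations must be >= 0")
  if (all(object@init == 0)) msg <- c(msg, "at least one nonzero initial concentration")
  if (length(object@times) < 1L || any(object@times <= 0) ||
      is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "times must be strictly increasing and positive")
  if (!object@barrierRule %in% c("constant", "clipped"))
    msg <- c(msg, "barrierRule must be 'constant' or 'clipped'")
  if (length(msg)) msg else TRUE
})

#' Microkinetic trajectory
#'
#' Time-resolved species concentrations and cumulative per-reaction flux
#' (integral of |net rate| over time) from \code{\link{integrateNetwork}}.
#'
#' @slot times time grid including t = 0.
#' @slot concentrations time x species matrix.
#' @slot fluxes time x reaction matrix of cumulative |net rate| integrals.
#' @slot network the simulated \linkS4class{ReactionNetwork}.
#' @slot conditions the \linkS4class{KineticConditions} used.
#'
#' @exportClass Trajectory
setClass("Trajectory",
  representation(
    times = "numeric",
    concentrations = "matrix",
    fluxes = "matrix",
    network = "ReactionNetwork",
    conditions = "KineticConditions"
  )
)

#' Molecular graph for the synthetic CHO generator
#'
#' A connected multigraph of C/H/O atoms with bond orders 1 or 2 and
#' explicit free valences marking radical sites. The enumeration
#' building block emulating a radical-rich CHO database.
#'
#' @slot elements character vector of element symbols (C, H, O).
#' @slot bonds integer matrix with columns i, j, order (i < j); zero rows
#'   for a single free atom.
#' @slot freeVal integer vector of unused valences (radical sites) per atom.
#'
#' @exportClass MolGraph
setClass("MolGraph",
  representation(elements = "character", bonds = "matrix",
                 freeVal = "integer"))

setValidity("MolGraph", function(object) {
  el <- object@elements
  if (!all(el %in% names(.MAX_VALENCE)))
    return("elements must be C, H or O")
  b <- object@bonds
  if (ncol(b) != 3L) return("bonds must have columns i, j, order")
  if (nrow(b)) {
    if (any(b[, 1] >= b[, 2])) return("bonds must be stored with i < j")
    if (any(b[, 3] < 1L | b[, 3] > 2L)) return("bond orders must be 1 or 2")
    if (max(b[, 1:2]) > length(el)) return("bond index out of range")
    key <- paste(b[, 1], b[, 2])
    if (anyDuplicated(key)) return("duplicate bond between one atom pair")
  }
  used <- .graphUsedValence(object)
  if (length(object@freeVal) != length(el))
    return("freeVal must have one entry per atom")
  if (any(object@freeVal < 0L))
    return("free valences must be >= 0")
  if (any(used + object@freeVal > .MAX_VALENCE[el]))
    return("valence exceeded (used + free > max)")
  if (!.graphIsConnected(object))
    return("molecular graph must be connected")
  TRUE
})

#' Reaction-energy predictions over a network
#'
#' Reaction energies composed via Hess's law from one consistent table
#' of atomization-energy predictions: every molecule's AE is predicted
#' once and reused across all its incident reactions, so hub molecules
#' share a single prediction and thermodynamic cycles close exactly.
#'
#' @slot predictions data.frame with columns reaction_id, e_reac_pred and,
#'   when references exist, e_reac_ref and abs_error.
#' @slot aeTable named numeric vector of the predicted AEs (eV) used.
#' @slot sigmaAE optional assumed per-AE uncertainty, eV.
#'
#' @exportClass REPredictionSet
setClass("REPredictionSet",
  representation(predictions = "data.frame", aeTable = "numeric",
                 sigmaAE = "numeric"),
  prototype(sigmaAE = NA_real_))
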