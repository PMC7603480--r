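#' @include AllClasses.R
NULL

#' Number of atoms
#' @param x a \linkS4class{Molecule} or \linkS4class{MolGraph}.
#' @return integer atom count.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Number of heavy (non-hydrogen) atoms
#' @param x a \linkS4class{Molecule} or \linkS4class{MolGraph}.
#' @return integer heavy-atom count.
#' @export
setGeneric("nHeavy", function(x) standardGeneric("nHeavy"))

#' Molecule ids of a collection
#' @param x a \linkS4class{MoleculeSet} or \linkS4class{ReactionNetwork}.
#' @return character vector of ids.
#' @export
setGeneric("moleculeIds", function(x) standardGeneric("moleculeIds"))

#' Reaction ids of a network
#' @param x a \linkS4class{ReactionNetwork}.
#' @return character vector of reaction ids.
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))

#' Molecules of an object
#' @param x a \linkS4class{MoleculeSet} or \linkS4class{ReactionNetwork}.
#' @return for a network, its \linkS4class{MoleculeSet}; for a set, the
#'   named list of \linkS4class{Molecule}.
#' @export
setGeneric("molecules", function(x) standardGeneric("molecules"))

#' Reactions of a network
#' @param x a \linkS4class{ReactionNetwork}.
#' @return named list of \linkS4class{Reaction}.
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))

#' Kernel matrix of a MolecularKernel
#' @param x a \linkS4class{MolecularKernel}.
#' @return the numeric matrix with molecule-id dimnames.
#' @export
setGeneric("kernelMatrix", function(x) standardGeneric("kernelMatrix"))

#' Kernel mode accessor
#' @param x a \linkS4class{MolecularKernel} or \linkS4class{KRRModel}.
#' @return \code{"intensive"} or \code{"extensive"}.
#' @export
setGeneric("kernelMode", function(x) standardGeneric("kernelMode"))
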