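#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Construct a Molecule
#'
#' @param id molecule id.
#' @param elements character vector of element symbols.
#' @param coords N x 3 numeric matrix, Angstrom.
#' @param smiles optional SMILES string, carried as opaque metadata.
#' @param eTotal optional total energy, eV.
#' @param eAt optional atomization energy, eV.
#' @param geometrySource \code{"reference"} or \code{"approximate"}.
#' @return a \linkS4class{Molecule}.
#' @examples
#' m <- Molecule("h2", c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)))
#' nAtoms(m)
#' @export
Molecule <- function(id, elements, coords, smiles = NA_character_,
                     eTotal = NA_real_, eAt = NA_real_,
                     geometrySource = "reference") {
  coords <- matrix(as.numeric(coords), ncol = 3)
  new("Molecule", id = as.character(id), elements = as.character(elements),
      coords = coords, smiles = as.character(smiles),
      eTotal = as.numeric(eTotal), eAt = as.numeric(eAt),
      geometrySource = geometrySource)
}

#' Construct a MoleculeSet
#'
#' @param molecules a list of \linkS4class{Molecule} objects.
#' @return a \linkS4class{MoleculeSet} indexed by molecule id.
#' @export
MoleculeSet <- function(molecules = list()) {
  ids <- vapply(molecules, function(m) m@id, character(1))
  names(molecules) <- ids
  new("MoleculeSet", molecules = molecules)
}

#' Construct a Reaction
#'
#' Educts/products are given either as named integer vectors
#' (molecule id -> coefficient) or as character vectors of ids where
#' repetition encodes stoichiometry (\code{c("OH", "OH")} means 2 OH).
#'
#' @param id reaction id.
#' @param educts,products species specification, see Details.
#' @param eReac optional reaction energy, eV.
#' @return a \linkS4class{Reaction}.
#' @export
Reaction <- function(id, educts, products, eReac = NA_real_) {
  new("Reaction", id = as.character(id), educts = .asSide(educts),
      products = .asSide(products), eReac = as.numeric(eReac))
}

.asSide <- function(x) {
  if (is.character(x)) {
    tab <- table(x)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(as.integer(x), names(x))
  }
}

#' Construct a ReactionNetwork
#'
#' @param molecules a \linkS4class{MoleculeSet} (or list of Molecule).
#' @param reactions a list of \linkS4class{Reaction} objects.
#' @return a validated \linkS4class{ReactionNetwork}; element balance of
#'   every reaction is checked on construction.
#' @export
ReactionNetwork <- function(molecules, reactions = list()) {
  if (is.list(molecules)) molecules <- MoleculeSet(molecules)
  names(reactions) <- vapply(reactions, function(r) r@id, character(1))
  new("ReactionNetwork", molecules = molecules, reactions = reactions)
}

## ---- accessors -----------------------------------------------------------

#' @describeIn nAtoms atom count of a Molecule.
#' @export
setMethod("nAtoms", "Molecule", function(x) length(x@elements))

#' @describeIn nHeavy heavy-atom count of a Molecule.
#' @export
setMethod("nHeavy", "Molecule", function(x) sum(x@elements != "H"))

#' @describeIn nAtoms atom count of a MolGraph.
#' @export
setMethod("nAtoms", "MolGraph", function(x) length(x@elements))

#' @describeIn nHeavy heavy-atom count of a MolGraph.
#' @export
setMethod("nHeavy", "MolGraph", function(x) sum(x@elements != "H"))

#' @describeIn moleculeIds ids of a MoleculeSet.
#' @export
setMethod("moleculeIds", "MoleculeSet", function(x) names(x@molecules))

#' @describeIn moleculeIds ids of the molecules of a network.
#' @export
setMethod("moleculeIds", "ReactionNetwork",
          function(x) names(x@molecules@molecules))

#' @describeIn reactionIds ids of the reactions of a network.
#' @export
setMethod("reactionIds", "ReactionNetwork", function(x) names(x@reactions))

#' @describeIn molecules molecule list of a MoleculeSet.
#' @export
setMethod("molecules", "MoleculeSet", function(x) x@molecules)

#' @describeIn molecules MoleculeSet of a network.
#' @export
setMethod("molecules", "ReactionNetwork", function(x) x@molecules)

#' @describeIn reactions reaction list of a network.
#' @export
setMethod("reactions", "ReactionNetwork", function(x) x@reactions)

#' @export
setMethod("length", "MoleculeSet", function(x) length(x@molecules))

#' @export
setMethod("[[", "MoleculeSet", function(x, i) x@molecules[[i]])

#' @export
setMethod("[", "MoleculeSet", function(x, i) MoleculeSet(x@molecules[i]))

setMethod("show", "Molecule", function(object) {
  cat(sprintf("Molecule '%s': %d atoms (%d heavy)", object@id,
              nAtoms(object), nHeavy(object)))
  if (!is.na(object@eAt)) cat(sprintf(", AE = %.4f eV", object@eAt))
  if (!is.na(object@smiles)) cat(sprintf(", SMILES %s", object@smiles))
  cat("\n")
})

setMethod("show", "MoleculeSet", function(object) {
  cat(sprintf("MoleculeSet of %d molecules\n", length(object@molecules)))
  if (length(object@molecules)) {
    n <- min(5L, length(object@molecules))
    for (m in object@molecules[seq_len(n)]) show(m)
    if (length(object@molecules) > n) cat("...\n")
  }
})

setMethod("show", "Reaction", function(object) {
  fmt <- function(side) paste(
    ifelse(side > 1L, paste0(side, " ", names(side)), names(side)),
    collapse = " + ")
  cat(sprintf("Reaction '%s': %s -> %s", object@id,
              fmt(object@educts), fmt(object@products)))
  if (!is.na(object@eReac)) cat(sprintf("  (dE = %.4f eV)", object@eReac))
  cat("\n")
})

setMethod("show", "ReactionNetwork", function(object) {
  cat(sprintf("ReactionNetwork: %d molecules, %d reactions\n",
              length(object@molecules@molecules), length(object@reactions)))
})

## ---- energies ------------------------------------------------------------

#' Atomization energy from a total energy
#'
#' The atomization energy is the molecular total energy minus the total
#' energies of the isolated neutral atoms; it is negative for bound
#' molecules.
#'
#' @param eTotal molecular total energy, eV.
#' @param elements element symbols of the molecule.
#' @param refs named numeric vector of isolated-atom energies (eV), e.g.
#'   \code{\link{defaultAtomicReferences}()}.
#' @return atomization energy, eV.
#' @examples
#' atomizationEnergy(-24, c("C", "H", "H", "H", "H"),
#'                   c(C = -10, H = -3))  # -2
#' @export
atomizationEnergy <- function(eTotal, elements, refs) {
  missing <- setdiff(unique(elements), names(refs))
  if (length(missing))
    stop(sprintf("no atomic reference energy for element(s): %s",
                 paste(missing, collapse = ", ")))
  eTotal - sum(refs[elements])
}

#' Check total-vs-atomization energy consistency of a MoleculeSet
#'
#' For every molecule carrying both energies, asserts that they satisfy
#' the atomization-energy definition against \code{refs} within
#' \code{tol}.
#'
#' @param molSet a \linkS4class{MoleculeSet}.
#' @param refs atomic reference energies, eV.
#' @param tol absolute tolerance, eV.
#' @return invisibly \code{TRUE}; stops naming the first offender.
#' @export
validateEnergies <- function(molSet, refs, tol = 1e-8) {
  for (m in molSet@molecules) {
    if (!is.na(m@eTotal) && !is.na(m@eAt)) {
      ae <- atomizationEnergy(m@eTotal, m@elements, refs)
      if (abs(ae - m@eAt) > tol)
        stop(sprintf("molecule '%s': E_at %.10g inconsistent with E_total (expected %.10g)",
                     m@id, m@eAt, ae))
    }
  }
  invisible(TRUE)
}

## ---- network topology ----------------------------------------------------

#' Degree of molecules in a reaction network
#'
#' The degree of a molecule is the number of reactions it is incident
#' to; a species appearing on both sides of one reaction counts once.
#' High-degree "hub" molecules (small fragments such as OH or CH3) are
#' the channels through which atomization-energy errors propagate into
#' many reaction energies.
#'
#' @param network a \linkS4class{ReactionNetwork}.
#' @param ids molecule ids to report; default all molecules.
#' @return named integer vector of degrees.
#' @export
speciesDegree <- function(network, ids = moleculeIds(network)) {
  unknown <- setdiff(ids, moleculeIds(network))
  if (length(unknown))
    stop(sprintf("unknown molecule id(s): %s", paste(unknown, collapse = ", ")))
  deg <- stats::setNames(integer(length(ids)), ids)
  for (r in network@reactions) {
    sp <- unique(c(names(r@educts), names(r@products)))
    sp <- intersect(sp, ids)
    deg[sp] <- deg[sp] + 1L
  }
  deg
}

## ---- extended-XYZ I/O ----------------------------------------------------

#' Read molecules from an extended-XYZ file
#'
#' Per frame: line 1 the atom count, line 2 space-separated
#' \code{key=value} properties (an energy key, optional \code{id},
#' \code{smiles} and \code{geometry_source} keys), then one
#' \code{element x y z} line per atom. Missing energies leave
#' \code{eTotal} unset; missing ids are auto-generated as
#' \code{mol_<index>}.
#'
#' @param path file path.
#' @param energyKey property key holding the total energy (default
#'   \code{"energy"}).
#' @param aeKey optional property key holding the atomization energy.
#' @return a \linkS4class{MoleculeSet}.
#' @export
readMolecules <- function(path, energyKey = "energy", aeKey = "energy_at") {
  lines <- readLines(path)
  mols <- list()
  i <- 1L
  frame <- 0L
  ids <- character()
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    frame <- frame + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop(sprintf("frame %d: malformed atom count '%s'", frame, lines[i]))
    if (i + 1L + n > length(lines))
      stop(sprintf("frame %d: truncated frame (%d atoms declared)", frame, n))
    props <- .parseProps(lines[i + 1L])
    atomLines <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(atomLines), "[[:space:]]+")
    if (any(lengths(parts) < 4L))
      stop(sprintf("frame %d: malformed atom line", frame))
    elements <- vapply(parts, `[[`, character(1), 1L)
    coords <- t(vapply(parts, function(p) {
      v <- suppressWarnings(as.numeric(p[2:4]))
      if (any(is.na(v)))
        stop(sprintf("frame %d: non-numeric coordinates", frame))
      v
    }, numeric(3)))
    id <- if ("id" %in% names(props)) props[["id"]] else sprintf("mol_%d", frame)
    if (id %in% ids)
      stop(sprintf("frame %d: duplicate molecule id '%s'", frame, id))
    ids <- c(ids, id)
    eTotal <- if (energyKey %in% names(props))
      as.numeric(props[[energyKey]]) else NA_real_
    eAt <- if (aeKey %in% names(props)) as.numeric(props[[aeKey]]) else NA_real_
    smiles <- if ("smiles" %in% names(props)) props[["smiles"]] else NA_character_
    gs <- if ("geometry_source" %in% names(props))
      props[["geometry_source"]] else "reference"
    mols[[id]] <- Molecule(id, elements, coords, smiles = smiles,
                           eTotal = eTotal, eAt = eAt, geometrySource = gs)
    i <- i + 2L + n
  }
  MoleculeSet(mols)
}

.parseProps <- function(line) {
  toks <- strsplit(trimws(line), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  kv <- strsplit(toks, "=", fixed = TRUE)
  keys <- vapply(kv, `[[`, character(1), 1L)
  vals <- vapply(kv, function(x)
    if (length(x) >= 2L) paste(x[-1L], collapse = "=") else "", character(1))
  stats::setNames(as.list(vals), keys)
}

#' Write molecules to an extended-XYZ file
#'
#' Inverse of \code{\link{readMolecules}}: coordinates are written with
#' 8 decimals so a round trip reproduces them to well below 1e-6
#' Angstrom, energies with full precision.
#'
#' @param molSet a \linkS4class{MoleculeSet}.
#' @param path output file path.
#' @param energyKey,aeKey property keys used for the energies.
#' @return invisibly \code{path}.
#' @export
writeMolecules <- function(molSet, path, energyKey = "energy",
                           aeKey = "energy_at") {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in molSet@molecules) {
    props <- sprintf("id=%s", m@id)
    if (!is.na(m@eTotal))
      props <- paste(props, sprintf("%s=%.12g", energyKey, m@eTotal))
    if (!is.na(m@eAt))
      props <- paste(props, sprintf("%s=%.12g", aeKey, m@eAt))
    if (!is.na(m@smiles)) props <- paste(props, sprintf("smiles=%s", m@smiles))
    props <- paste(props, sprintf("geometry_source=%s", m@geometrySource))
    writeLines(as.character(nAtoms(m)), con)
    writeLines(props, con)
    writeLines(sprintf("%-2s %14.8f %14.8f %14.8f", m@elements,
                       m@coords[, 1], m@coords[, 2], m@coords[, 3]), con)
  }
  invisible(path)
}

## ---- reaction table I/O --------------------------------------------------

#' Read a reaction table into a ReactionNetwork
#'
#' Delimited text with header columns \code{reaction_id}, \code{educts},
#' \code{products} and optional \code{e_reac}; species within a side are
#' joined by \code{"+"}, repetition encodes stoichiometry. Every row is
#' validated for element balance against \code{molSet}.
#'
#' @param path file path (comma- or tab-separated, sniffed from header).
#' @param molSet the \linkS4class{MoleculeSet} the ids refer to.
#' @return a \linkS4class{ReactionNetwork}.
#' @export
readReactions <- function(path, molSet) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "")
  need <- c("reaction_id", "educts", "products")
  if (!all(need %in% names(df)))
    stop("reaction table must have columns reaction_id, educts, products")
  rxns <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    ed <- trimws(strsplit(df$educts[i], "+", fixed = TRUE)[[1]])
    pr <- trimws(strsplit(df$products[i], "+", fixed = TRUE)[[1]])
    er <- if ("e_reac" %in% names(df)) as.numeric(df$e_reac[i]) else NA_real_
    unknown <- setdiff(c(ed, pr), moleculeIds(molSet))
    if (length(unknown))
      stop(sprintf("row %d ('%s'): unknown molecule id(s): %s", i,
                   df$reaction_id[i], paste(unknown, collapse = ", ")))
    r <- Reaction(df$reaction_id[i], ed, pr, eReac = er)
    bal <- .reactionElementImbalance(r, molSet)
    if (length(bal))
      stop(sprintf("row %d ('%s'): element-unbalanced reaction (%s)", i,
                   df$reaction_id[i], paste(bal, collapse = ", ")))
    rxns[[i]] <- r
  }
  ReactionNetwork(molSet, rxns)
}

#' Write the reaction table of a network
#'
#' @param network a \linkS4class{ReactionNetwork}.
#' @param path output CSV path.
#' @return invisibly \code{path}.
#' @export
writeReactions <- function(network, path) {
  expand <- function(side) paste(rep(names(side), side), collapse = "+")
  df <- data.frame(
    reaction_id = reactionIds(network),
    educts = vapply(network@reactions, function(r) expand(r@educts), character(1)),
    products = vapply(network@reactions, function(r) expand(r@products), character(1)),
    e_reac = vapply(network@reactions, function(r) r@eReac, numeric(1)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- network export ------------------------------------------------------

#' Export a reaction network for graph tooling
#'
#' \code{"graphml"} writes the bipartite expansion (molecule nodes and
#' reaction nodes, edges labelled educt/product with coefficients) via
#' igraph. \code{"edgelist"} writes a round-trippable TSV with columns
#' reaction_id, molecule_id, role, coeff.
#'
#' @param network a \linkS4class{ReactionNetwork}.
#' @param path output path.
#' @param format \code{"graphml"} or \code{"edgelist"}.
#' @return invisibly \code{path}.
#' @export
writeNetwork <- function(network, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    rows <- list()
    for (r in network@reactions) {
      for (side in c("educt", "product")) {
        s <- if (side == "educt") r@educts else r@products
        rows[[length(rows) + 1L]] <- data.frame(
          reaction_id = r@id, molecule_id = names(s), role = side,
          coeff = as.integer(s), stringsAsFactors = FALSE)
      }
    }
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(reaction_id = character(), molecule_id = character(),
                 role = character(), coeff = integer())
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    g <- .networkToIgraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

.networkToIgraph <- function(network) {
  mids <- moleculeIds(network)
  rids <- reactionIds(network)
  deg <- speciesDegree(network)
  edges <- character(0)
  role <- character(0)
  coeff <- integer(0)
  for (r in network@reactions) {
    for (m in names(r@educts)) {
      edges <- c(edges, m, r@id); role <- c(role, "educt")
      coeff <- c(coeff, r@educts[[m]])
    }
    for (m in names(r@products)) {
      edges <- c(edges, r@id, m); role <- c(role, "product")
      coeff <- c(coeff, r@products[[m]])
    }
  }
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(mids, type = "molecule", degree = as.integer(deg[mids])) +
    igraph::vertices(rids, type = "reaction", degree = 0L)
  if (length(edges))
    g <- g + igraph::edges(edges, role = role, coeff = coeff)
  g
}

#' Read back an edge-list network export
#'
#' @param path TSV written by \code{writeNetwork(..., format = "edgelist")}.
#' @param molSet the molecules the ids refer to.
#' @return a \linkS4class{ReactionNetwork}.
#' @export
readNetworkEdgelist <- function(path, molSet) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  rxns <- list()
  for (rid in unique(df$reaction_id)) {
    sub <- df[df$reaction_id == rid, ]
    ed <- sub[sub$role == "educt", ]
    pr <- sub[sub$role == "product", ]
    rxns[[rid]] <- Reaction(rid,
      stats::setNames(ed$coeff, ed$molecule_id),
      stats::setNames(pr$coeff, pr$molecule_id))
  }
  ReactionNetwork(molSet, rxns)
}

#' Load a molecule + reaction corpus from one directory
#'
#' Single adaptation point for externally published datasets: expects
#' \code{molecules.xyz} (extended-XYZ, see \code{\link{readMolecules}})
#' and \code{reactions.csv} (see \code{\link{readReactions}}) in
#' \code{dir}; override the file names if the published layout differs.
#' Atomization energies are derived from total energies via \code{refs}
#' when absent.
#'
#' @param dir directory containing the corpus.
#' @param moleculesFile,reactionsFile file names inside \code{dir}.
#' @param energyKey property key of the total energy.
#' @param refs atomic reference energies used to fill in missing
#'   atomization energies; \code{NULL} to skip.
#' @return a \linkS4class{ReactionNetwork}.
#' @export
loadReactionCorpus <- function(dir, moleculesFile = "molecules.xyz",
                               reactionsFile = "reactions.csv",
                               energyKey = "energy",
                               refs = defaultAtomicReferences()) {
  mols <- readMolecules(file.path(dir, moleculesFile), energyKey = energyKey)
  if (!is.null(refs)) {
    mols <- MoleculeSet(lapply(mols@molecules, function(m) {
      if (is.na(m@eAt) && !is.na(m@eTotal))
        m@eAt <- atomizationEnergy(m@eTotal, m@elements, refs)
      m
    }))
  }
  rpath <- file.path(dir, reactionsFile)
  if (file.exists(rpath)) readReactions(rpath, mols)
  else ReactionNetwork(mols, list())
}
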