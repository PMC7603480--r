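#' @include synthetic-graphs.R chem-data.R
NULL

#' Surrogate bond-energy parameters
#'
#' Bond-counting energy oracle for synthetic fixtures: per-bond
#' dissociation energies (positive, eV), a per-free-valence radical
#' penalty, and optional Gaussian label noise. Magnitudes are plausible
#' for CHO chemistry so learned models face realistic scales; they are
#' configuration, not physics claims.
#'
#' @param bondEnergies named numeric vector over the bond types
#'   \code{C-C, C-H, C-O, H-H, O-H, O-O} (single) and
#'   \code{C=C, C=O, O=O} (double), eV.
#' @param radicalPenalty destabilization per free valence, eV.
#' @param sigma label-noise standard deviation, eV.
#' @param seed seed for the (per-molecule, reproducible) noise.
#' @return list of class parameters consumed by
#'   \code{\link{surrogateEnergy}}.
#' @export
surrogateParams <- function(bondEnergies = c(
                              "C-C" = 3.6, "C-H" = 4.3, "C-O" = 3.7,
                              "H-H" = 4.5, "O-H" = 4.8, "O-O" = 1.5,
                              "C=C" = 6.3, "C=O" = 7.7, "O=O" = 5.2),
                            radicalPenalty = 0.3, sigma = 0, seed = 1L) {
  if (any(bondEnergies <= 0)) stop("bond energies must be positive")
  if (sigma < 0) stop("sigma must be >= 0")
  bondEnergies <- .normBondTable(bondEnergies)
  list(bondEnergies = bondEnergies, radicalPenalty = radicalPenalty,
       sigma = sigma, seed = seed)
}

.bondKey <- function(e1, e2, order) {
  p <- sort(c(e1, e2))
  paste0(p[1], if (order == 2L) "=" else "-", p[2])
}

# Accept bond tables written in either element order (O-H == H-O).
.normBondTable <- function(tab) {
  parts <- strsplit(names(tab), "([-=])")
  sep <- ifelse(grepl("=", names(tab), fixed = TRUE), "=", "-")
  names(tab) <- vapply(seq_along(tab), function(i) {
    p <- sort(parts[[i]])
    paste0(p[1], sep[i], p[2])
  }, character(1))
  tab
}

#' Surrogate atomization/total energy of a molecular graph
#'
#' Bond-counting oracle standing in for quantum-chemical reference
#' energies: E_at = -sum of bond energies + penalty * (free valences)
#' (+ optional reproducible Gaussian noise). Isolated atoms have
#' E_at = 0 by the atomization-energy definition, so the radical
#' penalty applies only to molecules of two or more atoms. The total
#' energy is E_at plus the isolated-atom reference energies.
#'
#' @param graph a \linkS4class{MolGraph}.
#' @param params see \code{\link{surrogateParams}}.
#' @param refs atomic reference energies, eV.
#' @return list with \code{eAt} and \code{eTotal} (eV).
#' @export
surrogateEnergy <- function(graph, params = surrogateParams(),
                            refs = defaultAtomicReferences()) {
  b <- graph@bonds
  eAt <- 0
  if (nAtoms(graph) > 1L) {
    for (k in seq_len(nrow(b))) {
      key <- .bondKey(graph@elements[b[k, 1]], graph@elements[b[k, 2]],
                      b[k, 3])
      if (!key %in% names(params$bondEnergies))
        stop(sprintf("no bond energy for type '%s'", key))
      eAt <- eAt - params$bondEnergies[[key]]
    }
    eAt <- eAt + params$radicalPenalty * sum(graph@freeVal)
  }
  if (params$sigma > 0) {
    canon <- canonicalForm(graph)
    h <- sum(utf8ToInt(canon) * seq_along(utf8ToInt(canon))) %% 1e6
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(.subSeed(params$seed, h))
    eAt <- eAt + stats::rnorm(1, sd = params$sigma)
  }
  list(eAt = eAt, eTotal = eAt + sum(refs[graph@elements]))
}

# Equilibrium bond lengths (Angstrom) used by the embedder.
.BOND_LENGTHS <- c(
  "C-C" = 1.54, "C-H" = 1.09, "C-O" = 1.43, "H-H" = 0.74,
  "O-H" = 0.96, "O-O" = 1.48, "C=C" = 1.34, "C=O" = 1.22, "O=O" = 1.21)

#' Embed a molecular graph in 3D
#'
#' Deterministic geometry from standard bond lengths: atoms are placed
#' breadth-first along tetrahedrally distributed directions and the
#' layout is then relaxed against a harmonic bond-length target with a
#' soft nonbonded repulsion (handles rings). Optional seeded Gaussian
#' coordinate noise emulates reference-vs-approximate geometry pairs.
#' Fails if any two atoms remain closer than 0.7 Angstrom after 100
#' reseeded retries.
#'
#' @param graph a \linkS4class{MolGraph}.
#' @param id molecule id for the resulting \linkS4class{Molecule}.
#' @param seed integer seed; same seed and amplitude give identical
#'   coordinates.
#' @param amplitude Gaussian coordinate noise, Angstrom (0 = none).
#' @param bondLengths named bond-length table, Angstrom.
#' @return a \linkS4class{Molecule} (without energies); the geometry
#'   source is \code{"approximate"} when \code{amplitude > 0}.
#' @export
embedGeometry <- function(graph, id = "mol", seed = 1L, amplitude = 0,
                          bondLengths = .BOND_LENGTHS) {
  bondLengths <- .normBondTable(bondLengths)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  for (try in 0:100) {
    set.seed(.subSeed(seed, try))
    coords <- .embedOnce(graph, bondLengths)
    if (amplitude > 0)
      coords <- coords + matrix(stats::rnorm(length(coords), sd = amplitude),
                                ncol = 3)
    n <- nrow(coords)
    ok <- n == 1L || min(stats::dist(coords)) >= 0.7
    if (ok)
      return(Molecule(id, graph@elements, coords,
                      geometrySource = if (amplitude > 0) "approximate"
                      else "reference"))
  }
  stop(sprintf("embedding failed for %s after 100 retries",
               graphFormula(graph)))
}

.embedOnce <- function(graph, bondLengths) {
  n <- length(graph@elements)
  coords <- matrix(0, n, 3)
  if (n == 1L) return(coords)
  b <- graph@bonds
  adj <- vector("list", n)
  blen <- matrix(NA_real_, n, n)
  for (k in seq_len(nrow(b))) {
    i <- b[k, 1]; j <- b[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    key <- .bondKey(graph@elements[i], graph@elements[j], b[k, 3])
    L <- if (key %in% names(bondLengths)) bondLengths[[key]] else 1.4
    blen[i, j] <- L; blen[j, i] <- L
  }
  # tetrahedral direction template, randomly rotated per molecule
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, 1), c(-1, -1, 1),
                c(-1, 1, -1), c(1, 1, -1), c(1, -1, 1), c(-1, -1, -1))
  dirs <- dirs / sqrt(3)
  theta <- stats::runif(3, 0, 2 * pi)
  Rz <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0),
                          c(0, 0, 1))
  Rx <- function(a) rbind(c(1, 0, 0), c(0, cos(a), -sin(a)),
                          c(0, sin(a), cos(a)))
  dirs <- dirs %*% (Rz(theta[1]) %*% Rx(theta[2]) %*% Rz(theta[3]))
  placed <- logical(n)
  start <- order(-lengths(adj))[1]
  placed[start] <- TRUE
  queue <- start
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]
    for (j in adj[[p]]) {
      if (placed[j]) next
      best <- NULL; bestScore <- -Inf
      for (d in seq_len(nrow(dirs))) {
        cand <- coords[p, ] + blen[p, j] * dirs[d, ]
        sc <- min(sqrt(rowSums(
          (coords[placed, , drop = FALSE] -
             matrix(cand, sum(placed), 3, byrow = TRUE))^2)))
        if (sc > bestScore) { bestScore <- sc; best <- cand }
      }
      coords[j, ] <- best + stats::rnorm(3, sd = 0.02)
      placed[j] <- TRUE
      queue <- c(queue, j)
    }
  }
  .relaxGeometry(coords, blen)
}

# Relax against harmonic bond terms + soft nonbonded repulsion below
# 1.2 Angstrom (deterministic BFGS).
.relaxGeometry <- function(coords, blen) {
  n <- nrow(coords)
  if (n <= 2L) {
    # exact for diatomics: place along z at the target length
    if (n == 2L && !is.na(blen[1, 2]))
      return(rbind(c(0, 0, 0), c(0, 0, blen[1, 2])))
    return(coords)
  }
  ut <- upper.tri(blen)
  pairs <- which(ut, arr.ind = TRUE)
  isBond <- !is.na(blen[ut])
  target <- blen[ut]
  obj <- function(x) {
    xy <- matrix(x, n, 3)
    d <- as.matrix(stats::dist(xy))[ut]
    rep_ <- pmax(0, 1.2 - d[!isBond])
    sum((d[isBond] - target[isBond])^2) + sum(rep_^2)
  }
  grad <- function(x) {
    xy <- matrix(x, n, 3)
    diff <- xy[pairs[, 1], , drop = FALSE] - xy[pairs[, 2], , drop = FALSE]
    d <- sqrt(rowSums(diff^2))
    # dE/dd per pair: bonds 2(d - b); nonbonded -2(1.2 - d) when d < 1.2
    co <- ifelse(isBond, 2 * (d - target),
                 ifelse(d < 1.2, -2 * (1.2 - d), 0)) / pmax(d, 1e-12)
    f <- diff * co
    g <- matrix(0, n, 3)
    for (k in seq_len(nrow(pairs))) {
      g[pairs[k, 1], ] <- g[pairs[k, 1], ] + f[k, ]
      g[pairs[k, 2], ] <- g[pairs[k, 2], ] - f[k, ]
    }
    as.numeric(g)
  }
  res <- stats::optim(as.numeric(coords), obj, grad, method = "BFGS",
                      control = list(maxit = 300, reltol = 1e-10))
  matrix(res$par, n, 3)
}

#' Generate a complete synthetic test corpus
#'
#' One call produces a self-consistent, reproducible fixture emulating a
#' radical-rich CHO reference database: the exhaustive molecule
#' enumeration, embedded geometries, surrogate energies, and the
#' single-bond-cleavage reaction network (whose hub species are small
#' fragments, as in real bond-breaking networks). Reaction energies are
#' derived from the surrogate atomization energies, so Hess cycles close
#' exactly at zero label noise.
#'
#' @param maxHeavy maximum heavy atoms (default 4).
#' @param allowRadicals include open-shell species (default TRUE).
#' @param allowRings allow rings (default TRUE).
#' @param params surrogate energy parameters
#'   (\code{\link{surrogateParams}}).
#' @param perturbation geometry noise amplitude, Angstrom.
#' @param seed master seed.
#' @param dir optional output directory; when given, writes
#'   \code{molecules.xyz}, \code{reactions.csv} and
#'   \code{conditions.yaml}.
#' @param refs atomic reference energies.
#' @return list with \code{network} (a \linkS4class{ReactionNetwork}
#'   with energies), \code{graphs} (named list of
#'   \linkS4class{MolGraph} by molecule id), \code{config}, and
#'   \code{files} (paths, when \code{dir} was given).
#' @export
makeFixture <- function(maxHeavy = 4L, allowRadicals = TRUE,
                        allowRings = TRUE, params = surrogateParams(),
                        perturbation = 0, seed = 1L, dir = NULL,
                        refs = defaultAtomicReferences()) {
  graphs <- enumerateMolecules(maxHeavy, allowRadicals, allowRings)
  ids <- .assignIds(graphs)
  names(graphs) <- ids
  mols <- vector("list", length(graphs))
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    m <- embedGeometry(g, id = ids[i], seed = .subSeed(seed, i),
                       amplitude = perturbation)
    en <- surrogateEnergy(g, params, refs)
    m@eAt <- en$eAt
    m@eTotal <- en$eTotal
    mols[[i]] <- m
  }
  molSet <- MoleculeSet(mols)
  rxnTab <- enumerateBondBreaking(graphs)
  aeTable <- stats::setNames(
    vapply(mols, function(m) m@eAt, numeric(1)), ids)
  rxns <- vector("list", nrow(rxnTab))
  for (i in seq_len(nrow(rxnTab))) {
    prods <- c(rxnTab$product1[i], rxnTab$product2[i])
    prods <- prods[!is.na(prods)]
    r <- Reaction(sprintf("rxn_%04d", i), rxnTab$educt[i], prods)
    r@eReac <- reactionEnergy(r, aeTable)
    rxns[[i]] <- r
  }
  network <- ReactionNetwork(molSet, rxns)
  config <- list(maxHeavy = maxHeavy, allowRadicals = allowRadicals,
                 allowRings = allowRings, sigma = params$sigma,
                 radicalPenalty = params$radicalPenalty,
                 perturbation = perturbation, seed = seed)
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- list(molecules = file.path(dir, "molecules.xyz"),
                  reactions = file.path(dir, "reactions.csv"),
                  conditions = file.path(dir, "conditions.yaml"))
    writeMolecules(molSet, files$molecules)
    writeReactions(network, files$reactions)
    yaml::write_yaml(.defaultConditionsConfig(ids, seed), files$conditions)
  }
  list(network = network, graphs = graphs, config = config, files = files)
}

# Unique readable ids: molecular formula, radical count suffix, and a
# letter disambiguating isomers.
.assignIds <- function(graphs) {
  base <- vapply(graphs, function(g) {
    f <- graphFormula(g)
    fv <- sum(g@freeVal)
    if (fv > 0) paste0(f, "_r", fv) else f
  }, character(1))
  ids <- base
  for (b in unique(base[duplicated(base)])) {
    idx <- which(base == b)
    ids[idx] <- sprintf("%s_%02d", b, seq_along(idx))
  }
  unname(ids)
}

# Default microkinetic conditions: equal parts methane and molecular
# oxygen, everything else zero.
.defaultConditionsConfig <- function(ids, seed) {
  init <- list()
  if ("CH4" %in% ids) init[["CH4"]] <- 1.0
  if ("O2" %in% ids) init[["O2"]] <- 1.0
  if (!length(init)) init[[ids[1]]] <- 1.0
  list(temperature = 1000, barrier = 0.5, prefactor = 1,
       initial = init,
       times = as.numeric(10^seq(-2, 6, by = 0.5)),
       flux_threshold = 1e-3, seed = seed)
}
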