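#' @include AllClasses.R reaction-energies.R
NULL

#' Kinetic conditions constructor
#'
#' Defaults emulate an abstract constant-barrier exploration: T = 1000
#' K, barrier 0.5 eV, unit prefactor (time units arbitrary). The
#' simulation is driven solely by the reaction energies through detailed
#' balance and by the law of mass action.
#'
#' @param init named numeric vector of initial concentrations.
#' @param times strictly increasing positive output time grid.
#' @param temperature temperature, K.
#' @param barrier constant activation barrier, eV.
#' @param prefactor rate prefactor, 1/time.
#' @param barrierRule \code{"constant"} or \code{"clipped"} (forward
#'   barrier never below the endothermicity).
#' @param rtol relative tolerance of the stiff integrator.
#' @return a \linkS4class{KineticConditions}.
#' @export
KineticConditions <- function(init, times, temperature = 1000,
                              barrier = 0.5, prefactor = 1,
                              barrierRule = "constant", rtol = 1e-8) {
  new("KineticConditions", temperature = temperature, barrier = barrier,
      prefactor = prefactor, init = init, times = times,
      barrierRule = barrierRule, rtol = rtol)
}

#' Forward/reverse rate constants under a constant barrier
#'
#' Forward: k_fwd = A exp(-Ea0 / kB T). Reverse: k_rev =
#' A exp(-(Ea0 - dE) / kB T), so k_fwd / k_rev = exp(-dE / kB T)
#' (detailed balance with the reaction energy as the thermodynamic
#' driver). The \code{"clipped"} rule instead raises the forward barrier
#' to Ea0 + dE for endothermic reactions, keeping the same equilibrium.
#'
#' @param eReac reaction energy dE (products minus educts), eV; may be a
#'   vector.
#' @param conditions a \linkS4class{KineticConditions}.
#' @return list with numeric vectors \code{kFwd} and \code{kRev}.
#' @export
rateConstants <- function(eReac, conditions) {
  if (any(is.na(eReac))) stop("reaction energy (dE) missing")
  kBT <- .KB_EV * conditions@temperature
  A <- conditions@prefactor
  Ea0 <- conditions@barrier
  if (conditions@barrierRule == "constant") {
    eaF <- rep(Ea0, length(eReac))
  } else {
    eaF <- pmax(Ea0, Ea0 + eReac)
  }
  eaR <- eaF - eReac
  list(kFwd = A * exp(-eaF / kBT), kRev = A * exp(-eaR / kBT))
}

# Precompute index structures for the mass-action RHS.
.kineticSystem <- function(network, conditions, eReac = NULL,
                           reversible = TRUE) {
  mids <- moleculeIds(network)
  rids <- reactionIds(network)
  if (is.null(eReac))
    eReac <- vapply(network@reactions, function(r) r@eReac, numeric(1))
  else eReac <- eReac[rids]
  if (any(is.na(eReac)))
    stop("every reaction needs a reaction energy (reference or predicted)")
  ks <- rateConstants(unname(eReac), conditions)
  if (!reversible) ks$kRev <- ks$kRev * 0
  list(
    speciesIds = mids,
    reactionIds = rids,
    S = .stoichMatrix(network),
    educts = lapply(network@reactions, function(r)
      list(idx = match(names(r@educts), mids), coeff = unname(r@educts))),
    products = lapply(network@reactions, function(r)
      list(idx = match(names(r@products), mids), coeff = unname(r@products))),
    kFwd = ks$kFwd, kRev = ks$kRev
  )
}

.netRates <- function(conc, sys) {
  c0 <- pmax(conc, 0)
  vapply(seq_along(sys$reactionIds), function(j) {
    e <- sys$educts[[j]]; p <- sys$products[[j]]
    sys$kFwd[j] * prod(c0[e$idx]^e$coeff) -
      sys$kRev[j] * prod(c0[p$idx]^p$coeff)
  }, numeric(1))
}

#' Mass-action time derivative of species concentrations
#'
#' Net rate per reaction r = k_fwd prod(c_educt^coeff) -
#' k_rev prod(c_product^coeff); dc/dt = S r with the signed
#' stoichiometric matrix S. Because every reaction balances elements,
#' element totals are conserved analytically.
#'
#' @param conc named concentration vector over all network species.
#' @param network a \linkS4class{ReactionNetwork} with reaction
#'   energies.
#' @param conditions a \linkS4class{KineticConditions}.
#' @return named vector dc/dt in species order.
#' @export
massActionRHS <- function(conc, network, conditions) {
  sys <- .kineticSystem(network, conditions)
  c0 <- stats::setNames(numeric(length(sys$speciesIds)), sys$speciesIds)
  c0[names(conc)] <- conc
  r <- .netRates(c0, sys)
  stats::setNames(as.numeric(sys$S %*% r), sys$speciesIds)
}

#' Integrate a reaction network in time
#'
#' Stiff-capable implicit integration (lsoda) of the mean-field
#' mass-action ODEs, accumulating per-reaction cumulative flux
#' integral |net rate| dt alongside the state. Species absent from
#' \code{init} start at zero.
#'
#' @param network a \linkS4class{ReactionNetwork}.
#' @param conditions a \linkS4class{KineticConditions}.
#' @param eReac optional named vector of reaction energies overriding
#'   the reactions' own (e.g. ML-predicted REs).
#' @param reversible set \code{FALSE} to zero all reverse rates
#'   (irreversible forward-only kinetics, mainly for closed-form
#'   checks).
#' @return a \linkS4class{Trajectory}.
#' @export
integrateNetwork <- function(network, conditions, eReac = NULL,
                             reversible = TRUE) {
  sys <- .kineticSystem(network, conditions, eReac, reversible)
  ns <- length(sys$speciesIds); nr <- length(sys$reactionIds)
  unknown <- setdiff(names(conditions@init), sys$speciesIds)
  if (length(unknown))
    stop(sprintf("initial concentration for unknown species: %s",
                 paste(unknown, collapse = ", ")))
  y0 <- stats::setNames(numeric(ns), sys$speciesIds)
  y0[names(conditions@init)] <- conditions@init
  state0 <- c(y0, numeric(nr))
  times <- unique(c(0, conditions@times))
  rhs <- function(t, y, parms) {
    r <- .netRates(y[seq_len(ns)], sys)
    list(c(as.numeric(sys$S %*% r), abs(r)))
  }
  sol <- deSolve::lsoda(state0, times, rhs, parms = NULL,
                        rtol = conditions@rtol,
                        atol = conditions@rtol * 1e-4)
  if (attr(sol, "istate")[1] < 0)
    stop(sprintf("ODE solver failed at t = %.6g", sol[nrow(sol), 1]))
  conc <- sol[, 1 + seq_len(ns), drop = FALSE]
  if (min(conc) < -1e-9)
    stop(sprintf("negative concentration %.3g beyond tolerance at t = %.6g",
                 min(conc), sol[which(conc == min(conc), arr.ind = TRUE)[1], 1]))
  if (any(conc < 0)) {
    warning("clipping tiny negative concentrations (> -1e-9) to zero")
    conc[conc < 0] <- 0
  }
  flux <- sol[, 1 + ns + seq_len(nr), drop = FALSE]
  flux <- apply(flux, 2, cummax)   # enforce monotonicity against round-off
  if (nr == 1L) flux <- matrix(flux, ncol = 1L)
  colnames(conc) <- sys$speciesIds
  colnames(flux) <- sys$reactionIds
  new("Trajectory", times = sol[, 1], concentrations = conc, fluxes = flux,
      network = network, conditions = conditions)
}

setMethod("show", "Trajectory", function(object) {
  cat(sprintf(
    "Trajectory: %d time points, %d species, %d reactions (t in [%g, %g])\n",
    length(object@times), ncol(object@concentrations),
    ncol(object@fluxes), min(object@times), max(object@times)))
})

#' Element totals along a trajectory
#'
#' @param trajectory a \linkS4class{Trajectory}.
#' @return matrix time x element of total element amounts; constant to
#'   the solver tolerance for any balanced network.
#' @export
elementTotals <- function(trajectory) {
  mols <- trajectory@network@molecules@molecules
  species <- colnames(trajectory@concentrations)
  els <- sort(unique(unlist(lapply(mols[species], function(m) m@elements))))
  comp <- t(vapply(species, function(id) {
    tab <- .elementCounts(mols[[id]]@elements)
    vapply(els, function(e) if (e %in% names(tab)) as.numeric(tab[[e]]) else 0,
           numeric(1))
  }, numeric(length(els))))
  out <- trajectory@concentrations %*% comp
  colnames(out) <- els
  out
}

#' First-access times of reactions and species
#'
#' A reaction is "accessed" at the first grid time where its cumulative
#' flux exceeds \code{threshold} times the instantaneous maximum
#' cumulative flux over all reactions; a species is accessed when its
#' first incident reaction is (or at t = 0 if initially present).
#'
#' @param trajectory a \linkS4class{Trajectory}.
#' @param threshold relative flux threshold in (0, 1]; default 1e-3.
#' @return list with named numeric vectors \code{reactions} and
#'   \code{species} of first-access times (NA if never accessed).
#' @export
firstAccessTimes <- function(trajectory, threshold = 1e-3) {
  if (threshold <= 0) stop("threshold must be > 0")
  flux <- trajectory@fluxes
  times <- trajectory@times
  maxFlux <- apply(flux, 1, max)
  accessed <- flux > threshold * maxFlux   # time x reaction
  firstRxn <- apply(accessed, 2, function(col) {
    i <- which(col)[1]
    if (is.na(i)) NA_real_ else times[i]
  })
  net <- trajectory@network
  init0 <- trajectory@concentrations[1, ]
  firstSp <- stats::setNames(rep(NA_real_, ncol(trajectory@concentrations)),
                             colnames(trajectory@concentrations))
  firstSp[init0 > 0] <- 0
  for (r in net@reactions) {
    tr <- firstRxn[[r@id]]
    if (is.na(tr)) next
    for (sp in unique(c(names(r@educts), names(r@products))))
      firstSp[sp] <- min(firstSp[sp], tr, na.rm = TRUE)
  }
  list(reactions = firstRxn, species = firstSp)
}

#' Reduced reaction network at a simulation time
#'
#' Sub-network of all reactions accessed by time \code{t} (see
#' \code{\link{firstAccessTimes}}) plus all their species. Because
#' access is defined by first crossing, the sub-networks are nested in
#' time for a fixed threshold.
#'
#' @param trajectory a \linkS4class{Trajectory}.
#' @param t time within the trajectory grid.
#' @param threshold relative flux threshold.
#' @return a \linkS4class{ReactionNetwork} (possibly empty).
#' @export
reducedNetworkAt <- function(trajectory, t, threshold = 1e-3) {
  if (t < min(trajectory@times) || t > max(trajectory@times))
    stop("t outside the trajectory time grid")
  fa <- firstAccessTimes(trajectory, threshold)
  keep <- names(fa$reactions)[!is.na(fa$reactions) & fa$reactions <= t]
  rxns <- trajectory@network@reactions[keep]
  species <- unique(unlist(lapply(rxns, function(r)
    c(names(r@educts), names(r@products)))))
  ReactionNetwork(trajectory@network@molecules[species %||% character(0)],
                  rxns)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Growth sequence of reduced networks
#'
#' @param trajectory a \linkS4class{Trajectory}.
#' @param times strictly increasing times at which to extract reduced
#'   networks.
#' @param threshold relative flux threshold.
#' @return list with \code{networks} (one \linkS4class{ReactionNetwork}
#'   per time, nested), \code{times}, and the \code{firstAccess} record
#'   of per-reaction/per-species first-access times.
#' @export
growthSequence <- function(trajectory, times, threshold = 1e-3) {
  if (length(times) > 1L && is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  nets <- lapply(times, reducedNetworkAt, trajectory = trajectory,
                 threshold = threshold)
  list(networks = nets, times = times,
       firstAccess = firstAccessTimes(trajectory, threshold))
}

#' Export a reduced-network growth sequence as GraphML
#'
#' Writes the final network's bipartite graph with per-node/edge
#' first-access-time attributes, for rendering time-resolved network
#' growth.
#'
#' @param growth output of \code{\link{growthSequence}}.
#' @param path GraphML output path.
#' @return invisibly \code{path}.
#' @export
writeGrowthGraphML <- function(growth, path) {
  nets <- growth$networks
  final <- nets[[length(nets)]]
  g <- .networkToIgraph(final)
  fa <- growth$firstAccess
  vn <- igraph::V(g)$name
  tAcc <- ifelse(vn %in% names(fa$species), fa$species[vn], fa$reactions[vn])
  igraph::V(g)$first_access <- as.numeric(tAcc)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
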