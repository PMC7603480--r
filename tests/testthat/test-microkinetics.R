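# Minimal two-isomer network A <-> B with a prescribed reaction energy.
isomerNetwork <- function(dE, id = c("A", "B")) {
  coords <- function(s) rbind(c(0, 0, 0), c(0, 0, 1.2 + s))
  mols <- list(Molecule(id[1], c("O", "O"), coords(0)),
               Molecule(id[2], c("O", "O"), coords(0.1)))
  r <- Reaction("ab", id[1], id[2], eReac = dE)
  ReactionNetwork(mols, list(r))
}

kB <- 8.617333262e-5

test_that("rate constants satisfy detailed balance closed forms", {
  cond <- KineticConditions(init = c(A = 1), times = 1,
                            temperature = 1000, barrier = 0.5, prefactor = 1)
  # thermoneutral: forward equals reverse
  k0 <- rateConstants(0, cond)
  expect_equal(k0$kFwd, k0$kRev)
  # dE = -kB T ln 10 makes the equilibrium constant exactly 10
  k10 <- rateConstants(-kB * 1000 * log(10), cond)
  expect_equal(k10$kFwd / k10$kRev, 10, tolerance = 1e-12)
  # scalar evaluation against an independent constants source
  expect_equal(k0$kFwd, exp(-0.5 / (8.617e-5 * 1000)), tolerance = 1e-3)
  expect_error(rateConstants(NA_real_, cond), "missing")
  # clipped rule: endothermic forward barrier is raised, equilibrium kept
  condC <- KineticConditions(init = c(A = 1), times = 1, barrierRule = "clipped")
  kc <- rateConstants(0.3, condC)
  expect_equal(kc$kFwd, exp(-(0.5 + 0.3) / (kB * 1000)), tolerance = 1e-12)
  expect_equal(kc$kFwd / kc$kRev, exp(-0.3 / (kB * 1000)), tolerance = 1e-12)
})

test_that("mass-action derivative vanishes at equilibrium and conserves mass", {
  dE <- -0.1
  net <- isomerNetwork(dE)
  cond <- KineticConditions(init = c(A = 1), times = 1)
  expect_equal(unname(massActionRHS(c(A = 0, B = 0), net, cond)), c(0, 0))
  Keq <- exp(-dE / (kB * 1000))
  eq <- c(A = 1, B = Keq)
  rhs <- massActionRHS(eq, net, cond)
  expect_lt(max(abs(rhs)), 1e-12)
  # off equilibrium, element totals still conserved: dA/dt = -dB/dt
  rhs2 <- massActionRHS(c(A = 1, B = 0), net, cond)
  expect_equal(rhs2[["A"]], -rhs2[["B"]])
})

test_that("integration reaches the Boltzmann ratio for an isomer pair", {
  dE <- -0.1
  net <- isomerNetwork(dE)
  cond <- KineticConditions(init = c(A = 1), times = 10^seq(-2, 4, 0.5))
  traj <- integrateNetwork(net, cond)
  cEnd <- traj@concentrations[nrow(traj@concentrations), ]
  expect_equal(cEnd[["B"]] / cEnd[["A"]], exp(0.1 / (kB * 1000)),
               tolerance = 1e-3)
})

test_that("irreversible first-order decay matches the exponential solution", {
  net <- isomerNetwork(-0.2)
  cond <- KineticConditions(init = c(A = 1), times = c(0.5, 1, 2, 4))
  traj <- integrateNetwork(net, cond, reversible = FALSE)
  kf <- rateConstants(-0.2, cond)$kFwd
  expect_equal(traj@concentrations[, "A"],
               exp(-kf * traj@times), tolerance = 1e-3,
               ignore_attr = TRUE)
  # finite-difference of the trajectory is consistent with the RHS
  i <- 3
  dt <- 1e-3 * traj@times[i]
  c1 <- traj@concentrations[i, ]
  rhs <- massActionRHS(c1, net, cond)
  # A decays at kf*c_A under irreversible kinetics; the reversible RHS
  # differs only by the (here tiny) reverse term
  expect_equal(rhs[["A"]], -kf * c1[["A"]] + rateConstants(-0.2, cond)$kRev *
                 c1[["B"]], tolerance = 1e-10)
})

test_that("element totals stay constant along a fixture trajectory", {
  fx <- cachedFixture(2)
  cond <- KineticConditions(init = c(CH4 = 1, O2 = 1),
                            times = 10^seq(-2, 3, 0.5))
  traj <- integrateNetwork(fx$network, cond)
  tot <- elementTotals(traj)
  drift <- apply(tot, 2, function(x) max(abs(x - x[1])) / max(abs(x[1]), 1))
  expect_lt(max(drift), 1e-6)
  expect_gte(min(traj@concentrations), 0)
})

test_that("tightening the solver tolerance leaves final state stable", {
  fx <- cachedFixture(2)
  mk <- function(rtol) {
    cond <- KineticConditions(init = c(CH4 = 1, O2 = 1),
                              times = 10^seq(-2, 2, 0.5), rtol = rtol)
    traj <- integrateNetwork(fx$network, cond)
    traj@concentrations[nrow(traj@concentrations), ]
  }
  expect_lt(max(abs(mk(1e-8) - mk(5e-9))), 10 * 1e-8)
})

test_that("reduced networks grow as nested sub-networks over time", {
  fx <- cachedFixture(2)
  cond <- KineticConditions(init = c(CH4 = 1, O2 = 1),
                            times = 10^seq(-2, 3, 0.25))
  traj <- integrateNetwork(fx$network, cond)
  expect_equal(length(reactions(reducedNetworkAt(traj, 0))), 0L)
  expect_equal(length(reactions(reducedNetworkAt(traj, max(traj@times),
                                                 threshold = 1.5))), 0L)
  ts <- 10^seq(-1, 3, 1)
  gr <- growthSequence(traj, ts)
  sizes <- vapply(gr$networks, function(n) length(reactions(n)), integer(1))
  for (i in seq_len(length(ts) - 1)) {
    expect_true(all(reactionIds(gr$networks[[i]]) %in%
                      reactionIds(gr$networks[[i + 1]])))
    expect_true(all(moleculeIds(gr$networks[[i]]) %in%
                      moleculeIds(gr$networks[[i + 1]])))
  }
  expect_gt(sizes[length(sizes)], 0)
  expect_error(growthSequence(traj, c(2, 1)), "increasing")
  expect_error(reducedNetworkAt(traj, 2 * max(traj@times)), "outside")
})

test_that("a slow second step delays access in a three-species chain", {
  coords <- function(s) rbind(c(0, 0, 0), c(0, 0, 1.2 + s))
  mols <- list(Molecule("A", c("O", "O"), coords(0)),
               Molecule("B", c("O", "O"), coords(0.1)),
               Molecule("C", c("O", "O"), coords(0.2)))
  # A -> B fast (very exothermic), B -> C slow (endothermic)
  net <- ReactionNetwork(mols, list(
    Reaction("ab", "A", "B", eReac = -0.5),
    Reaction("bc", "B", "C", eReac = +0.4)))
  cond <- KineticConditions(init = c(A = 1), times = 10^seq(-3, 5, 0.25))
  traj <- integrateNetwork(net, cond)
  fa <- firstAccessTimes(traj, threshold = 1e-3)
  expect_lt(fa$reactions[["ab"]], fa$reactions[["bc"]])
  early <- reducedNetworkAt(traj, fa$reactions[["ab"]], 1e-3)
  expect_identical(reactionIds(early), "ab")
  # species appear in mechanistic order: A (initial), B, then C
  expect_equal(fa$species[["A"]], 0)
  expect_lte(fa$species[["B"]], fa$reactions[["bc"]])
  expect_gte(fa$species[["C"]], fa$reactions[["bc"]])
})
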