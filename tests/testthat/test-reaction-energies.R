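test_that("reaction energies compose atomization energies by Hess's law", {
  r <- Reaction("r1", "A", c("B", "C"))
  expect_equal(reactionEnergy(r, c(A = -10, B = -4, C = -3)), 3)
  expect_equal(reactionEnergy(Reaction("id", "A", "A"), c(A = -7)), 0)
  expect_error(reactionEnergy(r, c(A = -10, B = -4)), "C")
  # stoichiometric coefficients: H2O2 -> 2 OH
  r2 <- Reaction("r2", "H2O2", c("OH", "OH"))
  expect_equal(r2@products, c(OH = 2L))
  expect_equal(reactionEnergy(r2, c(H2O2 = -11.1, OH = -4.8)), 1.5,
               tolerance = 1e-12)
  # antisymmetry: reversing a reaction negates its energy
  fwd <- Reaction("f", "A", c("B", "C"))
  rev <- Reaction("b", c("B", "C"), "A")
  ae <- c(A = -10.3, B = -4.1, C = -2.2)
  expect_equal(reactionEnergy(fwd, ae), -reactionEnergy(rev, ae))
})

test_that("single-bond cleavage REs equal the surrogate bond parameter", {
  fx <- cachedFixture(3)
  net <- fx$network
  # CH4 -> CH3 + H cleaves one C-H bond; penalty applies to CH3 only
  ae <- vapply(molecules(net)@molecules, function(m) m@eAt, numeric(1))
  rxn <- Filter(function(r) identical(names(r@educts), "CH4") &&
                  "H_r1" %in% names(r@products), reactions(net))[[1]]
  expect_equal(reactionEnergy(rxn, ae), 4.3 + 0.3, tolerance = 1e-12)
  # H2O2 -> 2 OH cleaves the O-O bond; both fragments carry the penalty
  rxn2 <- Filter(function(r) identical(names(r@educts), "H2O2"),
                 reactions(net))
  oo <- Filter(function(r) identical(r@products, c(HO_r1 = 2L)), rxn2)[[1]]
  expect_equal(reactionEnergy(oo, ae), 1.5 + 2 * 0.3, tolerance = 1e-12)
})

test_that("network RE prediction caches one AE per molecule", {
  fx <- cachedFixture(2)
  molSet <- molecules(fx$network)
  desc <- cachedDescriptors(2)
  model <- trainKRR(molSet, desc, moleculeIds(molSet), 1e-10, "intensive")
  rep <- predictNetworkRE(fx$network, model, desc)
  # per-reaction recomputation oracle from the stored AE table
  for (r in reactions(fx$network)) {
    expect_equal(
      rep@predictions$e_reac_pred[rep@predictions$reaction_id == r@id],
      reactionEnergy(r, rep@aeTable), tolerance = 1e-12)
  }
  # one AE per molecule, shared across incident reactions
  expect_identical(sort(names(rep@aeTable)), sort(moleculeIds(fx$network)))
  # order of reactions does not matter
  shuffled <- ReactionNetwork(molSet, rev(reactions(fx$network)))
  rep2 <- predictNetworkRE(shuffled, model, desc)
  expect_equal(rep2@aeTable, rep@aeTable)
})

test_that("hub AE perturbations propagate degree-fold into the RE MAE", {
  fx <- cachedFixture(2)
  net <- fx$network
  ae <- vapply(molecules(net)@molecules, function(m) m@eAt, numeric(1))
  hub <- names(which.max(speciesDegree(net)))
  delta <- 0.25
  aePert <- ae
  aePert[hub] <- aePert[hub] + delta
  reTrue <- vapply(reactions(net), reactionEnergy, numeric(1), aeTable = ae)
  rePert <- vapply(reactions(net), reactionEnergy, numeric(1),
                   aeTable = aePert)
  changed <- abs(rePert - reTrue) > 1e-12
  incident <- vapply(reactions(net), function(r)
    hub %in% c(names(r@educts), names(r@products)), logical(1))
  expect_identical(unname(changed), unname(incident))
  # each incident RE moves by +/- delta * coefficient
  for (r in reactions(net)[incident]) {
    coeff <- sum(r@products[names(r@products) == hub]) -
      sum(r@educts[names(r@educts) == hub])
    expect_equal(unname(rePert[r@id] - reTrue[r@id]), delta * coeff,
                 tolerance = 1e-12)
  }
  # MAE_RE from a single perturbed hub is delta * degree / m
  m <- length(reactions(net))
  d <- sum(abs(vapply(reactions(net)[incident], function(r)
    sum(r@products[names(r@products) == hub]) -
      sum(r@educts[names(r@educts) == hub]), numeric(1))))
  expect_equal(mean(abs(rePert - reTrue)), delta * d / m, tolerance = 1e-12)
})

test_that("uncertainty propagation follows the sqrt(n-species) law", {
  out <- propagateAEUncertainty(1, nSpecies = 3, nMC = 1e6, seed = 2)
  expect_equal(out$analytic, sqrt(3), tolerance = 1e-12)
  expect_lt(abs(out$mc - sqrt(3)), 0.005)
  expect_equal(propagateAEUncertainty(0, 3, 1e4, 1)$mc, 0)
  out4 <- propagateAEUncertainty(1, nSpecies = 4, nMC = 1e6, seed = 3)
  expect_equal(out4$analytic, 2, tolerance = 1e-12)
  expect_lt(abs(out4$mc - 2), 3 * out4$se * 2)
})

test_that("AE/RE error report flags training overlap and perfect models", {
  fx <- cachedFixture(2)
  molSet <- molecules(fx$network)
  desc <- cachedDescriptors(2)
  model <- trainKRR(molSet, desc, moleculeIds(molSet), 1e-12, "intensive")
  rep <- aeReErrorReport(fx$network, model, desc)
  expect_lt(rep$maeAE, 1e-5)
  expect_lt(rep$maeRE, 1e-4)
  expect_equal(rep$trainingOverlap, 1)
  half <- moleculeIds(molSet)[seq_len(10)]
  model2 <- trainKRR(molSet, desc, half, 1e-8, "intensive")
  rep2 <- aeReErrorReport(fx$network, model2, desc)
  expect_equal(rep2$trainingOverlap, 10 / length(moleculeIds(molSet)))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  writeREReport(rep2, csv, js)
  tab <- read.csv(csv)
  expect_setequal(tab$reaction_id, reactionIds(fx$network))
  summ <- jsonlite::read_json(js)
  expect_equal(summ$mae_ae, rep2$maeAE, tolerance = 1e-12)
})

test_that("cycle sums vanish for REs derived from one AE table", {
  # A -> B, B -> C, A -> C triangle (element-balanced isomer chain)
  coords <- function(s) matrix(c(0, 0, 0, 0, 0, 1.2 + s), 2, 3, byrow = TRUE)
  mols <- list(Molecule("A", c("O", "O"), coords(0)),
               Molecule("B", c("O", "O"), coords(0.1)),
               Molecule("C", c("O", "O"), coords(0.2)))
  net <- ReactionNetwork(mols, list(
    Reaction("ab", "A", "B"), Reaction("bc", "B", "C"),
    Reaction("ac", "A", "C")))
  ae <- c(A = -5.2, B = -5.05, C = -4.6)
  re <- vapply(reactions(net), reactionEnergy, numeric(1), aeTable = ae)
  expect_lt(cycleConsistency(net, re), 1e-10)
  # acyclic network is vacuously consistent
  net2 <- ReactionNetwork(mols, list(Reaction("ab", "A", "B")))
  expect_equal(cycleConsistency(net2, re["ab"]), 0)
  # a fixture network with shared fragments has null-space cycles
  fx <- cachedFixture(3)
  ae3 <- vapply(molecules(fx$network)@molecules, function(m) m@eAt,
                numeric(1))
  re3 <- vapply(reactions(fx$network), reactionEnergy, numeric(1),
                aeTable = ae3)
  expect_lt(cycleConsistency(fx$network, re3), 1e-9)
  # an inconsistent table is caught (triangle: residual 0.5/sqrt(3))
  reBadTri <- re
  reBadTri["ab"] <- reBadTri["ab"] + 0.5
  expect_gt(cycleConsistency(net, reBadTri), 0.2)
})
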