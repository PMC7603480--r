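#' @include AllClasses.R learning.R
NULL

# Signed stoichiometric matrix, species x reactions (products positive).
.stoichMatrix <- function(network) {
  mids <- moleculeIds(network)
  rids <- reactionIds(network)
  S <- matrix(0, length(mids), length(rids), dimnames = list(mids, rids))
  for (r in network@reactions) {
    S[names(r@educts), r@id] <- S[names(r@educts), r@id] - r@educts
    S[names(r@products), r@id] <- S[names(r@products), r@id] + r@products
  }
  S
}

#' Reaction energy from atomization energies (Hess's law)
#'
#' E_reac = sum_products c * AE - sum_educts c * AE. Because reaction
#' energies are differences of per-molecule atomization energies,
#' thermodynamic cycles close exactly whenever one consistent AE table
#' is used.
#'
#' @param reaction a \linkS4class{Reaction}.
#' @param aeTable named numeric vector, molecule id -> AE (eV).
#' @return reaction energy, eV.
#' @examples
#' r <- Reaction("r1", "A", c("B", "C"))
#' reactionEnergy(r, c(A = -10, B = -4, C = -3))  # +3
#' @export
reactionEnergy <- function(reaction, aeTable) {
  species <- c(names(reaction@educts), names(reaction@products))
  missing <- setdiff(species, names(aeTable))
  if (length(missing))
    stop(sprintf("reaction '%s': no AE for molecule(s): %s", reaction@id,
                 paste(missing, collapse = ", ")))
  sum(reaction@products * aeTable[names(reaction@products)]) -
    sum(reaction@educts * aeTable[names(reaction@educts)])
}

#' Predict all reaction energies of a network
#'
#' Each molecule's atomization energy is predicted exactly once and the
#' single value is reused across all reactions it takes part in. Hub
#' molecules (high-degree fragments) therefore couple the errors of all
#' their incident reactions -- the mechanism that makes training-set
#' coverage of small fragments decisive for reaction-energy accuracy.
#'
#' @param network a \linkS4class{ReactionNetwork} whose molecules carry
#'   geometries.
#' @param model a trained \linkS4class{KRRModel}.
#' @param descSet optional precomputed \linkS4class{DescriptorSet} for
#'   the network molecules; computed from the model's parameters when
#'   omitted.
#' @param sigmaAE optional assumed per-AE uncertainty (eV), stored for
#'   reporting.
#' @return an \linkS4class{REPredictionSet}.
#' @export
predictNetworkRE <- function(network, model, descSet = NULL,
                             sigmaAE = NA_real_) {
  if (is.null(descSet))
    descSet <- computeDescriptors(network@molecules,
                                  model@trainDescriptors@params)
  aeTable <- predictAE(model, descSet)
  .rePredictionSet(network, aeTable, sigmaAE)
}

# Build the prediction table from one consistent AE table.
.rePredictionSet <- function(network, aeTable, sigmaAE = NA_real_) {
  re <- vapply(network@reactions, reactionEnergy, numeric(1),
               aeTable = aeTable)
  df <- data.frame(reaction_id = reactionIds(network), e_reac_pred = re,
                   stringsAsFactors = FALSE, row.names = NULL)
  ref <- vapply(network@reactions, function(r) r@eReac, numeric(1))
  if (any(!is.na(ref))) {
    df$e_reac_ref <- unname(ref)
    df$abs_error <- abs(df$e_reac_pred - df$e_reac_ref)
  }
  new("REPredictionSet", predictions = df, aeTable = aeTable,
      sigmaAE = sigmaAE)
}

setValidity("REPredictionSet", function(object) {
  ok <- TRUE
  df <- object@predictions
  if (!all(c("reaction_id", "e_reac_pred") %in% names(df)))
    ok <- "predictions must have reaction_id and e_reac_pred columns"
  ok
})

setMethod("show", "REPredictionSet", function(object) {
  cat(sprintf("REPredictionSet: %d reactions from %d molecular AEs\n",
              nrow(object@predictions), length(object@aeTable)))
})

#' Monte-Carlo propagation of a constant AE uncertainty
#'
#' Under an uncorrelated constant per-AE uncertainty sigma, the standard
#' deviation of a reaction energy over nSpecies participating molecules
#' is sqrt(nSpecies) * sigma (sqrt(3) * sigma for A -> B + C). The
#' Monte-Carlo estimate is returned next to the closed form.
#'
#' @param sigmaAE per-AE uncertainty, eV (>= 0).
#' @param nSpecies number of distinct species in the reaction (3 for
#'   A -> B + C).
#' @param nMC Monte-Carlo sample size.
#' @param seed RNG seed.
#' @return list with \code{mc} (sampled sigma_RE), \code{analytic}
#'   (sqrt(nSpecies) * sigmaAE) and \code{se} (standard error of the MC
#'   estimate).
#' @export
propagateAEUncertainty <- function(sigmaAE, nSpecies = 3L, nMC = 1e6,
                                   seed = 1L) {
  if (sigmaAE < 0) stop("sigmaAE must be >= 0")
  analytic <- sqrt(nSpecies) * sigmaAE
  if (sigmaAE == 0)
    return(list(mc = 0, analytic = 0, se = 0))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  perturb <- matrix(stats::rnorm(nSpecies * nMC, sd = sigmaAE),
                    nrow = nSpecies)
  s <- stats::sd(colSums(perturb))
  # sd of the sd estimator for Gaussian samples
  list(mc = s, analytic = analytic, se = analytic / sqrt(2 * (nMC - 1)))
}

#' Joint AE/RE error report over a network
#'
#' Computes the molecular AE MAE and the network RE MAE with one shared
#' AE prediction table (caching contract), and reports which fraction of
#' the network molecules was part of the model's training set: when the
#' overlap is nonzero the RE figures are not a pure out-of-sample
#' prediction.
#'
#' @param network a \linkS4class{ReactionNetwork} whose molecules carry
#'   reference atomization energies and (optionally) whose reactions
#'   carry reference reaction energies.
#' @param model a trained \linkS4class{KRRModel}.
#' @param descSet optional precomputed descriptors.
#' @return list with \code{maeAE}, \code{maeRE},
#'   \code{trainingOverlap} (fraction of network molecules in the
#'   training set) and the underlying \code{rePredictions}.
#' @export
aeReErrorReport <- function(network, model, descSet = NULL) {
  rep <- predictNetworkRE(network, model, descSet)
  aeRef <- vapply(network@molecules@molecules, function(m) m@eAt, numeric(1))
  if (any(is.na(aeRef)))
    stop("all network molecules need reference atomization energies")
  maeAE <- mean(abs(rep@aeTable[names(aeRef)] - aeRef))
  reRef <- vapply(network@reactions, function(r) r@eReac, numeric(1))
  if (any(is.na(reRef))) {
    # derive reference REs from the reference AE table (Hess's law)
    reRef <- vapply(network@reactions, reactionEnergy, numeric(1),
                    aeTable = aeRef)
  }
  maeRE <- mean(abs(rep@predictions$e_reac_pred - unname(reRef)))
  overlap <- length(intersect(model@trainIds, moleculeIds(network))) /
    length(moleculeIds(network))
  list(maeAE = maeAE, maeRE = maeRE, trainingOverlap = overlap,
       rePredictions = rep)
}

#' Write an RE report (CSV + JSON summary)
#'
#' @param report output of \code{\link{aeReErrorReport}}.
#' @param csvPath per-reaction CSV path.
#' @param jsonPath summary JSON path (MAE_AE, MAE_RE, training overlap).
#' @return invisibly \code{csvPath}.
#' @export
writeREReport <- function(report, csvPath, jsonPath = NULL) {
  utils::write.csv(report$rePredictions@predictions, csvPath,
                   row.names = FALSE, quote = FALSE)
  if (!is.null(jsonPath)) {
    jsonlite::write_json(
      list(mae_ae = report$maeAE, mae_re = report$maeRE,
           training_overlap = report$trainingOverlap),
      jsonPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(csvPath)
}

#' Hess-cycle consistency of network RE predictions
#'
#' Every vector in the null space of the signed stoichiometric matrix is
#' a (generalized) reaction cycle; reaction energies derived from one AE
#' table must sum to zero along each. Returns the largest absolute
#' weighted cycle sum -- a regression guard against AE-caching bugs.
#'
#' @param network a \linkS4class{ReactionNetwork}.
#' @param rePred an \linkS4class{REPredictionSet} or named numeric
#'   vector of reaction energies in \code{reactionIds(network)} order.
#' @return maximum absolute cycle residual (0 for acyclic networks).
#' @export
cycleConsistency <- function(network, rePred) {
  re <- if (is(rePred, "REPredictionSet"))
    stats::setNames(rePred@predictions$e_reac_pred,
                    rePred@predictions$reaction_id)
  else rePred
  re <- re[reactionIds(network)]
  S <- .stoichMatrix(network)
  if (!ncol(S)) return(0)
  sv <- svd(S, nu = 0, nv = ncol(S))
  tol <- max(dim(S)) * max(sv$d, 0) * .Machine$double.eps
  dpad <- c(sv$d, rep(0, ncol(S) - length(sv$d)))
  null <- sv$v[, dpad < tol, drop = FALSE]
  if (!ncol(null)) return(0)
  max(abs(crossprod(null, re)))
}
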