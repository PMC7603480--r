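#' @include synthetic-fixture.R learning.R microkinetics.R
NULL

#' Read a run configuration file
#'
#' YAML with any of the keys consumed by the \code{run*} pipeline
#' entry points; unknown keys are rejected so typos fail loudly.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("molecules", "reactions", "output_dir", "energy_key",
             "r_cut", "sigma_r", "n_bins", "zeta", "elements",
             "kernel_mode", "selection_mode", "sizes", "lambda",
             "lambda_grid", "zeta_grid", "test_fraction", "val_fraction",
             "max_heavy", "allow_radicals", "allow_rings", "sigma",
             "radical_penalty", "perturbation", "temperature", "barrier",
             "prefactor", "initial", "times", "flux_threshold", "seed",
             "model")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  cfg
}

.cfgGet <- function(cfg, key, default) {
  if (!is.null(cfg[[key]])) cfg[[key]] else default
}

.cfgDescriptorParams <- function(cfg) {
  DescriptorParams(
    rCut = .cfgGet(cfg, "r_cut", 4.0),
    sigmaR = .cfgGet(cfg, "sigma_r", 0.3),
    nBins = .cfgGet(cfg, "n_bins", 24L),
    elements = .cfgGet(cfg, "elements", c("C", "H", "O")),
    zeta = .cfgGet(cfg, "zeta", 2))
}

.writeManifest <- function(outDir, command, cfg, extra = list()) {
  inputs <- Filter(function(p) is.character(p) && length(p) == 1 &&
                     file.exists(p),
                   cfg[c("molecules", "reactions", "model")])
  md5 <- if (length(inputs))
    as.list(tools::md5sum(unname(unlist(inputs)))) else list()
  manifest <- c(list(command = command, seed = .cfgGet(cfg, "seed", 1L),
                     config = cfg, input_md5 = md5),
                extra)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Generate a fixture corpus from a configuration
#'
#' @param config list (or YAML path) with \code{max_heavy},
#'   \code{allow_radicals}, \code{allow_rings}, \code{sigma},
#'   \code{radical_penalty}, \code{perturbation}, \code{seed} and
#'   \code{output_dir}.
#' @return the \code{\link{makeFixture}} result, invisibly.
#' @export
runFixture <- function(config) {
  cfg <- if (is.character(config)) readRunConfig(config) else config
  outDir <- .cfgGet(cfg, "output_dir", ".")
  fx <- makeFixture(
    maxHeavy = .cfgGet(cfg, "max_heavy", 4L),
    allowRadicals = .cfgGet(cfg, "allow_radicals", TRUE),
    allowRings = .cfgGet(cfg, "allow_rings", TRUE),
    params = surrogateParams(sigma = .cfgGet(cfg, "sigma", 0),
                             radicalPenalty = .cfgGet(cfg, "radical_penalty", 0.3),
                             seed = .cfgGet(cfg, "seed", 1L)),
    perturbation = .cfgGet(cfg, "perturbation", 0),
    seed = .cfgGet(cfg, "seed", 1L), dir = outDir)
  .writeManifest(outDir, "fixture", cfg,
                 list(n_molecules = length(fx$graphs),
                      n_reactions = length(fx$network@reactions)))
  invisible(fx)
}

#' Train an atomization-energy model and write its learning curve
#'
#' Splits the dataset (seeded random test split, default 20 percent),
#' selects training molecules per \code{selection_mode}, trains KRR
#' models at the requested sizes and writes \code{learning_curve.csv}
#' plus the final \code{model.rds} archive to \code{output_dir}.
#'
#' @param config list or YAML path; see \code{\link{readRunConfig}}.
#' @return list with \code{model}, \code{curve} and \code{paths},
#'   invisibly.
#' @export
runTrain <- function(config) {
  cfg <- if (is.character(config)) readRunConfig(config) else config
  outDir <- .cfgGet(cfg, "output_dir", ".")
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  seed <- .cfgGet(cfg, "seed", 1L)
  molSet <- readMolecules(cfg$molecules,
                          energyKey = .cfgGet(cfg, "energy_key", "energy"))
  haveAE <- vapply(molSet@molecules, function(m) !is.na(m@eAt), logical(1))
  if (!all(haveAE)) {
    refs <- defaultAtomicReferences()
    molSet <- MoleculeSet(lapply(molSet@molecules, function(m) {
      if (is.na(m@eAt) && !is.na(m@eTotal))
        m@eAt <- atomizationEnergy(m@eTotal, m@elements, refs)
      m
    }))
  }
  params <- .cfgDescriptorParams(cfg)
  descSet <- computeDescriptors(molSet, params)
  ids <- moleculeIds(molSet)
  nTest <- max(1L, round(.cfgGet(cfg, "test_fraction", 0.2) * length(ids)))
  testIds <- randomSelect(ids, nTest, seed = seed)
  poolIds <- setdiff(ids, testIds)
  sizes <- .cfgGet(cfg, "sizes",
                   unique(pmin(c(25, 50, 100, 200), length(poolIds))))
  curve <- learningCurve(
    molSet, descSet,
    selectionMode = .cfgGet(cfg, "selection_mode", "fps_intensive"),
    kernelMode = .cfgGet(cfg, "kernel_mode", "intensive"),
    sizes = sizes, testIds = testIds, poolIds = poolIds,
    lambda = .cfgGet(cfg, "lambda", 1e-8),
    zeta = .cfgGet(cfg, "zeta", NULL), seed = seed)
  sel <- attr(curve, "selection")
  model <- trainKRR(molSet, descSet, sel[seq_len(max(sizes))],
                    lambda = .cfgGet(cfg, "lambda", 1e-8),
                    kernelMode = .cfgGet(cfg, "kernel_mode", "intensive"),
                    zeta = .cfgGet(cfg, "zeta", NULL))
  paths <- list(curve = file.path(outDir, "learning_curve.csv"),
                model = file.path(outDir, "model.rds"))
  utils::write.csv(curve, paths$curve, row.names = FALSE, quote = FALSE)
  saveModel(model, paths$model)
  .writeManifest(outDir, "train", cfg,
                 list(n_test = length(testIds), sizes = sizes))
  invisible(list(model = model, curve = curve, paths = paths))
}

#' Predict reaction energies over a network and write the RE report
#'
#' @param config list or YAML path with \code{molecules},
#'   \code{reactions}, \code{model} (archive path) and
#'   \code{output_dir}.
#' @return the \code{\link{aeReErrorReport}} list, invisibly.
#' @export
runPredictRE <- function(config) {
  cfg <- if (is.character(config)) readRunConfig(config) else config
  outDir <- .cfgGet(cfg, "output_dir", ".")
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  model <- loadModel(cfg$model)
  molSet <- readMolecules(cfg$molecules,
                          energyKey = .cfgGet(cfg, "energy_key", "energy"))
  network <- readReactions(cfg$reactions, molSet)
  report <- aeReErrorReport(network, model)
  writeREReport(report, file.path(outDir, "re_report.csv"),
                file.path(outDir, "re_summary.json"))
  .writeManifest(outDir, "predict-re", cfg,
                 list(mae_ae = report$maeAE, mae_re = report$maeRE,
                      training_overlap = report$trainingOverlap))
  invisible(report)
}

#' Run a microkinetic simulation and extract reduced networks
#'
#' Integrates the network under the configured conditions (reference or
#' model-predicted reaction energies) and writes the concentration and
#' flux trajectories, plus a GraphML of the final reduced network with
#' first-access times.
#'
#' @param config list or YAML path with \code{molecules},
#'   \code{reactions}, kinetic keys (\code{temperature}, \code{barrier},
#'   \code{prefactor}, \code{initial}, \code{times},
#'   \code{flux_threshold}) and optionally \code{model}.
#' @return list with \code{trajectory} and \code{growth}, invisibly.
#' @export
runSimulate <- function(config) {
  cfg <- if (is.character(config)) readRunConfig(config) else config
  outDir <- .cfgGet(cfg, "output_dir", ".")
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  molSet <- readMolecules(cfg$molecules,
                          energyKey = .cfgGet(cfg, "energy_key", "energy"))
  network <- readReactions(cfg$reactions, molSet)
  eReac <- NULL
  if (!is.null(cfg$model)) {
    model <- loadModel(cfg$model)
    rep <- predictNetworkRE(network, model)
    eReac <- stats::setNames(rep@predictions$e_reac_pred,
                             rep@predictions$reaction_id)
  }
  conditions <- KineticConditions(
    init = unlist(cfg$initial),
    times = as.numeric(.cfgGet(cfg, "times", 10^seq(-2, 6, by = 0.5))),
    temperature = .cfgGet(cfg, "temperature", 1000),
    barrier = .cfgGet(cfg, "barrier", 0.5),
    prefactor = .cfgGet(cfg, "prefactor", 1))
  traj <- integrateNetwork(network, conditions, eReac = eReac)
  thr <- .cfgGet(cfg, "flux_threshold", 1e-3)
  outTimes <- traj@times[traj@times > 0]
  growth <- growthSequence(traj, outTimes[unique(round(
    seq(1, length(outTimes), length.out = min(6, length(outTimes)))))], thr)
  utils::write.csv(data.frame(time = traj@times, traj@concentrations,
                              check.names = FALSE),
                   file.path(outDir, "trajectory.csv"), row.names = FALSE)
  utils::write.csv(data.frame(time = traj@times, traj@fluxes,
                              check.names = FALSE),
                   file.path(outDir, "fluxes.csv"), row.names = FALSE)
  writeGrowthGraphML(growth, file.path(outDir, "reduced_network.graphml"))
  .writeManifest(outDir, "simulate", cfg,
                 list(flux_threshold = thr,
                      temperature = conditions@temperature,
                      barrier = conditions@barrier,
                      prefactor = conditions@prefactor,
                      n_accessed = length(
                        growth$networks[[length(growth$networks)]]@reactions)))
  invisible(list(trajectory = traj, growth = growth))
}

#' Kernel PCA map of a molecule file
#'
#' @param config list or YAML path with \code{molecules},
#'   \code{kernel_mode} and \code{output_dir}.
#' @return the score matrix, invisibly.
#' @export
runKPCA <- function(config) {
  cfg <- if (is.character(config)) readRunConfig(config) else config
  outDir <- .cfgGet(cfg, "output_dir", ".")
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  molSet <- readMolecules(cfg$molecules,
                          energyKey = .cfgGet(cfg, "energy_key", "energy"))
  descSet <- computeDescriptors(molSet, .cfgDescriptorParams(cfg))
  K <- molecularKernel(descSet, mode = .cfgGet(cfg, "kernel_mode", "intensive"))
  proj <- kernelPCA(K, nComponents = 2L)
  df <- data.frame(molecule_id = rownames(proj$scores), proj$scores)
  utils::write.csv(df, file.path(outDir, "kpca.csv"), row.names = FALSE)
  .writeManifest(outDir, "kpca", cfg,
                 list(variance_explained = proj$varianceExplained))
  invisible(proj$scores)
}
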