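# Shared in-memory fixtures, built once per test run.
.fixtureCache <- new.env()

cachedFixture <- function(maxHeavy = 3L, seed = 1L, sigma = 0) {
  key <- sprintf("fx_%d_%d_%g", maxHeavy, seed, sigma)
  if (!exists(key, envir = .fixtureCache)) {
    assign(key, makeFixture(maxHeavy = maxHeavy, seed = seed,
                            params = surrogateParams(sigma = sigma,
                                                     seed = seed)),
           envir = .fixtureCache)
  }
  get(key, envir = .fixtureCache)
}

cachedDescriptors <- function(maxHeavy = 3L, seed = 1L) {
  key <- sprintf("desc_%d_%d", maxHeavy, seed)
  if (!exists(key, envir = .fixtureCache)) {
    fx <- cachedFixture(maxHeavy, seed)
    assign(key, computeDescriptors(molecules(fx$network)),
           envir = .fixtureCache)
  }
  get(key, envir = .fixtureCache)
}

# A handful of embedded small molecules for kernel/descriptor tests.
testMolecules <- function(n = 5, seed = 42) {
  graphs <- enumerateMolecules(2)
  pick <- round(seq(1, length(graphs), length.out = n))
  mols <- lapply(seq_along(pick), function(i)
    embedGeometry(graphs[[pick[i]]], id = sprintf("t%d", i),
                  seed = seed + i))
  MoleculeSet(mols)
}

randomRotation <- function(seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(9), 3)))
}
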