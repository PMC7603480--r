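Package: rxnspace
Title: Kernel Ridge Regression of Reaction Energies over Chemical
    Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for machine learning in chemical reaction space.
    Atomization energies of closed- and open-shell CHO molecules are
    learned with kernel ridge regression on per-atom environment
    descriptors, using either an intensive (average) or an extensive
    (sum) molecular kernel. Predicted atomization energies are composed
    into reaction energies over bond-breaking reaction networks via
    Hess's law, with uncertainty propagation and hub-molecule error
    analysis. A mean-field microkinetic simulator with constant
    activation barriers extracts reduced reaction sub-networks from a
    large candidate network as a function of simulation time. A
    synthetic-data generator enumerates radical-rich CHO molecule sets
    with a bond-counting surrogate energy oracle so the whole pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'chem-data.R'
    'descriptors.R'
    'kernels.R'
    'learning.R'
    'reaction-energies.R'
    'microkinetics.R'
    'synthetic-graphs.R'
    'synthetic-fixture.R'
    'pipelines.R'
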