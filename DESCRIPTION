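Package: emdrsim
Title: Hybrid Discrete-Continuum Simulation of Environmentally Mediated Drug
    Resistance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An on-lattice hybrid discrete-continuum model of a solid tumour
    growing in a homeostatic stromal tissue and responding to a molecularly
    targeted inhibitor drug delivered through a static vasculature. Cancer and
    stroma cells are discrete agents on a square lattice; the inhibitor drug
    and a local proliferation signal are continuum fields advanced by explicit
    finite differences. Reactive stroma (cancer-associated fibroblasts) can be
    activated by above-threshold drug concentrations when in contact with
    cancer, providing paracrine rescue of cancer cells and giving rise to
    environmentally mediated drug resistance (EMDR). The package provides
    vessel-layout generators (circle packed and regular grids), intermittent
    treatment scheduling, full simulation runs, and the spatial analysis
    readouts used to characterise residual-disease niches (longitudinal
    occupancy, neighbourhood composition, threshold-highlight maps, niche
    labelling).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'agents.R'
    'analysis.R'
    'emdrsim-package.R'
    'engine.R'
    'fields.R'
    'fixtures.R'
    'io.R'
    'methods.R'
    'params.R'
    'vasculature.R'
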