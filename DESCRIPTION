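Package: minn
Title: Metabolic-Informed Neural Networks for Flux Prediction from Multi-Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid mechanistic/machine-learning prediction of genome-scale
    metabolic flux distributions from multi-omics measurements. A single hidden
    layer feed-forward network maps transcript, protein and exchange-flux
    features to a candidate flux vector, which an unrolled gradient-descent
    mechanistic layer then refines toward the flux-balance-analysis (FBA)
    constraint set (steady state, uptake bounds, non-negativity). Training
    balances the data-driven and mechanistic loss terms through several
    selectable strategies (constant weighting, loss bounding, exponential
    moving-average normalisation, phase scheduling). The package also provides
    the supporting constraint-based-modelling toolkit (SBML input, reversible
    reaction splitting, FVA- and FBA-sampling model reduction, FBA,
    parsimonious FBA, flux variability analysis, Euclidean projection of
    measured fluxes onto the steady-state solution space via quadratic
    programming), a reservoir variant that couples a frozen neural FBA
    surrogate to parsimonious FBA, a nested leave-one-out/5-fold evaluation
    protocol, and generators for toy metabolic models and chemostat-style
    synthetic multi-omics datasets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
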