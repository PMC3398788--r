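Package: SignalGSA
Title: Global Sensitivity Analysis of Kinetic Signalling Network Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Model-based global sensitivity analysis for kinetic models of
    cell signalling networks. Samples the parameter hypercube with Sobol
    low-discrepancy sequences, integrates the ODE ensemble under paired
    no-drug/drug conditions, summarises phospho-protein readouts as
    normalised area-under-curve metrics, computes partial rank correlation
    coefficient (PRCC) sensitivity profiles with significance, assesses
    sample-size adequacy with the top-down coefficient of concordance, and
    classifies parameters into candidate drug targets, susceptibility
    biomarkers, resistance biomarkers and combination-therapy candidates.
    Includes a reduced ErbB2/3-like receptor/PI3K/PTEN/Akt fixture model,
    analytic benchmark models with closed-form sensitivities, an SBML subset
    importer/exporter, and a local sensitivity analysis spectrum for
    comparison with the global profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, deSolve, xml2
Suggests: testthat (>= 3.0.0), jsonlite, optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'fixtures.R'
    'interpret.R'
    'lsa.R'
    'metrics.R'
    'model-core.R'
    'parameter-space.R'
    'sbml.R'
    'sensitivity.R'
    'sobol.R'
    'tdcc.R'
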