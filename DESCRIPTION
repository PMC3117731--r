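Package: atorkin
Title: Dynamic Modeling of Atorvastatin Biotransformation in Primary Human Hepatocytes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic two-compartment kinetic model of atorvastatin uptake,
    phase I/II metabolism (CYP3A4 hydroxylation, UGT1A3 lactonization), lactone
    hydrolysis, unspecific macromolecular binding and membrane transport in
    cultured primary human hepatocytes. Provides stiff ODE simulation of the
    full and transport-lumped model variants, weighted least-squares parameter
    estimation with a self-adaptive evolutionary strategy under inequality
    constraints, Fisher-information identifiability analysis with an iterative
    transport-lumping model reduction, relative-abundance scaling of maximal
    enzyme rates from protein expression data, virtual-population simulation of
    inter-individual CYP3A4/UGT1A3 variability with AUC/c_max/t(c_max)
    summaries and log-logistic distribution fits, and a synthetic-data
    generator emulating the LC-MS/MS time-series measurement structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    fitdistrplus,
    flexsurv,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
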