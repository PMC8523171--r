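Package: coopbind
Title: Cooperative Binding of Proteins to Repeat Nucleic-Acid Lattices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the cooperative association of RNA-binding
    proteins (such as the tandem RNA recognition motifs of TDP-43) with
    GU/GT-repeat nucleic-acid lattices. Implements the footprint/register
    stoichiometry model, sequential (Adair) binding polynomials with species
    distributions and mass-balance equilibration, simulation and fitting of
    isothermal titration calorimetry experiments under a one- or two-site
    sequential model (with the Kd1/Kd2 cooperativity statistic, model
    selection and bootstrap confidence intervals), ratiometric two-channel
    line-profile analysis for microtubule-bench demixing detection with a
    Kolmogorov-Smirnov comparison, per-object condensate classification and
    the nucleo-cytoplasmic distribution slope, plus seeded synthetic-data
    generators for every input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
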