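Package: crisprqsp
Title: Translational Quantitative Systems Pharmacology for In Vivo CRISPR-Cas9 Therapies
Version: 0.1.0
Authors@R:
    person("QSP", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation, calibration, and uncertainty analysis for a minimal
    physiologically based model of lipid-nanoparticle delivered CRISPR-Cas9
    therapy. Tracks the lipid nanoparticle, single guide RNA, Cas9 mRNA,
    Cas9 protein, and ribonucleoprotein complex across plasma, a
    three-layer liver, kidney, and a lumped remainder compartment in mouse,
    cynomolgus monkey, and human, with opsonin binding, phagocytosis by the
    mononuclear phagocyte system, LDL-receptor mediated uptake, and renal
    elimination. Couples the liver-cell ribonucleoprotein concentration to
    serum transthyretin (indirect response), PCSK9 (transit/feedback), and
    LDL cholesterol (precursor-dependent) pharmacodynamics. Includes
    fixed-effect maximum-likelihood calibration with a proportional
    residual-error model, Sobol global sensitivity analysis, lognormal
    virtual-population Monte Carlo simulation, a synthetic study-data
    generator, and a command-line workflow driver. The stiff initial value
    problems are solved with a compiled L-stable Rosenbrock method.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
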