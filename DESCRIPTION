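Package: angiofit
Title: Mechanistic Modeling of VEGF-Gated Tumor Growth and Anti-VEGF
    Treatment Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-compartment (normal tissue, blood, tumor) systems
    pharmacology model of VEGF ligand-receptor kinetics and transport in
    tumor-bearing mice, coupled to a Simeoni-type tumor growth law gated by
    the angiogenic signal (VEGF-bound receptor complexes on tumor
    endothelial cells).  Includes bevacizumab treatment simulation and
    relative tumor volume prediction, multistart bounded least-squares
    estimation of tumor growth kinetic parameters from xenograft growth
    curves, extended Fourier Amplitude Sensitivity Test (eFAST) global
    sensitivity analysis, NIPALS partial least squares regression with VIP
    scores, nonparametric comparison of fitted parameter sets, receptor
    density response scans, and a synthetic xenograft dataset generator
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
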