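Package: viscoclutch
Title: Molecular Clutch Dynamics on Viscoelastic Substrates and
    Stress-Relaxation Nanoindentation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Monte Carlo simulation of integrin-based molecular clutch
    dynamics on a Standard Linear Solid (SLS) viscoelastic substrate,
    including force-dependent slip-bond dissociation, talin unfolding,
    finite-rate vinculin reinforcement with integrin recruitment, and
    Piezo1-knockdown modelling as increased clutch dissociation. Also
    provides the companion nanoindentation stress-relaxation analysis
    pipeline (curve preprocessing, averaging, time-to-80-percent-force,
    energy dissipation, Hertzian Young's modulus fitting) and synthetic
    data generators with known ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
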