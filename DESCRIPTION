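Package: porethz
Title: Terahertz Porosity and Pore-Shape Analysis of Powder Compacts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for porosity and pore-shape analysis of pharmaceutical
    powder compacts from terahertz time-domain spectroscopy (THz-TDS)
    effective refractive indices. Implements closed-form solvers for the
    anisotropic Bruggeman effective medium approximation (AB-EMA) in its
    real and complex forms, the Wiener bounds and the derived per-sample
    bounds for the depolarisation factor, grid-search AB-EMA fitting with
    a shared solid-index variant and a modified AB-EMA with porosity
    dependent pore shape, tablet-geometry porosity calculations for flat
    faced and biconvex tablets, spectral band averaging, and three
    deterministic simulation studies quantifying the model's error
    sources (material absorption, pore-shape gradients, radial density
    distribution).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
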