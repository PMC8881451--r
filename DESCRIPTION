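Package: gwirekit
Title: Hydrodynamic and Structural Analysis of DNA G-Wire Self-Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of guanine-quadruplex nanowires (G-wires)
    assembled from short G-rich oligonucleotides. Converts dynamic light
    scattering (DLS) intensity-autocorrelation traces into translational
    diffusion coefficients by two-mode exponential fitting, inverts the
    Tirado-de la Torre rigid-rod hydrodynamic model to obtain effective wire
    lengths and stacked building-block counts, summarises atomic force
    microscopy (AFM) ridge length/height tables with log-normal statistics
    and finite-tip corrections, extracts per-groove phosphate-phosphate
    distance series from multi-model PDB coordinate ensembles, and estimates
    melting midpoints from UV absorbance curves. Seeded synthetic-data
    generators emulate every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    bio3d,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
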