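Package: golphkit
Title: Kinetic, Permeability and Energetic Analysis of a Golgi
    pH-Regulating Cation Channel
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for the electrophysiology and molecular
    modelling of GolpHCat (TMEM87A), a voltage-dependent, inwardly
    rectifying Golgi cation channel. Provides an exact continuous-time
    Markov simulator of single-channel gating with closed, open and
    subconductance states; half-amplitude idealization, open-probability,
    dwell-time and Gaussian-mixture amplitude analysis of single-channel
    records; whole-cell ramp I-V analysis with Goldman-Hodgkin-Katz
    bi-ionic permeability ratios, Hill dose-response fitting and Henderson
    liquid-junction-potential correction; Gaussian-accelerated-dynamics
    boost-potential mechanics with a one-dimensional Langevin
    demonstrator and a linear-interaction-energy binding free-energy
    estimator; principal-axis lipid-binding-state geometry; and
    ratiometric organelle-pH analysis. A synthetic-data generator with
    known ground truth backs every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
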