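Package: rogueryr
Title: Coupled Stochastic Calcium Release and Action Potential Model of
    Rogue-RyR-Driven Afterdepolarizations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multiscale simulation of a cardiac ventricular myocyte coupling a
    two-dimensional stochastic subcellular calcium reaction-diffusion sheet
    (ryanodine-receptor clusters plus randomly scattered solitary "rogue"
    channels, gated by local cytosolic and luminal calcium) to a whole-cell
    human ventricular action-potential model. Provides control and
    heart-failure parameter sets, pacing and rest protocols, Monte Carlo
    ensembles over rogue-channel density, detection of delayed
    afterdepolarizations and triggered action potentials, linescan images,
    and ensemble statistics (mean, SEM, one-way ANOVA).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
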