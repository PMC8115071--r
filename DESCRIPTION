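Package: oxphosimc
Title: Single-Neuron OxPhos Deficiency Profiling from Imaging Mass Cytometry
Version: 0.1.0
Authors@R:
    person("Open", "Contributor", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies mitochondrial oxidative phosphorylation (OxPhos)
    protein expression in single midbrain neurons from multichannel imaging
    mass cytometry data. Extracts per-neuron mean cytoplasmic intensities
    from multichannel images and manually outlined neuron polygons, fits
    pooled-control ln-ln regressions of each OxPhos subunit on the
    mitochondrial mass marker VDAC1, derives perpendicular-distance z-scores
    and 80 percent prediction-interval deficiency calls, profiles combined
    complex deficiencies (severity categories 0-5), and compares groups with
    a robust Bayesian two-group model (Student-t likelihood, highest density
    intervals, effect sizes) plus classical nonparametric statistics. A
    synthetic cohort and image generator with ground-truth labels makes the
    whole pipeline testable without access to post-mortem tissue data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    coda,
    optparse,
    sp,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
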