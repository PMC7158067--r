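Package: stsurveil
Title: Bayesian Spatiotemporal Surveillance Models for Areal Disease Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Hierarchical Bayesian models for surveillance of non-communicable
    disease counts on an area-by-time grid: spatiotemporal disease mapping with
    an intrinsic CAR spatial prior, a two-component normal mixture on the
    space-time interaction (STmix), and a common-trend versus area-specific-trend
    relative-risk mixture with per-area model choice. Includes exceedance-probability
    and posterior-model-probability detection rules with Bayesian false-discovery-rate
    control, a synthetic scenario generator with ground-truth anomaly labels, and a
    replicate simulation benchmark scoring detectors by sensitivity, specificity,
    FDR and FOR. All posterior computation is by Markov chain Monte Carlo.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
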