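Package: dyadcoord
Title: Interpersonal Movement Coordination Analysis for Improvising Dyads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterizes moments of high and low interpersonal
    movement coordination between two freely improvising partners from
    overhead hand-tracking data. Reads marker coordinates in the DeepLabCut
    CSV dialect, derives preprocessed hand-speed time series, computes the
    maximum correlation vector (MCV) over rolling-window Spearman
    correlations of the four between-participant hand pairings, assesses
    significance with a data-sliding permutation test, classifies rated
    moments as high or low coordination by area-under-curve evidence, and
    quantifies directed leader-follower influence with windowed normalized
    symbolic transfer entropy (NSTE) and its asymmetry index. A synthetic
    dyad simulator with scripted coupling, independence and joint-stillness
    episodes provides ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
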