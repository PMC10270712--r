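Package: edgefid
Title: Edge-Centric Functional Information Decay Analysis for Multiregion Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for edge-centric timescale analysis of epoched multiregion
    neural time series. Builds edge co-activation signals as products of
    z-scored regional signals, estimates how long information persists in each
    signal via the decay of auto-mutual information (histogram plug-in
    estimator with a tail-fit stopping rule), aggregates decay times into the
    region-by-region functional information decay (FID) matrix, and contrasts
    the empirical decays against three null models (spectrally matched
    Gaussian surrogates, phase-randomized surrogates preserving static
    correlations, and a regional geometric-mean null) to classify trials along
    a local-to-nonlocal axis and track the gradient of nodal timescales. A
    synthetic-data generator with known AR(1) timescale gradients and
    switchable dynamic coupling, plus a toy leadfield/beamformer leakage
    simulation, make the whole pipeline testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
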