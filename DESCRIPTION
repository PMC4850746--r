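Package: msburst
Title: Stochastic Simulation and Hidden Markov Inference of Transcriptional Bursting from MS2 Live-Cell Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing transcriptional bursting from live-cell
    imaging of MS2/MCP-tagged nascent RNA. Provides an exact event-driven
    Monte Carlo simulator of polymerase initiation, elongation with steric
    exclusion, termination and photobleaching recovery; a closed-form
    bivariate-Gaussian theory of transcription-spot pulsing; model-free
    trace analytics (pulse extraction, autocorrelation decomposition,
    smFISH quantile calibration); a processive-polymerase FRAP recovery
    model; a two-layer hidden Markov model over gene activity states and
    per-frame polymerase initiation counts with Baum-Welch training, AIC
    model-order selection, Gibbs sampling of initiation trajectories and
    downstream bursting statistics; and negative-binomial fitting of
    steady-state cytoplasmic mRNA distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
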