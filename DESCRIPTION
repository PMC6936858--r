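Package: pathprobe
Title: Probing Phase-Dependent Communication Pathways in Delay-Coupled
    Neural Mass Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates networks of delay-coupled Jansen-Rit neural mass
    models on a structural connectome and probes pairs of nodes with two
    weak sinusoidal drivers at controlled phase offsets.  Provides the
    analysis chain (band-pass filtering, analytic signal, phase-locking
    coherence, Welch spectra, Kuramoto order parameter), graph machinery
    over the connectome (simple-path enumeration, Dijkstra distance on
    inverted connection strengths), and metrics quantifying
    phase-dependent communication routing: pathway synchronization
    facilitation (PSF), pathway activation (PA), pathway phase
    selectivity (PPS) and the pathway switching index (PSI).  Includes a
    synthetic connectome generator standing in for diffusion-imaging
    derived structural connectivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
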