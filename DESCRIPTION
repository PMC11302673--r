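Package: homscaffold
Title: Persistence Homological Scaffolds of Functional Connectomes and
    Aperiodic Spectral Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools linking the topology of functional connectivity networks
    to aperiodic electrophysiological dynamics. Builds Vietoris-Rips flag
    filtrations from Pearson connectomes via the pseudo-distance 1 - r,
    computes first-homology persistence barcodes over Z/2, extracts
    volume-optimal persistent cycles by exact combinatorial optimisation
    with a linear-programming relaxation fallback, aggregates cycles into
    persistence homological scaffolds and persistence centrality, estimates
    Welch power spectra with IRASA aperiodic/periodic separation and band
    power ratios, and compares task-evoked changes across modalities with
    cosine similarity, Kendall rank association, Mann-Whitney U and a
    cluster-based sign-flip permutation paired t-test. Includes a
    synthetic-data module that plants persistent rings and topology-to-
    spectrum coupling for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
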