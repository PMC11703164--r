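Package: syllabr
Title: Sub-Second Behavioral Syllable Segmentation and Transition Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for sub-second locomotor behavior in
    open-field assays. Segments pose time series into behavioral syllables
    with a reduced sticky autoregressive hidden Markov model (egocentric
    alignment, PCA, blocked Gibbs sampling, kappa scanning against a 400 ms
    target duration), quantifies per-syllable velocity, usage and duration,
    characterizes the syllable Markov chain (transition matrices,
    steady-state distribution, entropy rate, transition frequency), and runs
    rank-based group comparisons (Kruskal-Wallis with Dunn's post hoc,
    Benjamini-Hochberg correction, Mann-Whitney U, delta-vs-velocity
    regressions). Ships a seeded synthetic cohort generator emulating
    control and Parkinsonian (dopamine-depleted) groups so the whole
    pipeline is testable end to end without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
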