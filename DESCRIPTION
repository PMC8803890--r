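Package: rccm
Title: Robust Convergent Cross-Mapping with Information-Geometric Masking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers directed causal links between pairs of nonlinear
    dynamical time series with a bootstrap-robustified convergent
    cross-mapping estimator (RCCM): Takens delay embedding, simplex
    cross-map prediction, convergence-in-library-size curves, extended
    (lagged) cross-mapping with positive-lag rejection, windowed
    bootstrap runs with median aggregation, and automatic embedding
    dimension selection. Strong or instantaneous couplings are
    disambiguated by entropy-based information-geometric causal
    inference (IGCI) using a recursive median-partitioning (kDP)
    differential entropy estimator, and the two criteria are combined
    into a masking rule. Includes pixel-wise orchestration over gridded
    spatio-temporal datacubes with dominance maps, skill-difference
    maps and stratified summaries, plus generators for coupled
    logistic-map benchmarks, planted-lag systems and planted-regime
    synthetic datacubes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
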