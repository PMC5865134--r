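Package: carmap
Title: Bayesian Disease Mapping of Area-Level Emergency Incidence with
    Conditional Autoregressive Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Small-area incidence analysis for prehospital emergency events:
    indirect age-gender standardisation (stratum standard rates, expected
    caseloads, crude standardised incidence ratios and case rates per 10,000),
    Queen-contiguity neighbour structures with GAL file interchange, a
    Besag-York-Mollie Poisson spatial model fitted by a purpose-built
    Metropolis-within-Gibbs sampler (smoothed SIRs with 95% credible
    intervals, Gelman-Rubin and Monte Carlo error diagnostics, DIC),
    quintile covariate categorisation with DIC-ordered stepwise spatial
    regression, a synthetic area-data generator with known ground truth,
    and choropleth-ready GeoJSON export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
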