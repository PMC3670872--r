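Package: nmafwer
Title: Family-Wise Error Simulation for Bayesian Network Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monte Carlo machinery for studying family-wise false-positive
    rates of Bayesian random-effects network meta-analysis (mixed treatment
    comparisons) on binary outcomes. Generates synthetic arm-level trial
    networks emulating the summary structure of a large antidepressant
    evidence base (117 trials, 236 arms, 12 treatments, 25,928 participants),
    fills them with responses under the null hypothesis of no treatment
    differences, fits a binomial-logit consistency model by Markov chain
    Monte Carlo to every replication, and summarises the distribution of
    spuriously significant pairwise odds-ratio contrasts. Also provides a
    classical pairwise random-effects meta-analysis of 2x2 tables with
    restricted maximum likelihood heterogeneity estimation, treatment rank
    probabilities, convergence diagnostics, and Bonferroni re-analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rjags,
    coda,
    metafor
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
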