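Package: schoolnet
Title: Gender-Specific Social Network Intervention Simulation for School Health Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of health-behavior diffusion on gendered
    small-world school networks. Generates Watts-Strogatz-style networks with
    gender homophily, selects influential agents by betweenness, closeness,
    eigenvector or PageRank centrality (or at random), propagates behavior
    adoption with gender-specific spread and reversion probabilities, and runs
    replicated seeding-condition experiments with diffusion-speed and
    success-rate summaries. Also provides gender-stratified cohort statistics
    (prevalence reconstruction, two-proportion z-tests, chi-square tests,
    Pearson correlation) together with a synthetic cohort generator that
    reproduces configured prevalence margins exactly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
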