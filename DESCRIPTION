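Package: walkrank
Title: Degree-Neutralized Random-Walk Ratings for Competition Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rates competitors in weighted directed competition networks
    (sports leagues, dominance hierarchies, paired-comparison data) with a
    random walk whose edge gradients are set by contest scores and whose
    transition probabilities are discounted by node degree, removing the
    bias that network topology alone induces on occupation probabilities.
    Includes four classical comparison raters (win-loss differential with a
    net-points tie breaker, Colley's matrix method, Park-Newman generalized
    wins-losses, and PageRank read as weakness), a season-evaluation
    protocol (cumulative weekly prediction accuracy, Spearman
    rank-convergence, line crossings with an exponential fit, jackknife
    rating errors), a synthetic season generator with known latent
    strengths, and readers/writers for delimited game-result files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    minpack.lm,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
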