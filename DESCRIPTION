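Package: crossinhib
Title: Cross-Inhibition Quantised Consensus Dynamics on Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-level model of quantised consensus among three opinions
    (two committed states X and Y plus an uncommitted state Z), inspired by
    honeybee nest-site selection with recruitment (waggle dance) and
    cross-inhibition (stop signals). Provides the deterministic mean-field
    evolutionary-game map on the population simplex, the stochastic
    agent-based process on explicit graphs (Erdos-Renyi and Watts-Strogatz),
    fixed-point location with Jacobian eigenvalue stability classification,
    and seeded experiment runners comparing the two levels: paired
    trajectory comparison, reward-ratio sweeps, and small-world agreement
    studies. All results are tidy tibbles with ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
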