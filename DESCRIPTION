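Package: gfsnet
Title: Differential Brain-Network Analysis with 2-Hop Random Walk Node Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for differential analysis of weighted structural brain
    networks (fiber-number connectomes). Implements a 2-hop random walk with
    restart (2hopRWR) whose steady-state probability matrix yields a
    2hop-connectivity node score, combines it with degree, betweenness and
    closeness centrality and the number of maximal cliques into a Global
    Feature Score (GFS), ranks nodes by the between-group GFS difference,
    and relates GFS to external subject scores through canonical correlation
    analysis. Includes a synthetic two-group connectome generator with
    planted affected nodes for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
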