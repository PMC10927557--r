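Package: dietshift
Title: Cluster-Based Linear Programming of Climate-Constrained Healthy Diets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies a dietary-survey population into eating-pattern clusters
    by hierarchical clustering (Canberra distance, Ward linkage) and solves, per
    cluster and for the total population, a linear programme that minimises the
    total relative deviation from the baseline diet subject to dietary reference
    values, food-based dietary guidelines, per-food acceptability bounds and a
    greenhouse-gas cap. Includes a synthetic survey-population generator with
    planted cluster structure, post-hoc cluster profiling (Kruskal-Wallis with
    Dunn/Benjamini-Hochberg post-hoc tests, healthy-eating index scoring) and
    report tables for emission, cost and food-group shifts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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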