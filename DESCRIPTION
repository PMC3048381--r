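Package: gssa
Title: Gene-Set Selection Analysis of Evolutionary Rate Rankings
Version: 0.1.0
Authors@R:
    person("GSSA", "Maintainers", email = "gssa@example.org", role = c("aut", "cre"))
Description: A segmentation test for detecting functional modules (GO/KEGG-style
    gene sets) whose member genes are significantly skewed toward high or low
    values in genome-wide rankings of evolutionary rates (dS, dN, omega = dN/dS,
    and the ancestor-to-descendant change in omega). Genes are ranked by an
    evolutionary variable, the ranked list is cut at a fixed number of
    partitions, each partition is scored with a two-tailed Fisher's exact test,
    and p-values are corrected jointly over all terms and partitions by the
    Benjamini-Hochberg procedure. Includes annotation handling (GMT input, DAG
    ancestor propagation, term-level windows, minimum set sizes),
    randomization-based false-positive calibration, and a synthetic-data
    generator with planted rank-shifted modules for power testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
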