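Package: isoniche
Title: Individual Dietary Specialization from Serially Sampled Enamel Carbon Isotopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying individual dietary specialization in herbivorous
    mammals from serially sampled tooth-enamel stable carbon isotope (d13C) profiles.
    Reads and validates flat serial-sample tables, computes per-individual isotopic
    niche summaries and the isotopic individuality index (III, the average individual
    d13C range of a taxon divided by the taxon's total d13C range), standardizes
    samples-per-tooth bias with a five-sample moving-window range analysis, partitions
    d13C variance across nested scales (between species, between individuals within
    species, within individuals) by method-of-moments nested ANOVA for unbalanced
    designs and by REML, and compares dietary and body-size groups with Kruskal-Wallis
    and Dunn's tests. Includes a hierarchical synthetic-data generator with seasonal
    sinusoid option so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nlme,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
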