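Package: twinmeth
Title: Differential and Variable DNA Methylation Analysis in Monozygotic Twin Designs
Version: 0.1.0
Authors@R:
    person("twinmeth", "developers", email = "twinmeth@example.org", role = c("aut", "cre"))
Description: Analysis of Illumina 450K-style beta-value matrices from
    monozygotic twin designs with concordant, discordant and healthy pairs.
    Identifies differentially methylated probes (DMPs) in disease-discordant
    pairs by a rank-combination of paired t-test P-values and mean intrapair
    beta differences, cross-validates top probes against concordant and
    healthy pairs with exact Wilcoxon-Mann-Whitney tests, and identifies
    variably methylated probes (VMPs) by thresholding group medians of
    absolute intrapair differences and partitioning probes by
    group-exclusivity. Includes a hypergeometric gene-set over-representation
    stand-in for pathway analysis, a seeded synthetic twin-data generator
    so every stage is testable without external data, and a command-line
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
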