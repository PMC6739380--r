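Package: sibseg
Title: Discordant-Sibling Exome Segregation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Family-based prioritization of exome variants in siblings with
    discordant phenotypes. Implements an auditable variant filter cascade
    (genotype quality, transcript confirmation, UTR exclusion, alternate-allele
    coverage, synonymous exclusion, reference-minor-allele exclusion) with
    per-stage accounting, cross-family segregation calling under recessive
    (shared homozygosity) and dominant (shared variant) inheritance models with
    k-of-N family confirmation and phenotype-group exclusivity, gene-set
    over-representation analysis with Benjamini-Hochberg correction, and
    enrichment-map network construction. Includes a synthetic cohort generator
    with Hardy-Weinberg background variants and planted segregating variants
    for end-to-end validation, plus worked-example genotype-table fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
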