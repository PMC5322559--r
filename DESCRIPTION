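Package: setraits
Title: Mapping Selenium Utilization Traits and Candidate Genes Across Prokaryotic Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative-genomics toolkit for profiling selenium (Se)
    utilization across prokaryotic genomes and nominating new Se-related
    candidate genes. Builds genome compendia from gene-coordinate tables
    (GFF3 or TSV), assigns protein families by bidirectional-best-hit
    orthology combined with domain evidence, classifies genomes into the
    three known SelD-dependent Se utilization traits (selenocysteine
    decoding, selenouridine, and Se-containing cofactor), detects compact
    Se gene islands, scores candidate families by genomic linkage
    recurrence and presence/absence co-occurrence statistics, and provides
    tree utilities (Poisson-corrected protein distances, neighbor joining,
    clade-enrichment scans, conserved-residue and motif scans). A
    synthetic-compendium simulator with full ground truth (Yule species
    trees, binary gain/loss trait evolution, planted gene islands and
    linked candidates, noisy homology tables) makes every stage testable
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    jsonlite,
    seqinr,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
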