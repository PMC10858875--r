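Package: phagedyn
Title: Seasonal Eco-Evolutionary Dynamics of Gut Phage Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidy toolkit for longitudinal gut phageome analysis: screening
    of candidate phage contigs (gene-content rule, alternative genetic-code
    selection, lifestyle resolution), clustering of phage genomes into viral
    operational taxonomic units (vOTUs) at 95% average nucleotide identity and
    85% alignment fraction with source/lifestyle splitting, trimmed-mean
    coverage abundance profiling, diet-season assignment from feeding bouts
    and rank-based diet-responsive population testing, CRISPR-spacer and
    genome-homology host prediction, shared protein-cluster statistics as a
    horizontal gene transfer proxy, within-population SNP turnover over time
    series, and the supporting community-ecology statistics (Hellinger,
    Bray-Curtis, PCoA, PERMANOVA, Mantel, Benjamini-Hochberg). Includes a
    synthetic-data generator that plants ground truth for every stage so the
    whole pipeline is testable without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
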