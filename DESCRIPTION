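Package: soilvirome
Title: Soil Virome Catalogs, Strand-Specific Activity, and Seasonal Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for downstream-of-assembly analysis of paired soil
    metagenomes and metatranscriptomes: clustering of viral contigs into
    viral operational taxonomic units (vOTUs) by greedy average nucleotide
    identity / aligned fraction clustering, strand-specific coverage and
    breadth-masked RPKM computation, decision-rule classification of DNA
    phage activity and lytic infection from expressed genes, dual-strand
    detection of actively replicating ssRNA viruses, propagation of
    taxonomy and host labels through unanimous monophyletic clades on
    reference phylogenies, generalized UniFrac distances, and seasonal
    community statistics (PERMANOVA, per-vOTU ANOVA with Tukey-Kramer post
    hoc tests and Storey false-discovery-rate control, z-score activity
    profiles). Includes a synthetic community generator with planted ground
    truth that emulates a seed-bank viral community across a months by
    depths by locations sampling design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    Biostrings,
    GenomicRanges,
    IRanges,
    optparse,
    Rsamtools,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
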