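Package: reannotr
Title: Evidence-Based Gene Set Merging, Structural Comparison and miRNA
    Target Conservation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for upgrading a genome annotation with RNA-Seq
    evidence, modelled on the workflow used for insect official gene
    sets. Filters spliced-alignment evidence into supported intron
    candidates (identity, mate-distance and ambiguity prefilters;
    length, splice-site and contradiction-ratio restrictions), merges
    an established gene set with a new prediction set using the
    specifically-supported-gene and rescue rules, classifies join and
    split events and gene correspondence between annotation versions,
    computes annotation quality metrics, predicts microRNA seed sites
    (8mer, 7mer-m8, 7mer-A1) in 3'UTRs, and tests cross-species
    conservation of miRNA targets with a permutation null. A seeded
    simulator generates complete synthetic fixtures with ground-truth
    manifests for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringi,
    stringr,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
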