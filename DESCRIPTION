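Package: bsapilla
Title: Bulked-Segregant Mapping of Husk Papilla Density in Foxtail Millet
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for QTL-seq style bulked-segregant analysis (BSA-Seq) of a
    monogenic dominant trait, built around the mapping of husk papilla density
    in foxtail millet (Setaria italica). Computes per-bulk SNP-index and
    InDel-index values from parent and bulk variant calls, delta-index tracks,
    sliding-window aggregation and threshold-based candidate-interval calling;
    annotates intervals with genes and co-localizes candidates across two F2
    populations; classifies stage-wise FPKM expression patterns to filter
    candidates; and tests Mendelian segregation ratios. Includes a synthetic
    F2 bulked-segregant simulator (Haldane recombination, Poisson read depth,
    symmetric sequencing error) that generates VCF, GFF3 and FPKM fixtures for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
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
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
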