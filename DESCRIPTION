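Package: regland
Title: Define H3K27ac Regulatory Regions and Link Them to Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for defining active regulatory
    regions from replicate H3K27ac ChIP-seq peak sets and integrating them
    with differential gene expression. Builds replicate-consensus regions,
    classifies them as promoters or enhancers by distance to the nearest
    transcription start site, labels regions as cell-type-specific or
    shared between two conditions by reciprocal overlap, stitches enhancers
    and separates super-enhancers from typical enhancers at the inflection
    point of the ranked input-subtracted signal curve (ROSE-style), and
    nominates target genes whose differential expression is concordant with
    the cell specificity of nearby regions. Includes a seeded synthetic-data
    generator with planted regulatory structure so every stage can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    limma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    GenomicRanges,
    IRanges
Config/testthat/edition: 3
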