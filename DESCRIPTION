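Package: cladepop
Title: Clade-Targeted Marker-Gene Population Structure and Transcription
    Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for species-level population structure analysis of a
    single bacterial clade from marker-gene (e.g. pmoA) amplicons:
    quality filtering, primer trimming, dereplication to amplicon
    sequence variants (ASVs), Jukes-Cantor distances, neighbor-joining
    trees, delineation of species-like groups by a fixed distance
    threshold on the tree, composition, alpha diversity (Chao1, Shannon,
    Simpson) with nonparametric cross-site comparison, Bray-Curtis
    dissimilarity and nonmetric multidimensional scaling.  Includes a
    transcription-level ranking scheme (TPM, inverse percentile ranks,
    six ordered categories) for companion RNA-seq count tables, and a
    synthetic-community generator with known ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    phangorn,
    purrr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    jsonlite,
    knitr,
    mclust,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
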