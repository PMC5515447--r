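Package: amplihap
Title: Intragenomic Haplotype Profiling of Multi-Copy Amplicons from
    Paired-End Deep Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Profiles intragenomic variation of multi-copy amplicons (such as
    the ribosomal RNA internal transcribed spacer two) from paired-end deep
    sequencing. Provides a ground-truthed read simulator, quality filtering and
    overlap merging of read pairs, affine-gap alignment to a reference with
    canonical variant extraction (SNVs, multi-nucleotide substitutions,
    indels), haplotype calling by repeated random subsampling with a
    demonstrable-variant frequency threshold, within- and between-group
    p-distance summaries with replicate reproducibility statistics, and
    neighbor-joining trees with column-resampling bootstrap support.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
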