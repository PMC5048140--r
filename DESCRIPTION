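Package: phylotai
Title: Phylotranscriptomic Age and Polymorphism Indices for Developmental
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phylotranscriptomic analysis of ordered developmental
    transcriptomes: assignment of gene evolutionary ages (phylostrata) from
    homology hit tables, length-weighting and trimmed-mean-of-M-values (TMM)
    normalization of stage-resolved count matrices with redundancy filters,
    per-gene Watterson's theta from population resequencing genotypes,
    expression-weighted stage profiles (transcriptome age index TAI, relative
    expression levels REL, and the transcriptome polymorphism index TPI),
    cross-species developmental-stage similarity via reciprocal-best-hit
    orthologs and Spearman correlation, and uncertainty via gene-resampling
    bootstrap confidence intervals and per-stage permutation nulls with
    gamma moment fits and a combined pattern p-value. Includes a synthetic
    data generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    edgeR,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
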