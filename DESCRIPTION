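Package: mztallele
Title: Allelic Multi-Omics Analysis of the Maternal-to-Zygotic Transition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking which parental genome drives zygotic genome
    activation (ZGA) and maternal RNA degradation in early embryos, using
    uniparental (parthenogenetic and androgenetic) embryos as proxies for the
    maternal and paternal genomes. Implements exact-binomial allele-specific
    expression calling from parental read counts, a pooled exact
    differential-expression test with maternal-to-zygotic transition gene
    classification, Fisher-exact differentially methylated site and region
    calling from bisulfite CpG counts, and scale-factor-normalized allelic
    DNase hypersensitive site calling, together with a synthetic embryo
    multi-omics generator with known ground truth for end-to-end validation.
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
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
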