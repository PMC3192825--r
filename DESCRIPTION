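Package: linksel
Title: Linked Selection, Recombination, and Neutral Diversity in Genomic Windows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how natural selection at linked sites shapes
    putatively neutral variation across a genome. Provides windowed genome
    summaries (SNP density normalized by interspecies divergence, minor
    allele frequency, Tajima's D) with mask-aware filtering, method-of-moments
    and maximum-likelihood estimation of population allele frequencies from
    low-coverage pooled read counts, Nei-Gojobori counting of synonymous and
    nonsynonymous sites and differences, Spearman and partial Spearman
    correlation machinery with permutation and bootstrap inference, and a
    forward-in-time Wright-Fisher simulator of 100 kb windows with
    recombination hotspots, a distribution of fitness effects, selective
    sweeps, and a two-species split demography. Synthetic-data generators
    with known ground truth make the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    IRanges,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
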