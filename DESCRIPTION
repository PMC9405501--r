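Package: sexratio
Title: Molecular Sexing from Low-Quantity Shotgun Data via the X:Autosome Coverage Ratio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies the genetic sex of a single individual from very
    low-quantity shotgun sequencing data mapped to an arbitrary reference
    assembly. Putative X-linked and Y-linked regions of the reference are
    located by synteny to donor sex-chromosome assemblies using a canonical
    k-mer anchor and collinear-chaining mapper; pseudoautosomal overlap is
    masked by interval subtraction; sex is then called from the ratio of mean
    read depth over X-linked sites to mean depth over autosomal sites,
    estimated by replicated random site sampling. Includes a sex-dosage-aware
    genome, assembly and read simulator so the whole pipeline can be validated
    without external data, and an experiment driver that sweeps mapped-read
    counts and reference-assembly quality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    Rsamtools,
    methods,
    tibble,
    tidyr,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
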