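Package: clonephylo
Title: Multi-Sample Subclonal Deconvolution and Clone Tree Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the clonal architecture of a tumour from
    multi-region or multi-metastasis sequencing data. Converts per-sample
    somatic SNV read counts into cancer cell fraction (CCF) estimates using
    tumour purity and allele-specific copy number, removes pseudo-heterogeneity
    explainable by copy-number differences between samples, clusters SNVs
    across samples with a multidimensional Dirichlet-process binomial mixture
    sampled by Gibbs, and reconstructs clone trees under the sum and crossing
    rules implied by the infinite sites assumption. Includes a read-count
    simulator that generates multi-sample SNV data from a known clone tree with
    Poisson coverage and binomial allele sampling, together with orthogonal
    validation calling.
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
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
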