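Package: fikat
Title: Functionally Informed Kernel-Based Rare-Variant Association Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-based rare-variant association testing for quantitative
    traits using variant effect predictions. Implements weighted max-burden
    collapsing and kernel-based variance-component tests (weighted linear,
    locally collapsing by amino-acid position, and a directional RNA-binding
    protein kernel combining effect-vector cosine similarity with a Gaussian
    positional kernel), evaluated with a two-stage score/restricted
    likelihood-ratio procedure (sLRT). Score-test p-values come from the
    Davies chi-square-mixture tail with a saddlepoint fallback; RLRT p-values
    come from exact finite-sample null-statistic sampling pooled across genes
    into a parametric chi-square mixture. Includes Cauchy combination across
    variant categories, exome-style variant QC (minor-allele frequency,
    Hardy-Weinberg exact test, call rate, ancestry-based Fisher pruning),
    PLINK bed/bim/fam input and output, and a simulator generating genotypes,
    annotations and phenotypes with the statistical structure the tests
    assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
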