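Package: ecpgscan
Title: Genome-Wide Methylation-Expression Association Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies expression-associated CpGs (eCpGs) by scanning all
    CpG-transcript pairs with a linear mixed model that corrects for unmeasured
    confounders through an intersample correlation matrix estimated from the
    expression data itself, with genomic-inflation-factor quality control.
    Classifies significant pairs into cis, distal and trans categories and a
    detailed positional taxonomy (near promoter, gene body, closest flanking
    gene, and non-canonical configurations), corroborates results between and
    within studies via exact pair matching with a permutation null and
    neighbor-congruence statistics, performs interval-based functional
    enrichment (CpG island shores and shelves, chromatin states, binding
    sites) with Fisher and hypergeometric tests, and provides analytic power
    and multiple-testing arithmetic. Includes a synthetic-data module that
    generates toy genomes and cohorts with known planted effects so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
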