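Package: deamscan
Title: Deaminase Activity Scanning from Rolling-Circle Consensus Sequencing,
    Kinetics and Resistance Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise the DNA-editing activity of a deaminase
    from three complementary experiments. Simulates and analyses
    rolling-circle (tandem-repeat) consensus sequencing for genome-wide rare
    mutation detection: reads are folded into error-corrected consensus
    fragments, placed on the reference, and summarised as a six-type
    mutation spectrum with reverse-complement-collapsed trinucleotide
    context rates and ANOVA/Tukey group comparisons. Fits single-exponential
    deamination kinetics (apparent rate constant k_app with SEM) to
    cleavage-fraction time courses, computes fold-ratios between substrates,
    and annotates hairpin/linear oligonucleotide substrates including
    enzymatic cleavage read-out fragment sizes. Computes resistance-assay
    mutation frequencies with rank-sum comparisons and classifies
    marker-gene clone mutations with codon and context annotation. A
    synthetic-data module generates every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringi,
    ggplot2,
    generics,
    minpack.lm,
    Biostrings,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
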