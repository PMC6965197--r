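Package: eqpopgen
Title: Genomic Inbreeding and Selection-Signature Analysis for Closed
    Horse Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for SNP-array population genetics in closed
    domestic-animal populations such as the Thoroughbred horse: PLINK text
    and GENEPOP input/output, call-rate/MAF filtering, VIF-based linkage
    pruning and pi-hat relatedness exclusion, individual inbreeding
    coefficients (FIS) and runs-of-homozygosity inbreeding (FROH) with
    temporal trend statistics, sire genotype reconstruction from half-sib
    progeny, composite selection signal (CSS) scans combining FST,
    delta-SAF and XP-EHH, LD-based effective population size, and PCA of
    the genetic relatedness matrix with sigma-outlier iteration. Includes
    forward Wright-Fisher simulators that generate genotype data with
    known ground truth for every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
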