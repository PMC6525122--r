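Package: ampliphase
Title: MHC Class IIa Haplotype Inference from Mixed Amplicon Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising major histocompatibility complex (MHC)
    class IIa haplotypes from Sanger consensus sequences of multi-locus
    amplicons. Observed IUPAC-ambiguity consensus sequences are deconvolved
    into minimal sets of known alleles, multi-locus haplotypes are phased by
    homozygote anchoring with heterozygote subtraction for rare alleles, DQB
    alleles are assigned to loci with a K80/neighbour-joining bootstrap
    phylogeny, and positive selection is assessed with pairwise Nei-Gojobori
    dN/dS and GY94 codon site models (M1a/M2a, M7/M8) compared by likelihood
    ratio tests, with naive empirical Bayes and FEL-style per-site scans. A
    synthetic-data generator emulates diploid populations and the
    assay-specific amplification behaviour of sheep DRB1/DQA/DQB genotyping,
    so the full pipeline can be exercised and calibrated without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
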