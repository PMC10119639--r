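Package: gevodyn
Title: Genome Evolution Dynamics: LTR Insertion Dating, Ks-Based WGD
    Detection, and Selfing Population Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for the genome-evolution questions raised by
    large, repeat-rich selfing plant genomes: k-mer based genome-size
    estimation from depth histograms, dating of long terminal repeat
    retrotransposon (LTR-RT) insertions from 5'/3' LTR divergence with
    solo-LTR screening and transposition-rate curves, Nei-Gojobori (1986)
    synonymous-substitution (Ks) estimation with collinear-block chaining
    and proportional whole-genome-duplication dating, and a SNP filter
    cascade feeding inbreeding-coefficient, selfing-rate and
    sliding-window nucleotide-diversity estimates. Seeded synthetic-data
    generators with truth tables support parameter-recovery testing of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
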