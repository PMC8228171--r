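Package: asmqc
Title: Assembly Quality Assessment and Structural Variation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quality assessment of long-read genome assemblies and
    analysis of structural variation from clone-based and read-depth evidence.
    Implements clone end-pair concordance classification and physical-coverage
    misassembly screening, permutation tests for interval-set enrichment,
    finished-clone global alignment with Phred-scaled per-base accuracy
    estimation, window-based read-depth copy-number estimation with rule-based
    segmental-duplication calling, indel size-spectrum analysis with
    mobile-element peak quantification, and tandem-duplication inference from
    everted read pairs and split-read alignments. Includes a synthetic-data
    generator that produces genomes, clone end pairs, depth tracks and
    error-bearing finished clones with known ground truth for validation.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
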