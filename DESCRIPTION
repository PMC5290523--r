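Package: nanoplex
Title: Forensic SNP Genotyping from Concatenated-Amplicon Nanopore Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genotypes forensic SNP panels from long nanopore reads that are
    random ligation concatemers of short PCR amplicons. Amplicon subreads are
    excised by approximate primer matching (edit distance), orientation
    normalized, locally aligned against 51-nt SNP reference contexts with an
    affine-gap Smith-Waterman aligner, and tabulated into per-locus allele
    counts. Genotypes are called with an allelic-imbalance cut-off rule, and
    loci whose SNP sits in or beside a homopolymer tract are flagged as at
    risk of false indels. A homopolymer-aware read simulator with full truth
    bookkeeping exercises every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
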