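Package: mitodiv
Title: Mitogenome Recovery and Maternal Diversity from Multi-Sample VCFs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Recovers haploid mitochondrial consensus sequences from
    multi-sample short-read VCFs that contain heteroplasmic and
    NUMT-contaminated genotypes, and analyses maternal diversity in the
    recovered mitogenomes. Provides quality filtering at site and animal
    level (QUAL/MQ/allele-count/depth caps, tissue-aware heteroplasmy
    limits), depth-aware consensus base calling with alternate-allele tie
    breaking, piecewise coordinate liftover between mitochondrial reference
    assemblies, haplogroup assignment against defining-variant trees with
    missing and private variant reporting, haplotype and nucleotide
    diversity, AMOVA variance components, haploid genomic relationship
    matrices with PCA, hierarchical haplotype clustering, and a
    masking/imputation cross-validation harness. A synthetic-data module
    generates VCFs, metadata, references and haplogroup definitions with
    the statistical structure of cattle mitogenome cohorts so the whole
    pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
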