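Package: ddcfdna
Title: Donor-Derived Cell-Free DNA Quantification from Informative SNPs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the percentage of donor-derived cell-free DNA
    (ddcfDNA) in a transplant recipient's plasma from whole-genome
    genotypes of the donor-recipient pair and site-level cfDNA allele
    counts. Implements GATK-style hard filtering of annotated variants,
    an unphased informative-SNP index with allele-level discriminating
    sets, a haplotype-aware (phased) donor/recipient variant-set
    comparison, allele calling under a minimum read-support rule,
    per-chromosome and pooled donor-fraction estimators (site-count and
    background-corrected read-fraction), cfDNA fragment-size statistics,
    and rejection-marker correlation reports. A synthetic-data generator
    emulates transplant-pair genomes and cfDNA mixtures at known donor
    fraction so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
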