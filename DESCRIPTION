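Package: recmapr
Title: Carrier-Informed Haplotype Association and Homozygosity Mapping
    for Recessive Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps autosomal recessive Mendelian traits in livestock-style
    pedigrees where only a handful of affected individuals are available for
    genotyping. Implements carrier-informed sliding-window haplotype
    association testing (affected/obligate-carrier/control response coding
    with principal-component stratification correction and genomic-control
    diagnostics), runs-of-homozygosity and shared-autozygosity segment
    detection, and a recessive-compatibility filtering cascade for
    sequence-level candidate variants. Ships a pedigree-structured genotype
    simulator (gene dropping with crossovers through a half-sib design
    seeded with a single carrier founder) that provides full ground truth
    for end-to-end validation, plus readers and writers for the PLINK
    PED/MAP dialect, phased-haplotype tables, sample tables and region VCFs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
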