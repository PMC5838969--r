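Package: arrayqc
Title: Quality Control for SNP Microarray Genotyping with Whole-Genome-Amplified DNA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quality-control pipeline for high-density Infinium-style SNP
    microarray studies that mix native genomic DNA (gDNA) and whole-genome
    amplified DNA (wgaDNA) inputs. Provides per-sample completion and
    heterozygosity metrics, chip- and plate-level systematic failure
    detection, replicate and duplicate-locus genotype concordance,
    GC/CpG-wave renormalization of the Log R Ratio, circular binary
    segmentation of Log R Ratio and mirrored B-allele frequency with
    matched-pair copy-number concordance, and an STR (Identifiler-style)
    profile quality screen. Includes a fully seeded synthetic-data
    generator that emulates Infinium final-report output with
    whole-genome-amplification artifacts (allele drop-out, subtelomeric
    under-amplification, GC waves, chip and plate failures) together with
    truth tables for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
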