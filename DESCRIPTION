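Package: hybridiag
Title: Diagnostic-SNP Detection of Natural Hybrids from Sanger Alignments
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for molecular diagnosis of natural hybrids between two
    parental lineages from pre-aligned mitochondrial and nuclear Sanger
    sequence fragments. Collapses sequences into haplotypes and emits
    variable-site tables, discovers fixed interspecific substitutions,
    scores putative hybrids for heterozygosity at diagnostic positions
    (IUPAC two-base ambiguity codes in direct consensus sequences),
    assigns mitochondrial haplotypes to a maternal lineage, phases cloned
    PCR alleles against diagnostic sites, and computes uncorrected
    p-distances with bootstrap standard errors. Includes a seeded
    synthetic-data generator with ground truth so the whole pipeline is
    testable without sequence downloads, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
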