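Package: haploscan
Title: Rare-Variant Co-Occurrence and Haplotype Case-Control Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans candidate genes for co-occurring rare variants in a
    case-control cohort genotyped by VCF, assesses whether the co-occurring
    alleles lie in cis using a phased reference panel, estimates carrier-based
    haplotype frequencies, and tests case-control association with two-tailed
    Fisher exact or chi-square statistics, relative risks and odds ratios
    against one or more control cohorts.  Includes a deterministic
    synthetic-data generator for cohorts and phased panels so the whole
    pipeline is testable without access to sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    vcfR,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
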