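Package: zygoteMeth
Title: Allele-Specific DNA Methylome Analysis for Hybrid Zygotes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for allele-aware whole-genome bisulfite methylome
    analysis in reciprocal plant hybrids, centred on parental methylation
    remodeling in the zygote. Implements per-cytosine methylation calling
    by sequence context (CG, CHG, CHH), SNP-based partitioning of aligned
    bisulfite reads into parental alleles with N-masking semantics,
    fixed-grid 50-bp differentially methylated region (DMR) detection via
    Fisher's exact test with Benjamini-Hochberg false discovery control,
    tracking of egg-sperm DMRs into hybrid zygotes and embryos with a
    least-squares estimator of the paternal remodeling coefficient, and
    classification of imprinted genes (PEGs/MEGs) from allelic expression
    counts in reciprocal crosses. A seeded synthetic-data generator
    produces parental haplotypes, cell-type methylomes with plantable
    DMRs, bisulfite reads with incomplete-conversion noise, and allelic
    expression counts, so every step of the pipeline is testable against
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
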