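Package: methlink
Title: Integrated Analysis of Cytokinin-Responsive DNA Methylation,
    Allele-Specific Expression, Small RNA Clusters, and Trait Association
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, simulation-backed pipeline for studying how a
    short-term phytohormone treatment (the synthetic cytokinin
    6-benzylaminopurine) reshapes a plant methylome and its downstream
    regulatory layers. The package quantifies per-cytosine methylation from
    bisulfite pileup counts with conversion-rate correction, calls
    differentially methylated regions by a sliding-window Fisher test with
    ANOVA confirmation, quantifies allele-specific expression from allelic
    read depths, calls and normalises 24-nt siRNA clusters, applies
    FPKM-based differential-expression criteria, annotates DMRs with
    overlapping genomic elements, and associates DMR SNPs with quantitative
    traits through a kinship-aware mixed linear model with
    additive/dominance effect decomposition. A synthetic-data module
    generates every input with a machine-readable truth table so each stage
    is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    data.table,
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
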