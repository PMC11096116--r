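Package: cladescope
Title: Clade-Partition Comparative Genomics, Co-Expression Modules and
    WGD Signal Detection
Version: 0.1.0
Authors@R:
    person("Cladescope", "Developers", email = "cladescope@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of protein domain repertoires,
    domain combinations and orthogroups across genomes partitioned into
    clades or body-plan groups: presence/exclusivity (Venn) algebra,
    two-group domain-expansion statistics with exact Wilcoxon tests,
    Fisher/hypergeometric enrichment with Benjamini-Hochberg control,
    highest-reciprocal-rank (HRR) co-expression network construction with
    heuristic cluster chiseling (HCCA) and functional-category
    co-occurrence summaries, and a whole-genome-duplication screening
    workflow (reciprocal best hits, NG86 Ks, corrected 4dtv, kernel
    density peak detection).  A synthetic-data module generates every
    input with planted ground truth so all stages are testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
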