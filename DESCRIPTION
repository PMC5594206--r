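Package: m5cpipe
Title: Transcriptome-Wide RNA Bisulfite Sequencing Analysis of m5C Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of RNA bisulfite sequencing (RNA-BisSeq)
    for 5-methylcytosine (m5C) profiling. Simulates strand-specific paired-end
    bisulfite-converted reads from a toy transcriptome with planted m5C sites
    of known stoichiometry and an unmethylated spike-in control; aligns reads
    in three-letter (C-to-T converted) space; builds per-cytosine pileups,
    computes spike-in conversion-rate QC, and calls credible m5C sites under
    coverage, level and methylated-depth gates; annotates sites by mRNA region
    and CG/CHG/CHH sequence context with transcriptome-proportion
    normalization; computes metagene and CDS positional profiles; gates
    expressed genes by RPKM; classifies sites across conditions
    (tissue-specific, developmental-dynamic, knockdown-regulated) with
    correlation clustering; and intersects sites with RIP peak intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    data.table,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
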