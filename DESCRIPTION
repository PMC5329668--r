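Package: epimatch
Title: Epitope-Based HLA Matching from Low-Resolution Typings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes eplet-mismatch and PIRCHE-II epitope scores for
    donor-recipient pairs when only low-resolution (serological split
    level) HLA typing is available. All high-resolution five-locus
    genotypes consistent with a typing are enumerated from a haplotype
    frequency table, with a step-wise locus-linkage breakdown when no
    full haplotype matches, and epitope scores are averaged over the
    candidate genotypes weighted by their normalized population
    frequencies (multiple imputation). Includes a virtual donor
    population simulator with allocation-rule couple formation,
    log-delta validation statistics, and a deterministic synthetic
    fixture generator for haplotype tables, serology maps, protein
    sequences and eplet registries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    Biostrings,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
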