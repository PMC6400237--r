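Package: hblhb
Title: Discovery and Gene Genealogy of Hexagonal-Bilayer Hemoglobin Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens transcriptome assemblies for the two protein components of
    giant hexagonal-bilayer hemoglobin (HBL-Hb): extracellular globins, validated
    by twelve invariant residues including the diagnostic Cys-19, and linker
    chains, validated by the cysteine-rich LDL-A motif. Provides six-frame ORF
    calling, signature matching, class-specific length and start-methionine
    filters, a similarity prescreen, progressive multiple alignment with
    gap-threshold and start-codon trimming, neighbor-joining gene genealogies
    with bootstrap support and midpoint rooting, monophyly tests for the globin
    (A/B) and linker (L1-L3) chain classes, and a synthetic transcriptome
    generator with planted genes and decoys so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
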