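Package: talscan
Title: Survey of Tail-Associated Lysins in Phage and Prophage Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to survey the tail-associated lysin (TAL) landscape of
    annotated bacteriophage and prophage genomes. Reads GenBank records,
    assigns genes to functional modules (packaging, head, tail, lysis, DNA
    metabolism, lysogeny), locates the tail module between the head and lysis
    modules, resolves the canonical tape measure protein (TMP), distal tail
    protein (Dit) and tail-associated lysin (Tal) unit, scans tail-module
    translations against a packaged motif library to classify lysins into
    five classes (endopeptidase TAEP, tape-measure lytic transglycosylase
    TMP-LT, NLPC/P60 peptidase, glycerophosphodiester phosphodiesterase GDPD
    and pectinesterase), assigns domain-architecture groups, verifies
    class-specific catalytic residues, builds consensus profiles and
    neighbor-joining trees, and aggregates cohort-level landscape summaries.
    A synthetic-genome generator with machine-readable ground truth supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
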