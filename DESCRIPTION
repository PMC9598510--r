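Package: crossddi
Title: Cross-Species Putative Interactomes from Domain-Domain Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs putative protein-protein interactomes between foreign
    (e.g. macroalgal) proteomes and human cancer genes by joining Pfam domain
    annotations through a domain-domain interaction (DDI) table. Includes
    readers for the standard upstream formats (FASTA, HMMER domtblout,
    SignalP 5 and TMHMM 2 short outputs, DOMINE-like DDI tables, GMT gene
    sets), a tumour-suppressor/oncogene catalogue with per-domain dual-role
    ratio classification, interactome summaries and cross-species overlap
    matrices, TSG-hub and secreted-protein filters, an exact hypergeometric
    over-representation test with Benjamini-Hochberg correction, and a
    seeded synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
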