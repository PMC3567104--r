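Package: idpcompare
Title: Comparative Analysis of Intrinsic Protein Disorder Between Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for proteome-scale comparative analysis of intrinsic
    protein disorder. Ingests per-residue disorder and disorder-binding
    score tracks, derives per-protein disorder metrics (relative disorder
    content, long disordered windows, disordered binding regions),
    propagates Gene Ontology annotations to ancestors, and contrasts the
    disorder of GO functional classes between two organisms with
    Yates-corrected chi-square tests, directional excess filtering and
    Benjamini-Hochberg correction. Includes single-organism enrichment of
    disordered protein sets (Fisher/EASE), ortholog-restricted validation
    of class-level disorder differences, SimRel-based semantic
    summarization of GO term lists, and a seeded synthetic-study generator
    with planted class-level disorder enrichment for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    igraph,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
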