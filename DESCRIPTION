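Package: nemtox
Title: Proteotranscriptomic Triage of Candidate Venom Toxins in Ribbon Worms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for discovering and classifying candidate
    venom toxins from paired tissue transcriptomes and secretome proteomes of
    nemerteans (ribbon worms). Implements TMM between-sample normalization, the
    conditional negative-binomial exact test for two-group differential
    expression with Benjamini-Hochberg FDR control, hypergeometric GO-term
    enrichment, two-peptide protein inference from peptide-evidence tables,
    rule-based classification of candidates into predatory, defensive and
    dual-function toxins, minimal-clade phylogenetic profiling of toxin
    orthogroups across a species tree, and average-mass matching of candidates
    against MALDI peak lists. Ships a coupled synthetic-data generator with
    known ground truth so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
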