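test_that("classification matches the hand-enumerated 12-pattern table", {
  for (i in seq_len(nrow(CLASS_TRUTH_TABLE))) {
    row <- CLASS_TRUTH_TABLE[i, ]
    expect_identical(
      classify_toxin(row$de_call, row$in_mucus, row$in_any_proboscis),
      row$expected,
      info = sprintf("(%s, mucus=%s, prob=%s)", row$de_call, row$in_mucus,
                     row$in_any_proboscis))
  }
  # untested behaves as not_de
  expect_identical(classify_toxin("untested", TRUE, TRUE), "dual")
  expect_identical(classify_toxin("untested", TRUE, FALSE), "unclassified")
  expect_error(classify_toxin("sideways", TRUE, TRUE), "de_call")
})

test_that("removing mucus presence follows the rule table, never a shortcut", {
  # dropping in_mucus can move dual -> predatory (for up_proboscis) or
  # dual/defensive -> unclassified, but never predatory -> defensive
  for (de in c("up_proboscis", "up_body", "not_de")) {
    for (prob in c(TRUE, FALSE)) {
      with_mucus <- classify_toxin(de, TRUE, prob)
      without <- classify_toxin(de, FALSE, prob)
      expect_false(with_mucus == "predatory" && without == "defensive")
      expect_identical(
        without,
        CLASS_TRUTH_TABLE$expected[CLASS_TRUTH_TABLE$de_call == de &
                                     !CLASS_TRUTH_TABLE$in_mucus &
                                     CLASS_TRUTH_TABLE$in_any_proboscis == prob])
    }
  }
})

make_annotations <- function(proteins, evalue = 1e-10, family = "Actinoporin-like") {
  annotation_table(data.frame(
    protein_id = proteins, gene_id = sub("\\.p1$", "", proteins),
    subject_id = sprintf("S%d", seq_along(proteins)), evalue = evalue,
    toxin_family = family, domain_label = "", stringsAsFactors = FALSE))
}

test_that("candidate selection needs annotation, e-value and proteome presence", {
  universe <- c("g1.p1", "g2.p1")
  ann <- annotation_table(data.frame(
    protein_id = c("g1.p1", "g2.p1", "g3.p1", "g4.p1"),
    gene_id = c("g1", "g2", "g3", "g4"),
    subject_id = c("S1", "S2", "S3", "S4"),
    evalue = c(1e-10, 1e-4, 1e-20, 1e-30),
    toxin_family = c("Kunitz-type inhibitor", "CAP superfamily",
                     "Parborlasin-like", ""),
    domain_label = "", stringsAsFactors = FALSE))
  sel <- select_candidates(universe, ann)
  # g1: annotated + present -> candidate
  expect_identical(sel$candidates$protein_id, "g1.p1")
  # g2: e-value 1e-4 above the 1e-5 cutoff
  expect_true(any(sel$rejected$protein_id == "g2.p1" &
                    sel$rejected$reason == "evalue_above_cutoff"))
  # g3: toxin-annotated but absent from every proteome
  expect_true(any(sel$rejected$protein_id == "g3.p1" &
                    sel$rejected$reason == "not_in_any_proteome"))
  # g2 also lacks any passing annotation but is in the universe: reported once
  expect_true(any(sel$rejected$protein_id == "g2.p1"))
  # unannotated protein in the universe
  sel2 <- select_candidates(c("g9.p1"), ann)
  expect_true(any(sel2$rejected$protein_id == "g9.p1" &
                    sel2$rejected$reason == "no_toxin_annotation"))
  expect_equal(nrow(sel2$candidates), 0)
  # domain evidence alone qualifies
  ann2 <- annotation_table(data.frame(
    protein_id = "g5.p1", gene_id = "g5", subject_id = "S5", evalue = 1e-9,
    toxin_family = "", domain_label = "ShKT domain", stringsAsFactors = FALSE))
  expect_identical(select_candidates("g5.p1", ann2)$candidates$protein_id,
                   "g5.p1")
})

test_that("classify_all joins evidence, partitions candidates and flags untested", {
  dge <- data.frame(gene_id = c("g1", "g2"), log2FC = c(3, -4),
                    logCPM = 5, p_value = 1e-6, fdr = c(1e-5, 1e-5),
                    call = c("up_proboscis", "up_body"),
                    stringsAsFactors = FALSE)
  class(dge) <- c("DGEResult", "data.frame")
  rows <- rbind(ev_row("PR1", "g1.p1", "PEPTIDEK"), ev_row("PR1", "g1.p1", "LLNK"),
                ev_row("MU", "g2.p1", "AAAK"), ev_row("MU", "g2.p1", "CCCR"),
                ev_row("WA", "g7.p1", "WWWK"), ev_row("WA", "g7.p1", "YYYK"))
  pm <- build_presence_matrix(tiny_evidence(rows))
  sel <- select_candidates(candidate_universe(pm),
                           make_annotations(c("g1.p1", "g2.p1", "g7.p1")))
  tr <- classify_all(sel, dge, pm)
  rec <- tr$records
  expect_equal(nrow(rec), 3)
  expect_identical(rec$assigned_class[rec$protein_id == "g1.p1"], "predatory")
  expect_identical(rec$assigned_class[rec$protein_id == "g2.p1"], "defensive")
  # g7 has no DGE row: untested, never dropped
  g7 <- rec[rec$protein_id == "g7.p1", ]
  expect_identical(g7$de_call, "untested")
  expect_identical(g7$assigned_class, "unclassified")
  expect_true(g7$in_whole_animal)
  # counts partition the candidate set
  expect_equal(sum(tr$class_counts), nrow(rec))
  # assigned classes are consistent with the rule applied to the fields
  for (i in seq_len(nrow(rec)))
    expect_identical(rec$assigned_class[i],
                     classify_toxin(rec$de_call[i], rec$in_mucus[i],
                                    rec$in_any_proboscis[i]))
})

test_that("classify_all output is independent of candidate order", {
  dge <- data.frame(gene_id = sprintf("g%d", 1:4), log2FC = c(3, -3, 0, 5),
                    logCPM = 5, p_value = 1e-5, fdr = 1e-4,
                    call = c("up_proboscis", "up_body", "not_de", "up_proboscis"),
                    stringsAsFactors = FALSE)
  class(dge) <- c("DGEResult", "data.frame")
  rows <- rbind(ev_row("PR1", "g1.p1", "PEPTIDEK"), ev_row("PR1", "g1.p1", "LLNK"),
                ev_row("MU", "g4.p1", "AAAK"), ev_row("MU", "g4.p1", "CCCR"),
                ev_row("PR2", "g4.p1", "DDDK"), ev_row("PR2", "g4.p1", "EEEK"))
  pm <- build_presence_matrix(tiny_evidence(rows))
  sel <- select_candidates(candidate_universe(pm),
                           make_annotations(c("g1.p1", "g4.p1")))
  fwd <- classify_all(sel, dge, pm)
  rev_sel <- sel
  rev_sel$candidates <- sel$candidates[rev(seq_len(nrow(sel$candidates))), ]
  bwd <- classify_all(rev_sel, dge, pm)
  expect_identical(fwd$records, bwd$records)
  expect_identical(fwd$class_counts, bwd$class_counts)
  expect_identical(fwd$records$assigned_class[fwd$records$protein_id == "g4.p1"],
                   "dual")
})

test_that("empty candidate sets give empty records and zero counts", {
  dge <- data.frame(gene_id = "g1", log2FC = 0, logCPM = 1, p_value = 1,
                    fdr = 1, call = "not_de", stringsAsFactors = FALSE)
  class(dge) <- c("DGEResult", "data.frame")
  pm <- build_presence_matrix(tiny_evidence(
    rbind(ev_row("WA", "g1.p1", "AAAK"), ev_row("WA", "g1.p1", "CCCR"))))
  sel <- select_candidates(character(0), make_annotations("g9.p1"))
  tr <- classify_all(sel, dge, pm)
  expect_equal(nrow(tr$records), 0)
  expect_true(all(tr$class_counts == 0))
})

test_that("planted classes are recovered exactly on a noiseless fixture", {
  cfg <- sim_config(n_genes = 600, peptide_count_fixed = 3,
                    decoy_fraction = 0, seed = 91)
  cs <- simulate_counts(cfg)
  ps <- simulate_proteomes(cfg, cs)
  an <- simulate_annotations(cfg, cs)
  truth <- true_classes(cs$truth, ps$truth, an$truth$toxin_proteins)
  # DGE result taken from generator truth: isolates classification + joins
  # from DGE power
  dge <- data.frame(
    gene_id = cs$truth$gene_id, log2FC = cs$truth$true_lfc,
    logCPM = 5, p_value = 1e-9, fdr = 1e-9,
    call = ifelse(cs$truth$de_status == "null", "not_de", cs$truth$de_status),
    stringsAsFactors = FALSE)
  class(dge) <- c("DGEResult", "data.frame")
  pm <- build_presence_matrix(ps$evidence)
  sel <- select_candidates(candidate_universe(pm), an$annotations)
  tr <- classify_all(sel, dge, pm)
  merged <- merge(tr$records[, c("protein_id", "assigned_class")], truth)
  expect_equal(nrow(merged), nrow(tr$records))
  expect_true(all(merged$assigned_class == merged$true_class))
  # candidates are exactly the toxin-annotated proteins in the universe
  expect_setequal(tr$records$protein_id,
                  intersect(an$truth$toxin_proteins, candidate_universe(pm)))
})
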