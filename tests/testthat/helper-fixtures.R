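# Small in-code fixtures shared across test files.

tiny_counts <- function() {
  m <- matrix(c(3, 0, 10, 2,
                1, 7, 12, 9,
                5, 5, 8, 6), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"),
                              c("p1", "p2", "b1", "b2")))
  meta <- data.frame(sample_id = c("p1", "p2", "b1", "b2"),
                     individual_id = c("i1", "i2", "i1", "i2"),
                     tissue = c("proboscis", "proboscis", "body", "body"),
                     stringsAsFactors = FALSE)
  count_matrix(m, meta)
}

tiny_evidence <- function(rows) {
  meta <- data.frame(
    proteome_sample_id = c("WA", "MU", "PR1", "PR2", "PR3"),
    secretome_class = c("whole_animal", "mucus", "proboscis", "proboscis",
                        "proboscis"),
    qvalue_threshold = c(0.01, 0.005, 0.01, 0.01, 0.01),
    stringsAsFactors = FALSE)
  peptide_evidence(rows, meta)
}

ev_row <- function(sample, protein, peptide, q = 0.001) {
  data.frame(proteome_sample_id = sample, protein_id = protein,
             peptide_sequence = peptide, qvalue = q, stringsAsFactors = FALSE)
}

test_tree <- function() {
  ape::read.tree(text = nemtox:::DEFAULT_SPECIES_TREE)
}

# Hand-enumerated truth table over de_call x in_mucus x in_any_proboscis.
# Dual takes precedence; predatory needs proboscis-biased expression plus
# proboscis-only presence; defensive needs body-biased expression plus
# mucus-only presence; everything else is unclassified.
CLASS_TRUTH_TABLE <- data.frame(
  de_call = rep(c("up_proboscis", "up_body", "not_de"), each = 4),
  in_mucus = rep(c(FALSE, FALSE, TRUE, TRUE), 3),
  in_any_proboscis = rep(c(FALSE, TRUE, FALSE, TRUE), 3),
  expected = c(
    "unclassified", "predatory", "unclassified", "dual",     # up_proboscis
    "unclassified", "unclassified", "defensive", "dual",     # up_body
    "unclassified", "unclassified", "unclassified", "dual"), # not_de
  stringsAsFactors = FALSE)

# Independent brute-force oracle for the conditional NB exact test:
# enumerate the full conditional distribution of yA given the total.
enumerate_exact_p <- function(yA, yB, nA, nB, phi) {
  t <- yA + yB
  if (t == 0) return(1)
  k <- 0:t
  pr <- if (phi == 0) {
    stats::dbinom(k, t, nA / (nA + nB))
  } else {
    r <- 1 / phi
    lp <- lgamma(k + nA * r) - lgamma(k + 1) +
      lgamma(t - k + nB * r) - lgamma(t - k + 1)
    exp(lp - max(lp)) / sum(exp(lp - max(lp)))
  }
  sum(pr[pr <= pr[yA + 1] * (1 + 1e-9)])
}

# Independent oracle for minimal-clade assignment: enumerate every named
# clade, filter by leaf-set containment, minimize by leaf count then depth.
enumerate_min_clade <- function(species, tree, focal) {
  if (length(species) == 1 && species == focal) return("species_unique")
  cl <- nemtox:::named_clades(tree)
  keep <- Filter(function(x) all(species %in% x$leaves), cl)
  if (length(keep) == 0) return("root")
  sizes <- vapply(keep, `[[`, numeric(1), "n_leaves")
  depths <- vapply(keep, `[[`, numeric(1), "depth")
  keep[[order(sizes, depths)[1]]]$label
}

# Random rooted tree over n species with every internal node named.
random_named_tree <- function(n_species) {
  sp <- sprintf("sp%02d", seq_len(n_species))
  tree <- ape::rtree(n_species, tip.label = sample(sp))
  tree$node.label <- sprintf("clade%02d", seq_len(tree$Nnode))
  tree
}
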