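test_that("simulated counts honour the planted design and are reproducible", {
  cfg <- sim_config(n_genes = 500, seed = 11)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)
  expect_equal(sum(a$truth$de_status != "null"),
               round(cfg$fraction_de * cfg$n_genes))
  expect_true(all(a$truth$true_lfc[a$truth$de_status != "null"] >= 2))
  expect_true(all(a$truth$true_lfc[a$truth$de_status == "null"] == 0))
  expect_equal(dim(a$counts$counts), c(500, 12))
})

test_that("null config plants nothing and group means agree in expectation", {
  cfg <- sim_config(n_genes = 400, fraction_de = 0, phi = 0.05,
                    library_size_log_sd = 0, seed = 5)
  sim <- simulate_counts(cfg)
  expect_true(all(sim$truth$de_status == "null"))
  tissue <- sim$counts$meta$tissue
  mp <- rowMeans(sim$counts$counts[, tissue == "proboscis"])
  mb <- rowMeans(sim$counts$counts[, tissue == "body"])
  # equal in expectation: paired per-gene means differ only by noise
  expect_lt(abs(mean(log2((mp + 1) / (mb + 1)))), 0.1)
})

test_that("phi = 0 counts are Poisson: variance/mean ratio near 1 at large n", {
  cfg <- sim_config(n_genes = 300, n_replicates_per_tissue = 200,
                    fraction_de = 0, phi = 0, library_size_log_sd = 0,
                    seed = 9)
  sim <- simulate_counts(cfg)
  m <- sim$counts$counts
  ratio <- apply(m, 1, stats::var) / rowMeans(m)
  keep <- rowMeans(m) > 5
  expect_lt(abs(median(ratio[keep]) - 1), 0.1)
})

test_that("NB moments match mean mu and variance mu + phi mu^2", {
  phi <- 0.2
  cfg <- sim_config(n_genes = 200, n_replicates_per_tissue = 400,
                    fraction_de = 0, phi = phi, library_size_log_sd = 0,
                    baseline_sdlog = 0.5, seed = 21)
  sim <- simulate_counts(cfg)
  m <- sim$counts$counts
  mu <- rowMeans(m)
  v <- apply(m, 1, stats::var)
  keep <- mu > 20
  rel <- (v[keep] - (mu[keep] + phi * mu[keep]^2)) / (mu[keep] + phi * mu[keep]^2)
  expect_lt(abs(median(rel)), 0.15)
})

test_that("proteome simulation is seeded and encodes presence truthfully", {
  cfg <- sim_config(n_genes = 300, seed = 13)
  cs <- simulate_counts(cfg)
  a <- simulate_proteomes(cfg, cs)
  b <- simulate_proteomes(cfg, cs)
  expect_identical(a$evidence$rows, b$evidence$rows)
  # true presence means >=2 distinct passing peptides: the two-peptide rule
  # applied to the evidence must reproduce the recorded truth exactly
  pm <- build_presence_matrix(a$evidence)
  common <- intersect(rownames(pm$matrix), rownames(a$truth$presence))
  expect_identical(pm$matrix[common, colnames(a$truth$presence)],
                   a$truth$presence[common, ])
  absent <- setdiff(rownames(a$truth$presence), rownames(pm$matrix))
  expect_true(all(!a$truth$presence[absent, ]))
})

test_that("forcing one peptide per protein yields an all-absent presence matrix", {
  cfg <- sim_config(n_genes = 200, peptide_count_fixed = 1,
                    decoy_fraction = 0, seed = 17)
  cs <- simulate_counts(cfg)
  ps <- simulate_proteomes(cfg, cs)
  expect_gt(nrow(ps$evidence$rows), 0)
  pm <- build_presence_matrix(ps$evidence)
  expect_false(any(pm$matrix))
  expect_length(candidate_universe(pm), 0)
})

test_that("steep detection slope detects every highly expressed protein", {
  cfg <- sim_config(n_genes = 150, detect_slope = 60, detect_intercept = -150,
                    peptide_count_fixed = 3, decoy_fraction = 0, seed = 19)
  cs <- simulate_counts(cfg)
  ps <- simulate_proteomes(cfg, cs)
  pm <- build_presence_matrix(ps$evidence)
  mu <- nemtox:::true_tissue_means(cs$truth)
  high <- cs$truth$gene_id[mu[, "proboscis"] > 100]
  high_p <- paste0(high, ".p1")
  prob_cols <- pm$sample_meta$proteome_sample_id[
    pm$sample_meta$secretome_class == "proboscis"]
  detected <- rownames(pm$matrix)[rowSums(
    pm$matrix[, prob_cols, drop = FALSE]) == length(prob_cols)]
  expect_true(all(high_p %in% detected))
})

test_that("orthogroup simulation recovers config clades and is seeded", {
  cfg <- sim_config(seed = 23)
  a <- simulate_orthogroups(cfg)
  b <- simulate_orthogroups(cfg)
  expect_identical(a$truth$orthogroups$true_clade, b$truth$orthogroups$true_clade)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_equal(nrow(a$truth$orthogroups), cfg$n_orthogroups)
  # species_unique orthogroups contain only the focal species
  og <- a$orthogroups
  uniq <- a$truth$orthogroups$orthogroup_id[
    a$truth$orthogroups$true_clade == "species_unique"]
  expect_true(all(og$species_id[og$orthogroup_id %in% uniq] ==
                    cfg$focal_species))
})

test_that("sharing mass on the root makes every orthogroup span all species", {
  cfg <- sim_config(n_orthogroups = 12,
                    clade_sharing_probs = c(Nemertea = 1), seed = 29)
  sim <- simulate_orthogroups(cfg)
  per_og <- tapply(sim$orthogroups$species_id, sim$orthogroups$orthogroup_id,
                   length)
  expect_true(all(per_og == length(sim$tree$tip.label)))
})

test_that("unknown clade names in the config are rejected", {
  cfg <- sim_config(clade_sharing_probs = c(Atlantonemertea = 1))
  expect_error(simulate_orthogroups(cfg), "Atlantonemertea")
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(phi = -0.1), "phi")
  expect_error(sim_config(fraction_de = 1.2), "probabilities")
  expect_error(sim_config(n_genes = 0), "n_genes")
})

test_that("full study fixture round-trips through the on-disk formats", {
  dir <- withr::local_tempdir()
  st <- simulate_study(sim_config(n_genes = 200, seed = 31))
  files <- write_fixture(st, dir)
  expect_true(all(file.exists(files)))
  cm <- read_count_matrix(files[["counts"]], files[["samples"]])
  expect_equal(cm$counts, st$counts$counts)
  ev <- read_peptide_evidence(files[["peptides"]], files[["proteome_samples"]])
  expect_equal(nrow(ev$rows), nrow(st$evidence$rows))
  tree <- read_newick(files[["tree"]])
  expect_identical(ape::write.tree(tree), ape::write.tree(st$tree))
})
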