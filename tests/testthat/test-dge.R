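test_that("TMM factors: identical libraries give factors of exactly 1", {
  m <- matrix(rpois(400, 50), nrow = 100, ncol = 4,
              dimnames = list(sprintf("g%d", 1:100), sprintf("s%d", 1:4)))
  m <- m[, c(1, 1, 1, 1)]
  colnames(m) <- sprintf("s%d", 1:4)
  expect_equal(unname(tmm_factors(m)), rep(1, 4))
})

test_that("TMM factors agree closely with the established implementation", {
  skip_if_not_installed("edgeR")
  # weights here use depth-normalized proportions (making factors exactly
  # depth-invariant), so agreement with the raw-count-weighted reference is
  # close but not bitwise
  set.seed(42)
  for (trial in 1:3) {
    m <- matrix(rnbinom(3000, mu = rlnorm(300, log(40), 1), size = 5),
                nrow = 300, ncol = 10)
    depth <- exp(rnorm(10, 0, 0.5))
    m <- round(sweep(m, 2, depth, "*"))
    dimnames(m) <- list(sprintf("g%d", 1:300), sprintf("s%d", 1:10))
    theirs <- edgeR::calcNormFactors(m, method = "TMM")
    expect_lt(max(abs(tmm_factors(m) - theirs) / theirs), 0.02)
  }
})

test_that("TMM factor is invariant to a pure depth change of one sample", {
  set.seed(7)
  m <- matrix(rnbinom(2400, mu = rlnorm(200, log(30), 1), size = 8),
              nrow = 200, ncol = 12,
              dimnames = list(sprintf("g%d", 1:200), sprintf("s%d", 1:12)))
  f0 <- tmm_factors(m)
  m2 <- m
  m2[, 3] <- m[, 3] * 2L  # doubling every count: depth only, composition fixed
  f1 <- tmm_factors(m2)
  expect_lt(abs(f1[3] - f0[3]), 1e-6)
})

test_that("TMM factors have geometric mean 1 and reject all-zero samples", {
  set.seed(8)
  m <- matrix(rpois(1000, 20), nrow = 100, ncol = 10,
              dimnames = list(sprintf("g%d", 1:100), sprintf("s%d", 1:10)))
  f <- tmm_factors(m)
  expect_lt(abs(exp(mean(log(f))) - 1), 1e-12)
  m[, 2] <- 0
  expect_error(tmm_factors(m), "all-zero")
})

test_that("exact NB test matches enumeration, symmetry and closed forms", {
  expect_equal(nb_exact_test(5, 0, 3, 3, 0), 0.0625)
  expect_equal(nb_exact_test(8, 8, 4, 4, 0.3), 1.0)
  expect_equal(nb_exact_test(0, 0, 4, 4, 0.1), 1.0)
  set.seed(101)
  for (i in 1:60) {
    t <- sample(1:30, 1)
    yA <- sample(0:t, 1)
    nA <- sample(1:6, 1)
    nB <- sample(1:6, 1)
    phi <- sample(c(0, 0.05, 0.5), 1)
    p <- nb_exact_test(yA, t - yA, nA, nB, phi)
    expect_equal(p, enumerate_exact_p(yA, t - yA, nA, nB, phi),
                 tolerance = 1e-9)
    expect_equal(p, nb_exact_test(t - yA, yA, nB, nA, phi), tolerance = 1e-12)
    expect_true(p > 0 && p <= 1)
  }
  expect_error(nb_exact_test(-1, 3, 2, 2, 0.1), "non-negative")
  expect_error(nb_exact_test(1, 3, 2, 2, -0.1), ">= 0")
})

test_that("common dispersion recovers the simulation parameter", {
  sim <- simulate_counts(sim_config(n_genes = 2000, phi = 0.1, seed = 77))
  phi_hat <- estimate_common_dispersion(sim$counts)
  expect_gt(phi_hat, 0.05)
  expect_lt(phi_hat, 0.2)
})

test_that("common dispersion hits the Poisson boundary on Poisson data", {
  sim <- simulate_counts(sim_config(n_genes = 2000, phi = 0, seed = 78))
  expect_lte(estimate_common_dispersion(sim$counts), 0.02)
})

test_that("dispersion of identical replicates is zero", {
  m <- matrix(7L, nrow = 1, ncol = 12,
              dimnames = list("g1", sprintf("s%d", 1:12)))
  meta <- data.frame(sample_id = sprintf("s%d", 1:12),
                     individual_id = rep(sprintf("i%d", 1:6), 2),
                     tissue = rep(c("proboscis", "body"), each = 6))
  cm <- count_matrix(m, meta)
  expect_equal(estimate_common_dispersion(cm, factors = rep(1, 12)), 0)
})

test_that("common dispersion tracks the established estimator", {
  skip_if_not_installed("edgeR")
  sim <- simulate_counts(sim_config(n_genes = 1500, phi = 0.15, seed = 79))
  d <- edgeR::DGEList(sim$counts$counts, group = sim$counts$meta$tissue)
  d <- edgeR::calcNormFactors(d)
  d <- edgeR::estimateCommonDisp(d)
  expect_equal(estimate_common_dispersion(sim$counts), d$common.dispersion,
               tolerance = 0.15)
})

test_that("run_dge applies the call-rule thresholds exactly", {
  sim <- simulate_counts(sim_config(n_genes = 800, seed = 55))
  res <- run_dge(sim$counts, dge_config(alpha = 0.001, min_lfc = 2))
  tested <- res$call != "untested"
  de <- res$call %in% c("up_proboscis", "up_body")
  expect_true(all(res$fdr[de] < 0.001))
  expect_true(all(abs(res$log2FC[de]) >= 2))
  # threshold semantics: fdr in [alpha, 1) never called, whatever the FC
  expect_true(all(res$call[tested & res$fdr >= 0.001] == "not_de"))
  # genes failing only the fold-change bar are also not called
  expect_true(all(res$call[tested & abs(res$log2FC) < 2] == "not_de"))
  # calls partition tested genes
  expect_true(all(res$call[tested] %in% c("up_proboscis", "up_body", "not_de")))
  # BH monotonicity: fdr >= p, and ordering by p implies ordering by fdr
  ok <- tested & !is.na(res$p_value)
  expect_true(all(res$fdr[ok] >= res$p_value[ok] - 1e-12))
  o <- order(res$p_value[ok])
  expect_true(all(diff(res$fdr[ok][o]) > -1e-12))
})

test_that("run_dge excludes all-zero genes as untested and needs both tissues", {
  sim <- simulate_counts(sim_config(n_genes = 300, seed = 57))
  cm <- sim$counts
  cm$counts[5, ] <- 0
  res <- run_dge(cm, dge_config(dispersion = 0.1))
  expect_equal(res$call[5], "untested")
  expect_true(is.na(res$p_value[5]))
  keep <- cm$meta$tissue == "proboscis"
  cm_bad <- cm
  cm_bad$counts <- cm_bad$counts[, keep]
  cm_bad$meta <- cm_bad$meta[keep, ]
  cm_bad$samples <- cm_bad$samples[keep]
  expect_error(run_dge(cm_bad, dge_config()), "tissue")
})

test_that("planted fold changes are recovered with the right sign", {
  sim <- simulate_counts(sim_config(n_genes = 1000, phi = 0.1,
                                    lfc_range = c(4, 4), seed = 60))
  res <- run_dge(sim$counts, dge_config(alpha = 0.001, min_lfc = 2,
                                        dispersion = 0.1))
  truth <- sim$truth
  de_true <- truth$de_status != "null"
  called <- res$call %in% c("up_proboscis", "up_body")
  sens <- mean(called[de_true])
  expect_gt(sens, 0.8)
  hits <- de_true & called
  expect_gt(mean(res$call[hits] == truth$de_status[hits]), 0.99)
})

test_that("hypergeometric enrichment matches closed-form combinatorics", {
  genes <- sprintf("g%d", 1:10)
  ann <- data.frame(gene_id = genes[1:5], term = "T1")
  res <- enrich_terms(target = genes[1:4], background = genes[5:10],
                      annotations = ann)
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-12)
  expect_equal(res$enrichment_fold, 2.0)
  expect_equal(res$b, 4)
  expect_equal(res$B, 5)
  expect_equal(res$N, 10)
})

test_that("enrichment fold is 1 when target and background rates agree", {
  genes <- sprintf("g%d", 1:20)
  ann <- data.frame(gene_id = genes[c(1:2, 5:12)], term = "T1")
  res <- enrich_terms(target = genes[1:4], background = genes,
                      annotations = ann)
  expect_equal(res$enrichment_fold, 1)
  expect_error(enrich_terms(character(0), genes, ann), "non-empty")
})

test_that("a planted enriched term ranks first across seeded simulations", {
  wins <- 0L
  for (seed in 1:20) {
    cfg <- sim_config(n_genes = 1000, go_enriched_fold = 5, seed = seed)
    cs <- simulate_counts(cfg)
    an <- simulate_annotations(cfg, cs)
    target <- cs$truth$gene_id[cs$truth$de_status == "up_proboscis"]
    res <- enrich_terms(target, setdiff(cs$truth$gene_id, target), an$go)
    if (res$term[1] == an$truth$enriched_term) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})
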