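# Default ten-species nemertean backbone. Named clades cover the reporting
# vocabulary of the lineage analysis: the root (Nemertea), the two classical
# clades (Palaeonemertea and its sister Neonemertea = Pilidiophora +
# Hoplonemertea), and the focal genus Antarctonemertes.
DEFAULT_SPECIES_TREE <-
  paste0("((Tubulanus_polymorphus,Cephalothrix_hongkongiensis)Palaeonemertea,",
         "((Lineus_longissimus,(Riseriellus_occultus,Notospermus_geniculatus))Pilidiophora,",
         "((Emplectonema_gracile,Paranemertes_peregrina),",
         "((Antarctonemertes_valida,Antarctonemertes_riesgoae)Antarctonemertes,",
         "Malacobdella_grossa))Hoplonemertea)Neonemertea)Nemertea;")

#' Simulation configuration for the coupled synthetic study
#'
#' Defines the generative model for a desk-scale replica of the study design:
#' paired proboscis/body RNA-seq libraries from six individuals, five
#' proteome samples (one whole animal, one defensive mucus, three proboscis),
#' toxin-homology annotations, and toxin orthogroups shared across a
#' ten-species nemertean tree. All downstream ground truth (DE status,
#' secretome presence, toxin class, minimal clade) is recorded.
#'
#' @param n_genes number of genes (default 2000).
#' @param n_replicates_per_tissue libraries per tissue (default 6).
#' @param library_size_log_sd sd of log-normal relative library sizes
#'   (default 0.3; makes TMM non-trivial).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of per-gene
#'   baseline mean expression (defaults log(30), 1.2).
#' @param phi negative-binomial dispersion (>= 0; 0 gives Poisson counts).
#' @param fraction_de fraction of genes with a planted fold change.
#' @param lfc_range range of planted |log2 fold changes| (default c(2, 6)).
#' @param de_split_proboscis fraction of DE genes upregulated in the
#'   proboscis (default 0.5).
#' @param n_whole,n_mucus,n_proboscis proteome samples per secretome class
#'   (defaults 1, 1, 3).
#' @param detect_intercept,detect_slope logistic detection model: a protein
#'   is detected in a proteome sample with probability
#'   `plogis(intercept + slope * log1p(mean expression in the matching
#'   tissue))`; the whole-animal sample uses the across-tissue mean.
#' @param peptide_lambda detected proteins receive `1 + rpois(peptide_lambda)`
#'   distinct peptides (support includes 1, exercising the two-peptide rule).
#' @param peptide_count_fixed if not `NA`, every detected protein gets exactly
#'   this many distinct peptides (used for noiseless fixtures).
#' @param decoy_fraction fraction of detected (protein, sample) pairs that
#'   also emit one decoy row with q-value above the threshold.
#' @param qvalue_thresholds named vector of per-class identification
#'   thresholds (defaults: whole_animal 0.01, proboscis 0.01, mucus 0.005,
#'   mirroring an LC-MS/MS PSM FDR of 1% and a shotgun local FDR of 0.5%).
#' @param fraction_toxin fraction of genes carrying a toxin-homology
#'   annotation at a passing e-value.
#' @param species_tree Newick string for the backbone tree.
#' @param focal_species focal species leaf id.
#' @param n_orthogroups number of toxin orthogroups to simulate.
#' @param clade_sharing_probs named probabilities over `species_unique` and
#'   named clades of the backbone; each orthogroup's true minimal clade is
#'   drawn from this. Defaults are proportional to the sharing pattern of a
#'   hoplonemertean toxin repertoire (29 focal-unique : 6 genus : 13
#'   Hoplonemertea : 2 Pilidiophora+Hoplonemertea : 9 pan-nemertean).
#' @param orthogroup_dropout probability that a non-focal species of the true
#'   clade is missing from an orthogroup (default 0 = noiseless).
#' @param n_go_terms,go_terms_per_gene,go_enriched_fold GO simulation: flat
#'   term labels assigned at random, with one planted term over-represented
#'   in the proboscis-upregulated DE set at the given fold.
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @return list of class `SimulationConfig`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_replicates_per_tissue = 6,
                       library_size_log_sd = 0.3,
                       baseline_meanlog = log(30),
                       baseline_sdlog = 1.2,
                       phi = 0.1,
                       fraction_de = 0.1,
                       lfc_range = c(2, 6),
                       de_split_proboscis = 0.5,
                       n_whole = 1, n_mucus = 1, n_proboscis = 3,
                       detect_intercept = -6,
                       detect_slope = 1.2,
                       peptide_lambda = 3,
                       peptide_count_fixed = NA,
                       decoy_fraction = 0.05,
                       qvalue_thresholds = c(whole_animal = 0.01,
                                             mucus = 0.005,
                                             proboscis = 0.01),
                       fraction_toxin = 0.06,
                       species_tree = DEFAULT_SPECIES_TREE,
                       focal_species = "Antarctonemertes_valida",
                       n_orthogroups = 59,
                       clade_sharing_probs = c(species_unique = 29,
                                               Antarctonemertes = 6,
                                               Hoplonemertea = 13,
                                               Neonemertea = 2,
                                               Nemertea = 9) / 59,
                       orthogroup_dropout = 0,
                       n_go_terms = 40,
                       go_terms_per_gene = 4,
                       go_enriched_fold = 5,
                       seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(cfg$fraction_de, cfg$de_split_proboscis, cfg$decoy_fraction,
             cfg$orthogroup_dropout, cfg$clade_sharing_probs,
             cfg$qvalue_thresholds)
  if (any(probs < 0 | probs > 1)) stop_fmt("all probabilities must lie in [0,1]")
  if (cfg$phi < 0) stop_fmt("dispersion phi must be >= 0")
  if (cfg$n_genes < 1) stop_fmt("n_genes must be >= 1")
  if (abs(sum(cfg$clade_sharing_probs) - 1) > 1e-8)
    stop_fmt("clade_sharing_probs must sum to 1")
  structure(cfg, class = "SimulationConfig")
}

gene_ids <- function(n) sprintf("g%05d", seq_len(n))
protein_of <- function(gene) paste0(gene, ".p1")

# Per-gene true mean expression in each tissue given baseline and planted FC.
true_tissue_means <- function(truth) {
  up_p <- truth$de_status == "up_proboscis"
  up_b <- truth$de_status == "up_body"
  mu_p <- truth$baseline * ifelse(up_p, 2^truth$true_lfc, 1)
  mu_b <- truth$baseline * ifelse(up_b, 2^truth$true_lfc, 1)
  cbind(proboscis = mu_p, body = mu_b)
}

#' Simulate the paired-tissue RNA-seq count matrix with planted fold changes
#'
#' Counts are negative-binomially distributed with per-gene baselines drawn
#' log-normally, log-normal relative library sizes, and exactly
#' `round(fraction_de * n_genes)` genes carrying a planted |log2FC| in the
#' configured range, split between tissues.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (a `CountMatrix`) and `truth` (data.frame
#'   `gene_id`, `de_status` in up_proboscis/up_body/null, `true_lfc`,
#'   `baseline`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n <- config$n_genes
  nrep <- config$n_replicates_per_tissue
  genes <- gene_ids(n)
  baseline <- stats::rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  n_de <- round(config$fraction_de * n)
  de_status <- rep("null", n)
  true_lfc <- rep(0, n)
  if (n_de > 0) {
    de_ix <- sample.int(n, n_de)
    n_up <- round(config$de_split_proboscis * n_de)
    dirs <- c(rep("up_proboscis", n_up), rep("up_body", n_de - n_up))
    de_status[de_ix] <- dirs
    true_lfc[de_ix] <- stats::runif(n_de, config$lfc_range[1], config$lfc_range[2])
  }
  truth <- data.frame(gene_id = genes, de_status = de_status,
                      true_lfc = true_lfc, baseline = baseline,
                      stringsAsFactors = FALSE)
  mu_tissue <- true_tissue_means(truth)
  samples <- c(sprintf("prob_%d", seq_len(nrep)), sprintf("body_%d", seq_len(nrep)))
  tissue <- rep(c("proboscis", "body"), each = nrep)
  indiv <- rep(sprintf("ind_%d", seq_len(nrep)), times = 2)
  size_fac <- stats::rlnorm(2 * nrep, 0, config$library_size_log_sd)
  counts <- matrix(0, nrow = n, ncol = 2 * nrep,
                   dimnames = list(genes, samples))
  for (j in seq_len(2 * nrep)) {
    mu <- mu_tissue[, tissue[j]] * size_fac[j]
    counts[, j] <- if (config$phi == 0) stats::rpois(n, mu)
                   else stats::rnbinom(n, mu = mu, size = 1 / config$phi)
  }
  meta <- data.frame(sample_id = samples, individual_id = indiv,
                     tissue = tissue, stringsAsFactors = FALSE)
  list(counts = count_matrix(counts, meta), truth = truth)
}

random_peptides <- function(k, min_len = 8, max_len = 25) {
  out <- character(0)
  while (length(out) < k) {
    lens <- sample(min_len:max_len, k - length(out), replace = TRUE)
    out <- unique(c(out, vapply(lens, function(l)
      paste(sample(AA_ALPHABET, l, replace = TRUE), collapse = ""),
      character(1))))
  }
  out[seq_len(k)]
}

#' Simulate the five secretome proteomes with expression-dependent detection
#'
#' Every gene contributes one predicted protein. Detection in a proteome
#' sample follows a logistic model in log mean expression of the matching
#' tissue (proboscis samples: proboscis expression; mucus: body expression,
#' as mucus is secreted from the body wall; whole animal: the across-tissue
#' mean). Detected proteins receive a configured number of distinct random
#' peptides with passing q-values; decoy rows above the threshold are added
#' at the configured rate. True presence (the label the two-peptide rule
#' should recover) is `detected AND >= 2 distinct peptides`.
#'
#' @param config a [sim_config()].
#' @param counts_sim result of [simulate_counts()] under the same config.
#' @return list with `evidence` (a `PeptideEvidenceTable`) and `truth`
#'   (list: `presence` logical protein x sample matrix, `summary` data.frame
#'   with true `in_mucus`, `in_any_proboscis`, `in_whole_animal`).
#' @export
simulate_proteomes <- function(config, counts_sim) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1L)
  truth_g <- counts_sim$truth
  proteins <- protein_of(truth_g$gene_id)
  mu <- true_tissue_means(truth_g)
  sample_meta <- data.frame(
    proteome_sample_id = c(sprintf("whole_%d", seq_len(config$n_whole)),
                           sprintf("mucus_%d", seq_len(config$n_mucus)),
                           sprintf("prob_sec_%d", seq_len(config$n_proboscis))),
    secretome_class = rep(c("whole_animal", "mucus", "proboscis"),
                          times = c(config$n_whole, config$n_mucus,
                                    config$n_proboscis)),
    stringsAsFactors = FALSE)
  sample_meta$qvalue_threshold <-
    unname(config$qvalue_thresholds[sample_meta$secretome_class])
  x_by_class <- cbind(
    whole_animal = log1p(rowMeans(mu)),
    mucus = log1p(mu[, "body"]),
    proboscis = log1p(mu[, "proboscis"]))
  pres <- matrix(FALSE, nrow = length(proteins), ncol = nrow(sample_meta),
                 dimnames = list(proteins, sample_meta$proteome_sample_id))
  rows <- vector("list", nrow(sample_meta))
  for (s in seq_len(nrow(sample_meta))) {
    cls <- sample_meta$secretome_class[s]
    thr <- sample_meta$qvalue_threshold[s]
    p_det <- stats::plogis(config$detect_intercept +
                             config$detect_slope * x_by_class[, cls])
    detected <- stats::runif(length(proteins)) < p_det
    idx <- which(detected)
    if (length(idx) == 0) next
    k <- if (!is.na(config$peptide_count_fixed))
      rep(config$peptide_count_fixed, length(idx))
    else 1 + stats::rpois(length(idx), config$peptide_lambda)
    pres[idx, s] <- k >= 2
    peps <- lapply(k, random_peptides)
    block <- data.frame(
      proteome_sample_id = sample_meta$proteome_sample_id[s],
      protein_id = rep(proteins[idx], k),
      peptide_sequence = unlist(peps, use.names = FALSE),
      qvalue = stats::runif(sum(k), 0, thr),
      stringsAsFactors = FALSE)
    n_decoy <- stats::rbinom(1, length(idx), config$decoy_fraction)
    if (n_decoy > 0) {
      dix <- sample(idx, n_decoy)
      block <- rbind(block, data.frame(
        proteome_sample_id = sample_meta$proteome_sample_id[s],
        protein_id = proteins[dix],
        peptide_sequence = random_peptides(n_decoy),
        qvalue = stats::runif(n_decoy, thr + 1e-6, 1),
        stringsAsFactors = FALSE))
    }
    rows[[s]] <- block
  }
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    rows <- data.frame(proteome_sample_id = character(),
                       protein_id = character(),
                       peptide_sequence = character(), qvalue = numeric(),
                       stringsAsFactors = FALSE)
  cls <- sample_meta$secretome_class
  summary <- data.frame(
    protein_id = proteins,
    gene_id = truth_g$gene_id,
    in_mucus = rowSums(pres[, cls == "mucus", drop = FALSE]) > 0,
    in_any_proboscis = rowSums(pres[, cls == "proboscis", drop = FALSE]) > 0,
    in_whole_animal = rowSums(pres[, cls == "whole_animal", drop = FALSE]) > 0,
    stringsAsFactors = FALSE)
  list(evidence = peptide_evidence(rows, sample_meta),
       truth = list(presence = pres, summary = summary))
}

TOXIN_FAMILIES <- c("Cytotoxin A-like", "M12 astacin metalloprotease",
                    "Actinoporin-like", "Kunitz-type inhibitor",
                    "CAP superfamily", "Parborlasin-like",
                    "Nemertide alpha-like", "Plancitoxin-like")
DOMAIN_LABELS <- c("ShKT domain", "Galactose-binding lectin domain",
                   "EGF-like domain", "Peptidase M12 domain",
                   "Kazal-type domain", "")

#' Simulate toxin-homology annotations and flat GO labels
#'
#' A configured fraction of genes receives a toxin-family and/or domain
#' annotation at a passing e-value; a handful of extra proteins get a
#' too-weak e-value or a non-toxin hit to exercise the selection filters.
#' GO terms are flat labels assigned at random, with one planted term
#' over-represented among proboscis-upregulated DE genes.
#'
#' @param config a [sim_config()].
#' @param counts_sim result of [simulate_counts()].
#' @return list with `annotations` (an `AnnotationTable`), `go` (data.frame
#'   `gene_id`, `term`), and `truth` (list: `toxin_proteins`,
#'   `enriched_term`).
#' @export
simulate_annotations <- function(config, counts_sim) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 2L)
  truth_g <- counts_sim$truth
  n <- nrow(truth_g)
  n_tox <- max(1, round(config$fraction_toxin * n))
  # bias toxin annotations toward DE genes so planted classes are populated
  w <- ifelse(truth_g$de_status == "null", 1, 6)
  tox_ix <- sample.int(n, n_tox, prob = w)
  tox_genes <- truth_g$gene_id[tox_ix]
  ann <- data.frame(
    protein_id = protein_of(tox_genes),
    gene_id = tox_genes,
    subject_id = sprintf("UniProt_TOX%04d", seq_len(n_tox)),
    evalue = 10^stats::runif(n_tox, -30, -6),
    toxin_family = sample(TOXIN_FAMILIES, n_tox, replace = TRUE),
    domain_label = sample(DOMAIN_LABELS, n_tox, replace = TRUE),
    stringsAsFactors = FALSE)
  # weak hits (e-value above cutoff) and non-toxin hits
  other <- sample(setdiff(truth_g$gene_id, tox_genes), min(20, n - n_tox))
  half <- length(other) %/% 2
  weak <- data.frame(
    protein_id = protein_of(other[seq_len(half)]),
    gene_id = other[seq_len(half)],
    subject_id = sprintf("UniProt_WEAK%03d", seq_len(half)),
    evalue = 10^stats::runif(half, -4.5, -1),
    toxin_family = sample(TOXIN_FAMILIES, half, replace = TRUE),
    domain_label = "",
    stringsAsFactors = FALSE)
  rest <- other[(half + 1):length(other)]
  nontox <- data.frame(
    protein_id = protein_of(rest),
    gene_id = rest,
    subject_id = sprintf("UniProt_HK%03d", seq_along(rest)),
    evalue = 10^stats::runif(length(rest), -50, -10),
    toxin_family = "",
    domain_label = "",
    stringsAsFactors = FALSE)
  annotations <- annotation_table(rbind(ann, weak, nontox))
  # flat GO labels
  terms <- sprintf("GO:%07d", seq_len(config$n_go_terms))
  p0 <- config$go_terms_per_gene / config$n_go_terms
  assign <- matrix(stats::runif(n * config$n_go_terms) < p0,
                   nrow = n, ncol = config$n_go_terms)
  up_p <- truth_g$de_status == "up_proboscis"
  p_enriched <- min(1, config$go_enriched_fold * p0)
  assign[up_p, 1] <- stats::runif(sum(up_p)) < p_enriched
  hits <- which(assign, arr.ind = TRUE)
  go <- data.frame(gene_id = truth_g$gene_id[hits[, 1]],
                   term = terms[hits[, 2]], stringsAsFactors = FALSE)
  go <- go[order(go$gene_id, go$term), ]
  rownames(go) <- NULL
  list(annotations = annotations, go = go,
       truth = list(toxin_proteins = protein_of(tox_genes),
                    enriched_term = terms[1]))
}

#' Simulate toxin orthogroups over the nemertean backbone tree
#'
#' Each orthogroup draws a true minimal clade from the configured sharing
#' probabilities; its species set is all leaves of that clade (each non-focal
#' species independently dropped with the configured dropout probability; 0
#' by default, making minimal-clade recovery exact). Focal-species members
#' are toxin sequence ids; orthogroups whose true label is `species_unique`
#' contain only focal sequences.
#'
#' @param config a [sim_config()].
#' @param toxin_ids optional pool of focal-species toxin sequence ids to
#'   distribute over orthogroups; generated when `NULL`. Ids left
#'   unassigned represent toxins with no orthologs anywhere.
#' @return list with `orthogroups` (an `OrthogroupTable`), `tree` (`phylo`),
#'   and `truth` (data.frame `orthogroup_id`, `true_clade`, plus attribute-free
#'   list fields `assigned_toxins` and `unassigned_toxins`).
#' @export
simulate_orthogroups <- function(config, toxin_ids = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 3L)
  tree <- validate_species_tree(ape::read.tree(text = config$species_tree))
  clades <- named_clades(tree)
  labels <- names(config$clade_sharing_probs)
  missing <- setdiff(setdiff(labels, "species_unique"), names(clades))
  if (length(missing) > 0)
    stop_fmt("clade name(s) absent from tree: %s", paste(missing, collapse = ", "))
  if (!config$focal_species %in% tree$tip.label)
    stop_fmt("focal species '%s' is not a leaf of the tree", config$focal_species)
  n_og <- config$n_orthogroups
  if (!is.null(toxin_ids))  # every orthogroup needs >=1 focal toxin member
    n_og <- min(n_og, length(toxin_ids))
  if (n_og < 1) stop_fmt("need at least one toxin id to build orthogroups")
  og_ids <- sprintf("OG%07d", seq_len(n_og))
  true_clade <- sample(labels, n_og, replace = TRUE,
                       prob = config$clade_sharing_probs)
  if (is.null(toxin_ids))
    toxin_ids <- sprintf("tox%04d", seq_len(ceiling(1.6 * n_og)))
  toxin_ids <- sample(toxin_ids)  # shuffle before distributing
  assigned <- toxin_ids[seq_len(min(n_og, length(toxin_ids)))]
  leftover <- setdiff(toxin_ids, assigned)
  og_members_focal <- as.list(assigned)
  if (length(og_members_focal) < n_og)
    stop_fmt("need at least n_orthogroups toxin ids (%d < %d)",
             length(toxin_ids), n_og)
  extra_take <- stats::runif(length(leftover)) < 0.6
  for (tid in leftover[extra_take]) {
    g <- sample.int(n_og, 1)
    og_members_focal[[g]] <- c(og_members_focal[[g]], tid)
  }
  unassigned <- leftover[!extra_take]
  rows <- list()
  for (g in seq_len(n_og)) {
    lab <- true_clade[g]
    sp <- if (lab == "species_unique") config$focal_species
          else clades[[lab]]$leaves
    others <- setdiff(sp, config$focal_species)
    if (config$orthogroup_dropout > 0 && length(others) > 0)
      others <- others[stats::runif(length(others)) >= config$orthogroup_dropout]
    sp <- c(config$focal_species, others)
    members <- lapply(sp, function(s) {
      if (s == config$focal_species) sort(og_members_focal[[g]])
      else paste0(s, "|seq", sample.int(99999, sample(1:3, 1)))
    })
    block <- data.frame(orthogroup_id = og_ids[g], species_id = sp,
                        stringsAsFactors = FALSE)
    block$member_sequence_ids <- members
    rows[[g]] <- block
  }
  rows <- do.call(rbind, rows)
  truth <- data.frame(orthogroup_id = og_ids, true_clade = true_clade,
                      stringsAsFactors = FALSE)
  truth$toxin_members <- og_members_focal
  list(orthogroups = orthogroup_table(rows), tree = tree,
       truth = list(orthogroups = truth, unassigned_toxins = unassigned))
}

#' Derive the true toxin class of each candidate from generator truth
#'
#' Applies the classification rule to the *true* DE status and *true*
#' secretome presence, giving the labels that a perfect pipeline recovers.
#'
#' @param counts_truth `truth` from [simulate_counts()].
#' @param proteome_truth `truth` from [simulate_proteomes()].
#' @param toxin_proteins candidate protein ids (toxin-annotated).
#' @return data.frame `protein_id`, `gene_id`, `true_class`.
#' @export
true_classes <- function(counts_truth, proteome_truth, toxin_proteins) {
  summ <- proteome_truth$summary
  ix <- match(toxin_proteins, summ$protein_id)
  if (anyNA(ix)) stop_fmt("unknown toxin protein id(s)")
  de <- counts_truth$de_status[match(summ$gene_id[ix], counts_truth$gene_id)]
  de <- ifelse(de == "null", "not_de", de)
  cls <- vapply(seq_along(ix), function(i)
    classify_toxin(de[i], summ$in_mucus[ix[i]], summ$in_any_proboscis[ix[i]]),
    character(1))
  data.frame(protein_id = toxin_proteins, gene_id = summ$gene_id[ix],
             true_class = cls, stringsAsFactors = FALSE)
}

#' Simulate protein sequences and a matching MALDI peak list
#'
#' Random amino-acid sequences for the given proteins (lengths spanning the
#' 1-15 kDa linear-mode window), plus a peak list containing singly
#' protonated peaks for a subset of them (with small mass jitter) and pure
#' noise peaks.
#'
#' @param config a [sim_config()].
#' @param protein_ids proteins to sequence.
#' @param n_true_peaks number of proteins given a matching peak.
#' @param n_noise_peaks number of uniformly placed noise peaks.
#' @param jitter_da sd of Gaussian mass jitter on true peaks (default 0.3).
#' @return list with `sequences` (named character), `peaks` (a `PeakList`),
#'   `truth` (data.frame `protein_id`, `mz` of the planted peak).
#' @export
simulate_mass_data <- function(config, protein_ids, n_true_peaks = 5,
                               n_noise_peaks = 15, jitter_da = 0.3) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 4L)
  lens <- sample(10:120, length(protein_ids), replace = TRUE)
  seqs <- vapply(lens, function(l)
    paste(sample(AA_ALPHABET, l, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- protein_ids
  n_true <- min(n_true_peaks, length(protein_ids))
  chosen <- sample(protein_ids, n_true)
  true_mz <- vapply(seqs[chosen], average_mass, numeric(1)) + PROTON_AVERAGE +
    stats::rnorm(n_true, 0, jitter_da)
  noise_mz <- stats::runif(n_noise_peaks, 1000, 15000)
  peaks <- peak_list(data.frame(
    mz = c(true_mz, noise_mz),
    intensity = stats::runif(n_true + n_noise_peaks, 10, 1000)))
  peaks <- peaks[order(peaks$mz), ]
  rownames(peaks) <- NULL
  list(sequences = seqs, peaks = peak_list(peaks),
       truth = data.frame(protein_id = chosen, mz = unname(true_mz),
                          stringsAsFactors = FALSE))
}

#' Simulate the complete coupled study
#'
#' Runs all generators in order under one config and returns every input the
#' pipeline consumes together with all ground-truth labels.
#'
#' @param config a [sim_config()].
#' @return list of class `SyntheticStudy` with elements `counts`, `evidence`,
#'   `annotations`, `go`, `orthogroups`, `tree`, `sequences`, `peaks`,
#'   `truth` (gene, presence, class, orthogroup and peak truth), and
#'   `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  cs <- simulate_counts(config)
  ps <- simulate_proteomes(config, cs)
  an <- simulate_annotations(config, cs)
  tox_prot <- an$truth$toxin_proteins
  cls <- true_classes(cs$truth, ps$truth, tox_prot)
  og <- simulate_orthogroups(config, toxin_ids = tox_prot)
  ms <- simulate_mass_data(config, tox_prot)
  structure(list(
    counts = cs$counts, evidence = ps$evidence,
    annotations = an$annotations, go = an$go,
    orthogroups = og$orthogroups, tree = og$tree,
    sequences = ms$sequences, peaks = ms$peaks,
    truth = list(genes = cs$truth, presence = ps$truth,
                 classes = cls, enriched_term = an$truth$enriched_term,
                 orthogroups = og$truth, peaks = ms$truth),
    config = config), class = "SyntheticStudy")
}

#' Write a synthetic study as a pipeline fixture directory
#'
#' Emits every file the pipeline reads (counts, metadata, peptide evidence,
#' annotations, GO table, Orthogroups.tsv, Newick tree, FASTA, peaks CSV, a
#' toxin-id list) plus `truth.json` with the ground-truth labels.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_fixture <- function(study, dir) {
  stopifnot(inherits(study, "SyntheticStudy"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_count_matrix(study$counts, p("counts.tsv"), p("samples.tsv"))
  write_peptide_evidence(study$evidence, p("peptides.tsv"), p("proteome_samples.tsv"))
  write_annotations(study$annotations, p("annotations.tsv"))
  write_tsv(study$go, p("go_terms.tsv"))
  write_orthogroups(study$orthogroups, p("orthogroups.tsv"),
                    species = study$tree$tip.label)
  write_newick(study$tree, p("species_tree.nwk"))
  write_fasta(study$sequences, p("candidates.fasta"))
  write_peaks(study$peaks, p("peaks.csv"))
  writeLines(study$truth$classes$protein_id, p("toxin_ids.txt"))
  truth <- list(
    genes = study$truth$genes,
    classes = study$truth$classes,
    enriched_term = study$truth$enriched_term,
    orthogroup_clades = study$truth$orthogroups$orthogroups[
      , c("orthogroup_id", "true_clade")],
    seed = study$config$seed)
  jsonlite::write_json(truth, p("truth.json"), dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  files <- c(counts = p("counts.tsv"), samples = p("samples.tsv"),
             peptides = p("peptides.tsv"),
             proteome_samples = p("proteome_samples.tsv"),
             annotations = p("annotations.tsv"), go = p("go_terms.tsv"),
             orthogroups = p("orthogroups.tsv"), tree = p("species_tree.nwk"),
             fasta = p("candidates.fasta"), peaks = p("peaks.csv"),
             toxin_ids = p("toxin_ids.txt"), truth = p("truth.json"))
  invisible(files)
}
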