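#' Write a secretome presence/absence matrix to TSV
#' @param presence a `PresenceMatrix`.
#' @param path output TSV (protein_id column + one logical column per sample).
#' @export
write_presence <- function(presence, path) {
  stopifnot(inherits(presence, "PresenceMatrix"))
  tab <- data.frame(protein_id = rownames(presence$matrix),
                    presence$matrix, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv(tab, path)
}

#' Read a secretome presence/absence matrix from TSV
#' @param path presence TSV written by [write_presence()].
#' @param meta_path proteome-sample metadata TSV (for secretome classes).
#' @return a `PresenceMatrix`.
#' @export
read_presence <- function(path, meta_path) {
  tab <- read_tsv_strict(path)
  meta <- read_tsv_strict(meta_path)
  mat <- as.matrix(tab[, -1, drop = FALSE]) == "TRUE" |
    as.matrix(tab[, -1, drop = FALSE]) == TRUE
  rownames(mat) <- tab$protein_id
  meta <- meta[match(colnames(mat), meta$proteome_sample_id), , drop = FALSE]
  if (anyNA(meta$proteome_sample_id))
    stop_fmt("presence matrix references samples missing from metadata")
  cls <- meta$secretome_class
  summ <- data.frame(
    protein_id = rownames(mat),
    in_mucus = rowSums(mat[, cls == "mucus", drop = FALSE]) > 0,
    in_any_proboscis = rowSums(mat[, cls == "proboscis", drop = FALSE]) > 0,
    in_whole_animal = rowSums(mat[, cls == "whole_animal", drop = FALSE]) > 0,
    n_proteomes_present = rowSums(mat),
    stringsAsFactors = FALSE)
  structure(list(matrix = mat, sample_meta = meta, summary = summ),
            class = "PresenceMatrix")
}

#' Assemble and validate a pipeline run configuration
#'
#' @param inputs named list/vector of input paths: `counts`, `samples`,
#'   `peptides`, `proteome_samples`, `annotations`, `go`, `orthogroups`,
#'   `tree`, `fasta`, `peaks`, and optionally `toxin_ids`.
#' @param out_dir output directory.
#' @param dge a [dge_config()].
#' @param evalue_cutoff candidate-selection e-value cutoff (default 1e-5).
#' @param mass_tolerance_da peak-match tolerance in Da (default 2).
#' @param monoisotopic use monoisotopic masses in mass matching.
#' @param focal_species focal species id.
#' @param seed integer seed recorded in the summary.
#' @param skip character vector of stage names to skip (subset of
#'   `c("dge","proteome","classify","lineage","enrich","massmatch")`).
#' @return list of class `RunConfig`.
#' @export
run_config <- function(inputs, out_dir, dge = dge_config(),
                       evalue_cutoff = 1e-5, mass_tolerance_da = 2,
                       monoisotopic = FALSE,
                       focal_species = "Antarctonemertes_valida",
                       seed = 1L, skip = character(0)) {
  inputs <- as.list(inputs)
  need <- c("counts", "samples", "peptides", "proteome_samples",
            "annotations", "go", "orthogroups", "tree", "fasta", "peaks")
  missing_keys <- setdiff(need, names(inputs))
  if (length(missing_keys) > 0)
    stop_fmt("run config missing input path(s): %s",
             paste(missing_keys, collapse = ", "))
  absent <- unlist(inputs[need])[!file.exists(unlist(inputs[need]))]
  if (length(absent) > 0)
    stop_fmt("input file(s) do not exist: %s", paste(absent, collapse = ", "))
  stages <- c("dge", "proteome", "classify", "lineage", "enrich", "massmatch")
  bad <- setdiff(skip, stages)
  if (length(bad) > 0) stop_fmt("unknown stage(s) in skip: %s", paste(bad, collapse = ", "))
  structure(list(inputs = inputs, out_dir = out_dir, dge = dge,
                 evalue_cutoff = evalue_cutoff,
                 mass_tolerance_da = mass_tolerance_da,
                 monoisotopic = monoisotopic, focal_species = focal_species,
                 seed = as.integer(seed), skip = skip),
            class = "RunConfig")
}

#' Load a pipeline run configuration from a YAML file
#'
#' The YAML mirrors [run_config()]: an `inputs` mapping, `out_dir`, and
#' optional `dge` (alpha, min_lfc, trim_m, trim_a, dispersion),
#' `evalue_cutoff`, `mass_tolerance_da`, `monoisotopic`, `focal_species`,
#' `seed`, `skip`. Relative input paths are resolved against the YAML file's
#' directory. `overrides` (e.g. from CLI flags) replace file values.
#'
#' @param path YAML config file.
#' @param overrides named list of top-level overrides.
#' @return a `RunConfig`.
#' @export
read_run_config <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  y[names(overrides)] <- overrides
  base <- dirname(normalizePath(path))
  inputs <- lapply(y$inputs, function(p)
    if (startsWith(p, "/")) p else file.path(base, p))
  dge_args <- if (is.null(y$dge)) list() else y$dge
  run_config(inputs = inputs,
             out_dir = if (is.null(y$out_dir)) "." else y$out_dir,
             dge = do.call(dge_config, dge_args),
             evalue_cutoff = if (is.null(y$evalue_cutoff)) 1e-5 else y$evalue_cutoff,
             mass_tolerance_da = if (is.null(y$mass_tolerance_da)) 2 else y$mass_tolerance_da,
             monoisotopic = isTRUE(y$monoisotopic),
             focal_species = if (is.null(y$focal_species))
               "Antarctonemertes_valida" else y$focal_species,
             seed = if (is.null(y$seed)) 1L else y$seed,
             skip = if (is.null(y$skip)) character(0) else unlist(y$skip))
}

log_msg <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), sprintf(...))
}

#' Run the full toxin-triage pipeline
#'
#' Executes dge, proteome, classify, lineage, enrich and massmatch in
#' dependency order, writing each stage's outputs before the next starts,
#' and returns (and writes) a machine-readable run summary. A stage failure
#' aborts the run with the stage name; a `<stage>.failed` marker is left in
#' the output directory and earlier outputs are retained. Skipped stages are
#' omitted from the summary; classification then falls back to whatever
#' evidence is available only if its prerequisites (dge, proteome) ran.
#'
#' @param config a [run_config()] or path to a YAML file.
#' @return the run summary (list), invisibly; written to
#'   `<out_dir>/summary.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  stage <- function(name, fun) {
    if (name %in% config$skip) {
      log_msg("stage %s: skipped", name)
      return(NULL)
    }
    log_msg("stage %s: start", name)
    res <- tryCatch(fun(), error = function(e) {
      writeLines(conditionMessage(e), out(paste0(name, ".failed")))
      stop_fmt("stage '%s' failed: %s", name, conditionMessage(e))
    })
    log_msg("stage %s: done", name)
    res
  }
  summary <- list(seed = config$seed,
                  params = list(alpha = config$dge$alpha,
                                min_lfc = config$dge$min_lfc,
                                evalue_cutoff = config$evalue_cutoff,
                                mass_tolerance_da = config$mass_tolerance_da,
                                focal_species = config$focal_species),
                  tool_version = as.character(utils::packageVersion("nemtox")),
                  stages = list())

  counts <- read_count_matrix(config$inputs$counts, config$inputs$samples)

  dge <- stage("dge", function() {
    res <- run_dge(counts, config$dge)
    write_tsv(res, out("dge.tsv"))
    res
  })
  if (!is.null(dge)) {
    tab <- table(factor(dge$call, levels = c(DE_CALLS[1:3], "untested")))
    summary$stages$dge <- list(
      n_genes = nrow(dge), n_tested = sum(dge$call != "untested"),
      n_up_proboscis = as.integer(tab[["up_proboscis"]]),
      n_up_body = as.integer(tab[["up_body"]]),
      dispersion = attr(dge, "dispersion"))
  }

  presence <- stage("proteome", function() {
    ev <- read_peptide_evidence(config$inputs$peptides,
                                config$inputs$proteome_samples)
    pm <- build_presence_matrix(ev)
    write_presence(pm, out("presence.tsv"))
    pm
  })
  if (!is.null(presence))
    summary$stages$proteome <- list(
      n_proteins = nrow(presence$matrix),
      n_samples = ncol(presence$matrix),
      n_detected = length(candidate_universe(presence)))

  triage <- NULL
  if (!("classify" %in% config$skip)) {
    if (is.null(dge) || is.null(presence))
      stop_fmt("classify requires the dge and proteome stages")
    triage <- stage("classify", function() {
      ann <- read_annotations(config$inputs$annotations)
      sel <- select_candidates(candidate_universe(presence), ann,
                               config$evalue_cutoff)
      tr <- classify_all(sel, dge, presence)
      write_results(tr$records, out("toxin_records.tsv"),
                    params = summary$params, seed = config$seed,
                    summary_path = out("toxin_records.summary.json"))
      tr
    })
    summary$stages$classify <- list(
      n_candidates = nrow(triage$records),
      class_counts = as.list(triage$class_counts))
  }

  if (!("lineage" %in% config$skip)) {
    prof <- stage("lineage", function() {
      ogs <- read_orthogroups(config$inputs$orthogroups)
      tree <- read_newick(config$inputs$tree)
      tox_ids <- if (!is.null(config$inputs$toxin_ids))
        readLines(config$inputs$toxin_ids)
      else if (!is.null(triage)) triage$records$protein_id
      else stop_fmt("no toxin id source: provide inputs$toxin_ids or run classify")
      pr <- profile_orthogroups(ogs, tox_ids, tree, config$focal_species)
      write_tsv(pr$assignments, out("clade_assignments.tsv"))
      write_tsv(data.frame(orthogroup_id = rownames(pr$presence), pr$presence,
                           check.names = FALSE, stringsAsFactors = FALSE),
                out("orthogroup_presence.tsv"))
      jsonlite::write_json(as.list(pr$clade_counts), out("clade_counts.json"),
                           auto_unbox = TRUE, digits = NA)
      pr
    })
    summary$stages$lineage <- list(
      n_orthogroups = nrow(prof$assignments),
      clade_counts = as.list(prof$clade_counts),
      toxin_summary = as.list(prof$toxin_summary))
  }

  if (!("enrich" %in% config$skip)) {
    if (is.null(dge)) stop_fmt("enrich requires the dge stage")
    enr <- stage("enrich", function() {
      go <- read_tsv_strict(config$inputs$go)
      target <- dge$gene_id[dge$call == "up_proboscis"]
      backgr <- dge$gene_id[!(dge$gene_id %in% target)]
      if (length(target) == 0) return(NULL)
      res <- enrich_terms(target, backgr, go)
      write_tsv(res, out("enrichment.tsv"))
      res
    })
    summary$stages$enrich <- if (is.null(enr)) {
      list(n_terms = 0L, n_significant = 0L)
    } else {
      list(n_terms = nrow(enr), n_significant = sum(enr$fdr < 0.05),
           top_term = if (nrow(enr) > 0) enr$term[1] else NA)
    }
  }

  if (!("massmatch" %in% config$skip)) {
    mm <- stage("massmatch", function() {
      seqs <- read_fasta(config$inputs$fasta)
      peaks <- read_peaks(config$inputs$peaks)
      res <- match_peaks(seqs, peaks, config$mass_tolerance_da,
                         config$monoisotopic)
      write_tsv(res, out("mass_matches.tsv"))
      res
    })
    summary$stages$massmatch <- list(
      n_candidates = length(read_fasta(config$inputs$fasta)),
      n_matches = nrow(mm))
  }

  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(summary)
}

# ---- command-line dispatcher ----------------------------------------------

cli_opts <- function(argv) {
  opts <- list()
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop_fmt("unexpected argument '%s'", a)
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(argv) || startsWith(argv[i + 1], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1
    } else {
      opts[[key]] <- argv[i + 1]
      i <- i + 2
    }
  }
  opts
}

opt_or <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else opts[[key]]
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `dge`, `enrich`, `proteome`,
#' `classify`, `lineage`, `massmatch` and `run`. Intended to be called from
#' the thin wrapper script shipped in `inst/scripts/nemtox.R`; exposed as a
#' function so the interface is testable in-process.
#'
#' @param argv character vector of command-line arguments (subcommand first).
#' @return invisibly, the subcommand's main result.
#' @export
nemtox_main <- function(argv) {
  if (length(argv) == 0)
    stop_fmt(paste("usage: nemtox <simulate|dge|enrich|proteome|classify|",
                   "lineage|massmatch|run> [--flag value ...]", sep = ""))
  cmd <- argv[1]
  opts <- cli_opts(argv[-1])
  res <- switch(cmd,
    simulate = {
      cfg <- sim_config(
        n_genes = as.integer(opt_or(opts, "n_genes", 2000)),
        phi = as.numeric(opt_or(opts, "phi", 0.1)),
        fraction_de = as.numeric(opt_or(opts, "fraction_de", 0.1)),
        seed = as.integer(opt_or(opts, "seed", 1)))
      write_fixture(simulate_study(cfg), opt_or(opts, "out", "fixture"))
    },
    dge = {
      counts <- read_count_matrix(opts$counts, opts$samples)
      disp <- opt_or(opts, "dispersion", "auto")
      cfg <- dge_config(
        alpha = as.numeric(opt_or(opts, "alpha", 0.001)),
        min_lfc = as.numeric(opt_or(opts, "min_lfc", 2)),
        dispersion = if (identical(disp, "auto")) "estimate_common"
                     else as.numeric(disp))
      res <- run_dge(counts, cfg)
      write_tsv(res, opt_or(opts, "out", "dge.tsv"))
      res
    },
    enrich = {
      dge <- read_tsv_strict(opts$dge)
      go <- read_tsv_strict(opts$go)
      target <- dge$gene_id[dge$call == "up_proboscis"]
      res <- enrich_terms(target, setdiff(dge$gene_id, target), go)
      write_tsv(res, opt_or(opts, "out", "enrichment.tsv"))
      res
    },
    proteome = {
      ev <- read_peptide_evidence(opts$peptides, opts$proteome_samples)
      pm <- build_presence_matrix(ev)
      write_presence(pm, opt_or(opts, "out", "presence.tsv"))
      pm
    },
    classify = {
      dge <- read_tsv_strict(opts$dge)
      class(dge) <- c("DGEResult", "data.frame")
      pm <- read_presence(opts$presence, opts$proteome_samples)
      ann <- read_annotations(opts$annotations)
      sel <- select_candidates(candidate_universe(pm), ann,
                               as.numeric(opt_or(opts, "evalue_cutoff", 1e-5)))
      tr <- classify_all(sel, dge, pm)
      write_results(tr$records, opt_or(opts, "out", "toxin_records.tsv"))
      tr
    },
    lineage = {
      pr <- profile_orthogroups(
        read_orthogroups(opts$orthogroups),
        readLines(opts$toxin_ids),
        read_newick(opts$tree),
        opt_or(opts, "focal_species", "Antarctonemertes_valida"))
      write_tsv(pr$assignments, opt_or(opts, "out", "clade_assignments.tsv"))
      pr
    },
    massmatch = {
      res <- match_peaks(read_fasta(opts$fasta), read_peaks(opts$peaks),
                         as.numeric(opt_or(opts, "tolerance_da", 2)),
                         isTRUE(opts$monoisotopic))
      write_tsv(res, opt_or(opts, "out", "mass_matches.tsv"))
      res
    },
    run = {
      overrides <- list()
      if (!is.null(opts$seed)) overrides$seed <- as.integer(opts$seed)
      if (!is.null(opts$out)) overrides$out_dir <- opts$out
      if (!is.null(opts$skip)) overrides$skip <- strsplit(opts$skip, ",")[[1]]
      run_pipeline(read_run_config(opts$config, overrides))
    },
    stop_fmt("unknown subcommand '%s'", cmd))
  invisible(res)
}
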