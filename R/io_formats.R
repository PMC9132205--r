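#' @importFrom utils read.delim write.table read.csv
NULL

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

TISSUES <- c("proboscis", "body")
SECRETOME_CLASSES <- c("whole_animal", "mucus", "proboscis")
TOXIN_CLASSES <- c("predatory", "defensive", "dual", "unclassified")
DE_CALLS <- c("up_proboscis", "up_body", "not_de", "untested")

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, quote = "", comment.char = "")
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

# ---- CountMatrix -----------------------------------------------------------

#' Construct a validated gene-by-sample count matrix
#'
#' The central transcriptomic container: raw RNA-seq read counts for genes
#' (rows) across libraries (columns), with per-sample metadata recording which
#' individual and which tissue (proboscis or body) each library comes from.
#' The design this models is a paired-tissue comparison: replicate proboscis
#' and body libraries from the same set of individuals.
#'
#' @param counts integer matrix, genes x samples, with unique dimnames.
#' @param meta data.frame with columns `sample_id`, `individual_id`, `tissue`;
#'   one row per column of `counts`; `tissue` must be `"proboscis"` or
#'   `"body"`, with at least one sample of each.
#' @return an object of class `CountMatrix` (list with `genes`, `samples`,
#'   `counts`, `meta`).
#' @export
count_matrix <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_fmt("count matrix must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop_fmt("duplicate gene ids: %s",
             paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop_fmt("duplicate sample ids: %s",
             paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_fmt("counts must be non-negative integers; offending cell gene '%s', sample '%s' (value %s)",
             rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
             format(counts[bad[1, 1], bad[1, 2]]))
  storage.mode(counts) <- "double"
  need <- c("sample_id", "individual_id", "tissue")
  if (!all(need %in% names(meta)))
    stop_fmt("metadata error: metadata must have columns %s", paste(need, collapse = ", "))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  missing <- setdiff(colnames(counts), meta$sample_id)
  if (length(missing) > 0)
    stop_fmt("metadata error: samples in counts missing from metadata: %s",
             paste(missing, collapse = ", "))
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (any(is.na(meta$tissue)) || !all(meta$tissue %in% TISSUES))
    stop_fmt("metadata error: tissue must be one of {%s} for every sample",
             paste(TISSUES, collapse = ", "))
  if (!all(TISSUES %in% meta$tissue))
    stop_fmt("metadata error: need at least one sample per tissue")
  structure(list(genes = rownames(counts), samples = colnames(counts),
                 counts = counts, meta = meta),
            class = "CountMatrix")
}

#' Read a count matrix and its sample metadata from TSV files
#'
#' @param path counts TSV: header row of sample ids, first column gene ids.
#' @param meta_path metadata TSV with columns `sample_id`, `individual_id`,
#'   `tissue`.
#' @return a [count_matrix()] object with file row/column order preserved.
#' @export
read_count_matrix <- function(path, meta_path) {
  tab <- read_tsv_strict(path)
  if (ncol(tab) < 2) stop_fmt("counts TSV needs a gene-id column plus >=1 sample column: %s", path)
  genes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop_fmt("format error: non-numeric count at gene '%s', sample '%s'",
             genes[bad[1]], colnames(m)[bad[2]])
  }
  nonint <- which(m != round(m) | m < 0, arr.ind = TRUE)
  if (nrow(nonint) > 0)
    stop_fmt("format error: count must be a non-negative integer at gene '%s', sample '%s' (value %s)",
             genes[nonint[1, 1]], colnames(m)[nonint[1, 2]],
             format(m[nonint[1, 1], nonint[1, 2]]))
  rownames(m) <- genes
  meta <- read_tsv_strict(meta_path)
  count_matrix(m, meta)
}

#' Write a count matrix (and optionally its metadata) to TSV
#' @param x a `CountMatrix`.
#' @param path counts TSV path.
#' @param meta_path optional metadata TSV path.
#' @export
write_count_matrix <- function(x, path, meta_path = NULL) {
  stopifnot(inherits(x, "CountMatrix"))
  tab <- data.frame(gene_id = x$genes, x$counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv(tab, path)
  if (!is.null(meta_path)) write_tsv(x$meta, meta_path)
  invisible(path)
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d samples (%d proboscis, %d body)\n",
              length(x$genes), length(x$samples),
              sum(x$meta$tissue == "proboscis"), sum(x$meta$tissue == "body")))
  invisible(x)
}

# ---- PeptideEvidenceTable --------------------------------------------------

#' Construct a validated peptide-evidence table
#'
#' Rows are peptide-to-protein identifications from upstream spectral search
#' (one row per peptide observation) with a q-value; sample metadata assigns
#' each proteome sample a secretome class (whole animal, defensive mucus, or
#' proboscis) and the identification q-value threshold used for that sample.
#'
#' @param rows data.frame with columns `proteome_sample_id`, `protein_id`,
#'   `peptide_sequence` (uppercase 20-letter amino-acid strings), `qvalue`.
#' @param sample_meta data.frame with columns `proteome_sample_id`,
#'   `secretome_class`, `qvalue_threshold`.
#' @return an object of class `PeptideEvidenceTable`.
#' @export
peptide_evidence <- function(rows, sample_meta) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  need <- c("proteome_sample_id", "protein_id", "peptide_sequence", "qvalue")
  if (!all(need %in% names(rows)))
    stop_fmt("evidence table must have columns %s", paste(need, collapse = ", "))
  needm <- c("proteome_sample_id", "secretome_class", "qvalue_threshold")
  if (!all(needm %in% names(sample_meta)))
    stop_fmt("evidence sample metadata must have columns %s", paste(needm, collapse = ", "))
  if (nrow(rows) > 0) {
    ok <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", rows$peptide_sequence)
    if (!all(ok))
      stop_fmt("invalid peptide sequence '%s' (row %d): must match ^[ACDEFGHIKLMNPQRSTVWY]+$",
               rows$peptide_sequence[which(!ok)[1]], which(!ok)[1])
    if (any(rows$qvalue < 0 | rows$qvalue > 1 | is.na(rows$qvalue)))
      stop_fmt("qvalue must lie in [0,1]")
    unknown <- setdiff(rows$proteome_sample_id, sample_meta$proteome_sample_id)
    if (length(unknown) > 0)
      stop_fmt("proteome sample(s) missing from sample metadata: %s",
               paste(unknown, collapse = ", "))
  }
  if (!all(sample_meta$secretome_class %in% SECRETOME_CLASSES))
    stop_fmt("secretome_class must be one of {%s}", paste(SECRETOME_CLASSES, collapse = ", "))
  if (any(is.na(sample_meta$qvalue_threshold) | sample_meta$qvalue_threshold <= 0 |
            sample_meta$qvalue_threshold >= 1))
    stop_fmt("every proteome sample needs a qvalue_threshold in (0,1)")
  structure(list(rows = rows, sample_meta = sample_meta),
            class = "PeptideEvidenceTable")
}

#' Read a peptide-evidence table from TSV files
#' @param path evidence TSV.
#' @param meta_path proteome-sample metadata TSV.
#' @return a [peptide_evidence()] object.
#' @export
read_peptide_evidence <- function(path, meta_path) {
  peptide_evidence(read_tsv_strict(path), read_tsv_strict(meta_path))
}

#' Write a peptide-evidence table to TSV
#' @param x a `PeptideEvidenceTable`.
#' @param path evidence TSV path.
#' @param meta_path metadata TSV path.
#' @export
write_peptide_evidence <- function(x, path, meta_path) {
  stopifnot(inherits(x, "PeptideEvidenceTable"))
  write_tsv(x$rows, path)
  write_tsv(x$sample_meta, meta_path)
  invisible(path)
}

# ---- AnnotationTable -------------------------------------------------------

#' Construct a validated toxin-annotation table
#'
#' Homology/domain evidence per predicted protein: best-hit subject, e-value,
#' a free-text toxin family from sequence similarity searches and a free-text
#' domain label from domain scanning (either may be empty). A `gene_id`
#' column maps protein ids to the gene space of the count matrix; when absent
#' the protein id is used as the gene id.
#'
#' @param rows data.frame with columns `protein_id`, `subject_id`, `evalue`,
#'   `toxin_family`, `domain_label` and optionally `gene_id`.
#' @return an object of class `AnnotationTable` (a data.frame).
#' @export
annotation_table <- function(rows) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  need <- c("protein_id", "subject_id", "evalue", "toxin_family", "domain_label")
  if (!all(need %in% names(rows)))
    stop_fmt("annotation table must have columns %s", paste(need, collapse = ", "))
  if (!("gene_id" %in% names(rows))) rows$gene_id <- rows$protein_id
  if (nrow(rows) > 0) {
    if (any(is.na(rows$evalue) | rows$evalue < 0))
      stop_fmt("evalue must be >= 0")
    key <- paste(rows$protein_id, rows$subject_id, sep = "\r")
    if (anyDuplicated(key))
      stop_fmt("duplicate (protein_id, subject_id) pair: %s",
               sub("\r", " / ", key[duplicated(key)][1]))
    rows$toxin_family[is.na(rows$toxin_family)] <- ""
    rows$domain_label[is.na(rows$domain_label)] <- ""
  }
  class(rows) <- c("AnnotationTable", "data.frame")
  rows
}

#' Read an annotation table from TSV
#' @param path annotation TSV.
#' @return an [annotation_table()].
#' @export
read_annotations <- function(path) {
  tab <- read_tsv_strict(path)
  for (col in c("toxin_family", "domain_label"))
    if (col %in% names(tab)) tab[[col]] <- ifelse(is.na(tab[[col]]), "", as.character(tab[[col]]))
  annotation_table(tab)
}

#' Write an annotation table to TSV
#' @param x an `AnnotationTable`.
#' @param path output path.
#' @export
write_annotations <- function(x, path) {
  write_tsv(as.data.frame(unclass(x), stringsAsFactors = FALSE), path)
}

# ---- OrthogroupTable -------------------------------------------------------

#' Construct a validated orthogroup table
#'
#' Long-format orthology assignments: one row per (orthogroup, species) with
#' the set of member sequence ids that species contributes. Orthogroups must
#' partition sequences within a species.
#'
#' @param rows data.frame with columns `orthogroup_id`, `species_id`,
#'   `member_sequence_ids` (a list-column of character vectors).
#' @return an object of class `OrthogroupTable`.
#' @export
orthogroup_table <- function(rows) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  need <- c("orthogroup_id", "species_id", "member_sequence_ids")
  if (!all(need %in% names(rows)))
    stop_fmt("orthogroup table must have columns %s", paste(need, collapse = ", "))
  if (!is.list(rows$member_sequence_ids))
    rows$member_sequence_ids <- strsplit(as.character(rows$member_sequence_ids), ",[ ]?")
  if (nrow(rows) > 0) {
    key <- paste(rows$orthogroup_id, rows$species_id, sep = "\r")
    if (anyDuplicated(key))
      stop_fmt("duplicate (orthogroup_id, species_id) pair: %s",
               sub("\r", " / ", key[duplicated(key)][1]))
    if (any(lengths(rows$member_sequence_ids) == 0))
      stop_fmt("member sequence sets must be non-empty")
  }
  class(rows) <- c("OrthogroupTable", "data.frame")
  rows
}

#' Read an OrthoFinder-style Orthogroups.tsv file
#'
#' First column `Orthogroup`; one column per species; cells hold
#' comma-space-separated sequence ids or are empty. Empty cells produce no
#' row in the long-format result.
#'
#' @param path Orthogroups.tsv path.
#' @return an [orthogroup_table()].
#' @export
read_orthogroups <- function(path) {
  tab <- read_tsv_strict(path)
  if (names(tab)[1] != "Orthogroup")
    stop_fmt("format error: first column of %s must be 'Orthogroup', got '%s'",
             path, names(tab)[1])
  if (anyDuplicated(tab$Orthogroup))
    stop_fmt("format error: duplicate orthogroup id '%s'",
             tab$Orthogroup[duplicated(tab$Orthogroup)][1])
  species <- names(tab)[-1]
  out <- list()
  for (sp in species) {
    cells <- as.character(tab[[sp]])
    cells[is.na(cells)] <- ""
    nonempty <- which(nzchar(trimws(cells)))
    if (length(nonempty) == 0) next
    out[[sp]] <- data.frame(
      orthogroup_id = tab$Orthogroup[nonempty],
      species_id = sp,
      stringsAsFactors = FALSE)
    out[[sp]]$member_sequence_ids <- strsplit(trimws(cells[nonempty]), ",[ ]?")
  }
  if (length(out) == 0) {
    empty <- data.frame(orthogroup_id = character(), species_id = character(),
                        stringsAsFactors = FALSE)
    empty$member_sequence_ids <- list()
    return(orthogroup_table(empty))
  }
  rows <- do.call(rbind, out)
  rows <- rows[order(match(rows$orthogroup_id, tab$Orthogroup),
                     match(rows$species_id, species)), ]
  rownames(rows) <- NULL
  orthogroup_table(rows)
}

#' Write an orthogroup table in OrthoFinder Orthogroups.tsv dialect
#' @param x an `OrthogroupTable`.
#' @param path output path.
#' @param species optional explicit column order (species ids).
#' @export
write_orthogroups <- function(x, path, species = NULL) {
  stopifnot(inherits(x, "OrthogroupTable"))
  if (is.null(species)) species <- unique(x$species_id)
  ogs <- unique(x$orthogroup_id)
  wide <- matrix("", nrow = length(ogs), ncol = length(species),
                 dimnames = list(ogs, species))
  for (i in seq_len(nrow(x)))
    wide[x$orthogroup_id[i], x$species_id[i]] <-
      paste(x$member_sequence_ids[[i]], collapse = ", ")
  tab <- data.frame(Orthogroup = ogs, wide, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv(tab, path)
}

# ---- SpeciesTree -----------------------------------------------------------

#' Read a species tree from a Newick file
#'
#' Internal node labels name clades (e.g. Hoplonemertea); leaves are species
#' ids. Validates uniqueness of leaf labels and of named internal nodes.
#'
#' @param path Newick file.
#' @return an [ape::read.tree()] `phylo` object, validated.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop_fmt("could not parse Newick file: %s", path)
  validate_species_tree(tree)
}

#' Validate a `phylo` object as a species tree
#' @param tree a `phylo` object.
#' @return the tree, invisibly validated.
#' @export
validate_species_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stop_fmt("duplicate leaf label(s): %s",
             paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  nl <- tree$node.label
  if (!is.null(nl)) {
    named <- nl[nzchar(nl)]
    if (anyDuplicated(named))
      stop_fmt("duplicate internal clade name(s): %s",
               paste(unique(named[duplicated(named)]), collapse = ", "))
  }
  tree
}

#' Write a species tree to Newick
#' @param tree a `phylo` object.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# ---- PeakList --------------------------------------------------------------

#' Read a MALDI peak list from CSV
#'
#' Columns `mz` (strictly positive) and `intensity` (non-negative); the list
#' may be empty. Linear-mode MALDI acquisitions in the 1-15 kDa range yield
#' such centroided peak lists.
#'
#' @param path CSV with columns `mz`, `intensity`.
#' @return data.frame of class `PeakList`.
#' @export
read_peaks <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  peak_list(tab)
}

#' Construct a validated peak list
#' @param tab data.frame with columns `mz` and `intensity`.
#' @return data.frame of class `PeakList`.
#' @export
peak_list <- function(tab) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  if (!all(c("mz", "intensity") %in% names(tab)))
    stop_fmt("peak list must have columns mz, intensity")
  if (nrow(tab) > 0) {
    if (any(is.na(tab$mz) | tab$mz <= 0))
      stop_fmt("mz must be strictly positive")
    if (any(is.na(tab$intensity) | tab$intensity < 0))
      stop_fmt("intensity must be >= 0")
  }
  class(tab) <- c("PeakList", "data.frame")
  tab
}

#' Write a peak list to CSV
#' @param x a `PeakList`.
#' @param path output path.
#' @export
write_peaks <- function(x, path) {
  utils::write.csv(as.data.frame(unclass(x)), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- FASTA -----------------------------------------------------------------

#' Read protein sequences from a FASTA file
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop_fmt("no FASTA records in %s", path)
  idx <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  out <- character(length(ids))
  names(out) <- ids
  out[as.integer(names(seqs))] <- unname(seqs)
  names(out) <- ids
  out
}

#' Write protein sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

# ---- Results writer --------------------------------------------------------

#' Write toxin-record results as TSV plus a JSON run summary
#'
#' @param records data.frame of toxin records (one row per candidate with all
#'   evidence columns); may have zero rows.
#' @param path output TSV path; the JSON summary is written next to it as
#'   `<path>.summary.json` unless `summary_path` is given.
#' @param params named list of run parameters to record.
#' @param seed integer seed to record.
#' @param summary_path optional explicit JSON path.
#' @return invisibly, the summary list.
#' @export
write_results <- function(records, path, params = list(), seed = NA_integer_,
                          summary_path = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) == 0 && ncol(records) == 0)
    records <- data.frame(protein_id = character(), gene_id = character(),
                          toxin_family = character(), domain_label = character(),
                          evalue = numeric(), de_call = character(),
                          in_mucus = logical(), in_any_proboscis = logical(),
                          in_whole_animal = logical(),
                          assigned_class = character(), stringsAsFactors = FALSE)
  write_tsv(records, path)
  counts <- as.list(structure(integer(length(TOXIN_CLASSES)), names = TOXIN_CLASSES))
  if (nrow(records) > 0 && "assigned_class" %in% names(records)) {
    tab <- table(factor(records$assigned_class, levels = TOXIN_CLASSES))
    counts <- as.list(as.integer(tab))
    names(counts) <- TOXIN_CLASSES
  }
  summary <- list(n_candidates = nrow(records), class_counts = counts,
                  params = params, seed = seed)
  if (is.null(summary_path)) summary_path <- paste0(path, ".summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(summary)
}
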