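#' Select candidate toxins from the proteome-detected universe
#'
#' A protein is a candidate iff it carries toxin evidence — a non-empty toxin
#' family from homology search or a non-empty domain label — at e-value at or
#' below the cutoff, AND it was detected in at least one proteome sample.
#' Proteins failing either test are reported with the failing criterion.
#'
#' @param universe character vector of proteome-detected protein ids
#'   (from [candidate_universe()]).
#' @param annotations an [annotation_table()].
#' @param evalue_cutoff homology e-value cutoff (default 1e-5).
#' @return list with `candidates` (data.frame: `protein_id`, `gene_id`,
#'   `toxin_family`, `domain_label`, `evalue`) and `rejected` (data.frame:
#'   `protein_id`, `reason`).
#' @export
select_candidates <- function(universe, annotations, evalue_cutoff = 1e-5) {
  stopifnot(inherits(annotations, "AnnotationTable"))
  ann <- as.data.frame(unclass(annotations), stringsAsFactors = FALSE)
  has_tox <- nzchar(ann$toxin_family) | nzchar(ann$domain_label)
  ok <- ann[has_tox & ann$evalue <= evalue_cutoff, , drop = FALSE]
  # best (lowest e-value) toxin-evidence row per protein
  ok <- ok[order(ok$protein_id, ok$evalue), , drop = FALSE]
  ok <- ok[!duplicated(ok$protein_id), , drop = FALSE]
  cand <- ok[ok$protein_id %in% universe,
             c("protein_id", "gene_id", "toxin_family", "domain_label", "evalue"),
             drop = FALSE]
  cand <- cand[order(cand$protein_id), , drop = FALSE]
  rownames(cand) <- NULL

  annotated_ids <- unique(ann$protein_id[has_tox & ann$evalue <= evalue_cutoff])
  weak_ids <- setdiff(unique(ann$protein_id[has_tox]), annotated_ids)
  rej <- function(ids, reason)
    data.frame(protein_id = ids, reason = rep(reason, length(ids)),
               stringsAsFactors = FALSE)
  rejected <- rbind(
    rej(setdiff(annotated_ids, universe), "not_in_any_proteome"),
    rej(intersect(weak_ids, universe), "evalue_above_cutoff"),
    rej(setdiff(universe, unique(ann$protein_id[has_tox])),
        "no_toxin_annotation"))
  rownames(rejected) <- NULL
  list(candidates = cand, rejected = rejected)
}

#' Classify one candidate toxin from its evidence pattern
#'
#' The four-way rule integrating tissue expression bias with secretome
#' presence, with dual-function taking precedence:
#' \itemize{
#'   \item dual: present in both the defensive mucus and at least one
#'     proboscis proteome (regardless of expression bias);
#'   \item predatory: upregulated in the proboscis, present in at least one
#'     proboscis proteome, absent from the mucus;
#'   \item defensive: upregulated in the body, present in the mucus, absent
#'     from every proboscis proteome;
#'   \item unclassified: any other pattern.
#' }
#'
#' @param de_call one of `"up_proboscis"`, `"up_body"`, `"not_de"`,
#'   `"untested"` (`untested` is treated as `not_de`).
#' @param in_mucus logical.
#' @param in_any_proboscis logical.
#' @return one of `"predatory"`, `"defensive"`, `"dual"`, `"unclassified"`.
#' @export
classify_toxin <- function(de_call, in_mucus, in_any_proboscis) {
  if (!de_call %in% DE_CALLS)
    stop_fmt("unknown de_call '%s'", de_call)
  if (de_call == "untested") de_call <- "not_de"
  if (in_mucus && in_any_proboscis) return("dual")
  if (de_call == "up_proboscis" && in_any_proboscis && !in_mucus)
    return("predatory")
  if (de_call == "up_body" && in_mucus && !in_any_proboscis)
    return("defensive")
  "unclassified"
}

#' Classify every candidate toxin and summarize class counts
#'
#' Joins candidates to the DGE result (via `gene_id`) and to the secretome
#' presence summary (via `protein_id`), applies [classify_toxin()] to each,
#' and reports the per-class counts and the evidence-pattern histogram.
#' A candidate whose gene has no DGE row gets `de_call = "untested"` and is
#' never silently dropped.
#'
#' @param candidates candidate seed data.frame from [select_candidates()]
#'   (`$candidates`), or the list itself.
#' @param dge a `DGEResult`.
#' @param presence a `PresenceMatrix`.
#' @return list of class `ToxinTriage`: `records` (one row per candidate with
#'   all evidence fields and `assigned_class`), `class_counts` (named integer
#'   vector over predatory/defensive/dual/unclassified), and
#'   `pattern_histogram` (counts per de_call x mucus x proboscis pattern).
#' @export
classify_all <- function(candidates, dge, presence) {
  if (is.list(candidates) && !is.data.frame(candidates) &&
      "candidates" %in% names(candidates))
    candidates <- candidates$candidates
  stopifnot(inherits(presence, "PresenceMatrix"))
  cand <- as.data.frame(candidates, stringsAsFactors = FALSE)
  if (nrow(cand) == 0) {
    counts <- structure(integer(length(TOXIN_CLASSES)), names = TOXIN_CLASSES)
    rec <- data.frame(protein_id = character(), gene_id = character(),
                      toxin_family = character(), domain_label = character(),
                      evalue = numeric(), de_call = character(),
                      log2FC = numeric(), fdr = numeric(),
                      in_mucus = logical(), in_any_proboscis = logical(),
                      in_whole_animal = logical(),
                      assigned_class = character(), stringsAsFactors = FALSE)
    return(structure(list(records = rec, class_counts = counts,
                          pattern_histogram = data.frame()),
                     class = "ToxinTriage"))
  }
  dge_ix <- match(cand$gene_id, dge$gene_id)
  de_call <- ifelse(is.na(dge_ix), "untested", dge$call[dge_ix])
  summ <- presence$summary
  p_ix <- match(cand$protein_id, summ$protein_id)
  in_mucus <- !is.na(p_ix) & summ$in_mucus[p_ix]
  in_prob <- !is.na(p_ix) & summ$in_any_proboscis[p_ix]
  in_whole <- !is.na(p_ix) & summ$in_whole_animal[p_ix]
  assigned <- vapply(seq_len(nrow(cand)), function(i)
    classify_toxin(de_call[i], in_mucus[i], in_prob[i]), character(1))
  rec <- data.frame(protein_id = cand$protein_id, gene_id = cand$gene_id,
                    toxin_family = cand$toxin_family,
                    domain_label = cand$domain_label, evalue = cand$evalue,
                    de_call = de_call,
                    log2FC = ifelse(is.na(dge_ix), NA_real_, dge$log2FC[dge_ix]),
                    fdr = ifelse(is.na(dge_ix), NA_real_, dge$fdr[dge_ix]),
                    in_mucus = in_mucus, in_any_proboscis = in_prob,
                    in_whole_animal = in_whole,
                    assigned_class = assigned, stringsAsFactors = FALSE)
  rec <- rec[order(rec$protein_id), , drop = FALSE]
  rownames(rec) <- NULL
  counts <- table(factor(rec$assigned_class, levels = TOXIN_CLASSES))
  counts <- structure(as.integer(counts), names = TOXIN_CLASSES)
  hist <- as.data.frame(table(de_call = rec$de_call, in_mucus = rec$in_mucus,
                              in_any_proboscis = rec$in_any_proboscis),
                        stringsAsFactors = FALSE)
  hist <- hist[hist$Freq > 0, , drop = FALSE]
  rownames(hist) <- NULL
  structure(list(records = rec, class_counts = counts,
                 pattern_histogram = hist),
            class = "ToxinTriage")
}

#' @export
print.ToxinTriage <- function(x, ...) {
  cat(sprintf("ToxinTriage: %d candidates (%s)\n", nrow(x$records),
              paste(sprintf("%s=%d", names(x$class_counts), x$class_counts),
                    collapse = ", ")))
  invisible(x)
}
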