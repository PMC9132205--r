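# Leaf sets and root distance of every named internal node (root included if
# labelled). Unnamed nodes are not assignable: sets contained only in unnamed
# clades roll up to the nearest named ancestor automatically, because that
# ancestor is the smallest *named* containing clade.
named_clades <- function(tree) {
  validate_species_tree(tree)
  ntip <- length(tree$tip.label)
  labels <- tree$node.label
  if (is.null(labels)) labels <- rep("", tree$Nnode)
  # edges from root to each node
  depth <- integer(ntip + tree$Nnode)
  root <- ntip + 1L
  edge <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
  for (i in seq_len(nrow(tree$edge)))
    depth[tree$edge[i, 2]] <- depth[tree$edge[i, 1]] + 1L
  out <- list()
  for (nd in seq_len(tree$Nnode)) {
    lab <- labels[nd]
    if (is.na(lab) || !nzchar(lab)) next
    node <- ntip + nd
    tips <- tree$tip.label[unlist(phangorn_free_descendants(tree, node))]
    out[[lab]] <- list(label = lab, leaves = tips, n_leaves = length(tips),
                       depth = depth[node])
  }
  out
}

# Tip indices descending from `node` (plain traversal; no extra deps).
phangorn_free_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  tips <- kids[kids <= ntip]
  for (k in kids[kids > ntip])
    tips <- c(tips, phangorn_free_descendants(tree, k))
  tips
}

#' Assign the minimal named clade containing a set of species
#'
#' Returns the smallest named clade (fewest leaves, ties broken by closeness
#' to the root) whose leaf set contains every species in `species_present`.
#' A set consisting of the focal species alone is reported as
#' `species_unique`. When no named clade contains the set (an unlabelled
#' root), the label `"root"` is reported.
#'
#' @param species_present non-empty character vector of species ids, all of
#'   which must be leaves of `tree`.
#' @param tree a species tree (`phylo`) with named internal clades.
#' @param focal_species the study species id (default
#'   `"Antarctonemertes_valida"`).
#' @return list of class `CladeAssignment`: `species_present`,
#'   `assigned_label`, `n_species`.
#' @export
assign_clade <- function(species_present, tree,
                         focal_species = "Antarctonemertes_valida") {
  species_present <- unique(as.character(species_present))
  if (length(species_present) == 0)
    stop_fmt("species_present must be non-empty")
  missing <- setdiff(species_present, tree$tip.label)
  if (length(missing) > 0)
    stop_fmt("species not in tree: %s", paste(missing, collapse = ", "))
  if (length(species_present) == 1 && species_present == focal_species) {
    return(structure(list(species_present = species_present,
                          assigned_label = "species_unique",
                          n_species = 1L),
                     class = "CladeAssignment"))
  }
  clades <- named_clades(tree)
  containing <- Filter(function(cl) all(species_present %in% cl$leaves), clades)
  if (length(containing) == 0) {
    label <- "root"
  } else {
    sizes <- vapply(containing, `[[`, numeric(1), "n_leaves")
    depths <- vapply(containing, `[[`, numeric(1), "depth")
    ord <- order(sizes, depths)  # fewest leaves, then closest to root
    label <- containing[[ord[1]]]$label
  }
  structure(list(species_present = species_present, assigned_label = label,
                 n_species = length(species_present)),
            class = "CladeAssignment")
}

#' Phylogenetic profile of toxin-containing orthogroups
#'
#' Restricts the orthogroup table to orthogroups containing at least one
#' focal-species toxin sequence, maps each onto the species tree via
#' [assign_clade()], and reports per-clade sharing counts, a binary
#' orthogroup-by-species presence matrix, and a toxin-level summary. Toxin
#' sequences found in no multi-species orthogroup count as unique to the
#' focal species.
#'
#' @param orthogroups an [orthogroup_table()].
#' @param toxin_ids character vector of focal-species toxin sequence ids.
#' @param tree species tree with named clades.
#' @param focal_species focal species id.
#' @return list of class `LineageProfile`: `assignments` (data.frame with
#'   `orthogroup_id`, `n_species`, `n_toxins`, `assigned_label`), `presence`
#'   (logical orthogroup x species matrix over all tree leaves),
#'   `clade_counts` (named integer vector of orthogroups per label), and
#'   `toxin_summary` (`n_toxins`, `n_in_shared_orthogroups`,
#'   `n_species_unique`).
#' @export
profile_orthogroups <- function(orthogroups, toxin_ids, tree,
                                focal_species = "Antarctonemertes_valida") {
  stopifnot(inherits(orthogroups, "OrthogroupTable"))
  validate_species_tree(tree)
  toxin_ids <- unique(as.character(toxin_ids))
  og <- as.data.frame(orthogroups, stringsAsFactors = FALSE)

  # orthogroups must partition sequences
  focal_rows <- og[og$species_id == focal_species, , drop = FALSE]
  seq2og <- data.frame(
    seq_id = unlist(focal_rows$member_sequence_ids, use.names = FALSE),
    orthogroup_id = rep(focal_rows$orthogroup_id,
                        lengths(focal_rows$member_sequence_ids)),
    stringsAsFactors = FALSE)
  dup <- unique(seq2og$seq_id[duplicated(seq2og$seq_id)])
  if (length(dup) > 0)
    stop_fmt("sequence id(s) in more than one orthogroup: %s",
             paste(dup, collapse = ", "))

  tox_map <- seq2og[seq2og$seq_id %in% toxin_ids, , drop = FALSE]
  tox_ogs <- unique(tox_map$orthogroup_id)
  species <- tree$tip.label
  if (length(tox_ogs) == 0) {
    pres <- matrix(FALSE, 0, length(species), dimnames = list(NULL, species))
    return(structure(list(
      assignments = data.frame(orthogroup_id = character(),
                               n_species = integer(), n_toxins = integer(),
                               assigned_label = character(),
                               stringsAsFactors = FALSE),
      presence = pres,
      clade_counts = integer(0),
      toxin_summary = c(n_toxins = length(toxin_ids),
                        n_in_shared_orthogroups = 0L,
                        n_species_unique = length(toxin_ids))),
      class = "LineageProfile"))
  }

  sub <- og[og$orthogroup_id %in% tox_ogs, , drop = FALSE]
  bad_sp <- setdiff(unique(sub$species_id), species)
  if (length(bad_sp) > 0)
    stop_fmt("species not in tree: %s", paste(bad_sp, collapse = ", "))
  pres <- matrix(FALSE, nrow = length(tox_ogs), ncol = length(species),
                 dimnames = list(tox_ogs, species))
  pres[cbind(match(sub$orthogroup_id, tox_ogs),
             match(sub$species_id, species))] <- TRUE
  assignments <- do.call(rbind, lapply(tox_ogs, function(g) {
    sp <- species[pres[g, ]]
    a <- assign_clade(sp, tree, focal_species)
    data.frame(orthogroup_id = g, n_species = a$n_species,
               n_toxins = sum(tox_map$orthogroup_id == g),
               assigned_label = a$assigned_label, stringsAsFactors = FALSE)
  }))
  rownames(assignments) <- NULL
  shared <- assignments[assignments$assigned_label != "species_unique", ,
                        drop = FALSE]
  counts <- table(assignments$assigned_label)
  counts <- structure(as.integer(counts), names = names(counts))
  n_in_shared <- sum(tox_map$orthogroup_id %in% shared$orthogroup_id)
  structure(list(
    assignments = assignments,
    presence = pres,
    clade_counts = counts,
    toxin_summary = c(n_toxins = length(toxin_ids),
                      n_in_shared_orthogroups = n_in_shared,
                      n_species_unique = length(toxin_ids) - n_in_shared)),
    class = "LineageProfile")
}

#' @export
print.LineageProfile <- function(x, ...) {
  cat(sprintf("LineageProfile: %d toxin orthogroups (%s); %d/%d toxins species-unique\n",
              nrow(x$assignments),
              paste(sprintf("%s=%d", names(x$clade_counts), x$clade_counts),
                    collapse = ", "),
              x$toxin_summary[["n_species_unique"]],
              x$toxin_summary[["n_toxins"]]))
  invisible(x)
}
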