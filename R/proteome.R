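# Standard average and monoisotopic residue masses (Da) for the 20
# proteinogenic amino acids; water is added once per chain.
AVERAGE_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0513, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

MONO_RESIDUE_MASS <- c(
  A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  E = 129.04259, Q = 128.05858, G = 57.02146, H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203, T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841)

WATER_AVERAGE <- 18.0153
WATER_MONO <- 18.010565
PROTON_AVERAGE <- 1.0079
PROTON_MONO <- 1.007276

#' Per-protein secretome presence/absence from peptide evidence
#'
#' Applies the two-peptide rule: a protein is considered reliably identified
#' in a proteome sample only if at least two distinct peptide sequences from
#' it pass that sample's identification q-value threshold. Distinctness is by
#' exact uppercase string comparison (I and L are distinct residues).
#' Repeated spectra of the same peptide never confer presence.
#'
#' @param evidence a [peptide_evidence()] object; every referenced sample
#'   must carry a `qvalue_threshold` in its metadata.
#' @param min_peptides minimum number of distinct passing peptides (default 2).
#' @return object of class `PresenceMatrix`: list with `matrix` (proteins x
#'   samples logical), `sample_meta`, and `summary` (per-protein `in_mucus`,
#'   `in_any_proboscis`, `in_whole_animal`, `n_proteomes_present`).
#' @export
build_presence_matrix <- function(evidence, min_peptides = 2) {
  stopifnot(inherits(evidence, "PeptideEvidenceTable"))
  meta <- evidence$sample_meta
  rows <- evidence$rows
  samples <- meta$proteome_sample_id
  thr <- meta$qvalue_threshold[match(rows$proteome_sample_id, samples)]
  if (nrow(rows) > 0 && anyNA(thr))
    stop_fmt("proteome sample without a qvalue_threshold: %s",
             paste(unique(rows$proteome_sample_id[is.na(thr)]), collapse = ", "))
  pass <- rows[!is.na(thr) & rows$qvalue <= thr, , drop = FALSE]
  pass <- unique(pass[, c("proteome_sample_id", "protein_id", "peptide_sequence")])
  proteins <- sort(unique(rows$protein_id))
  mat <- matrix(FALSE, nrow = length(proteins), ncol = length(samples),
                dimnames = list(proteins, samples))
  if (nrow(pass) > 0) {
    npep <- stats::aggregate(peptide_sequence ~ protein_id + proteome_sample_id,
                             data = pass, FUN = length)
    hit <- npep[npep$peptide_sequence >= min_peptides, , drop = FALSE]
    if (nrow(hit) > 0)
      mat[cbind(match(hit$protein_id, proteins),
                match(hit$proteome_sample_id, samples))] <- TRUE
  }
  cls <- meta$secretome_class
  summ <- data.frame(
    protein_id = proteins,
    in_mucus = rowSums(mat[, cls == "mucus", drop = FALSE]) > 0,
    in_any_proboscis = rowSums(mat[, cls == "proboscis", drop = FALSE]) > 0,
    in_whole_animal = rowSums(mat[, cls == "whole_animal", drop = FALSE]) > 0,
    n_proteomes_present = rowSums(mat),
    stringsAsFactors = FALSE)
  rownames(summ) <- NULL
  structure(list(matrix = mat, sample_meta = meta, summary = summ),
            class = "PresenceMatrix")
}

#' @export
print.PresenceMatrix <- function(x, ...) {
  cat(sprintf("PresenceMatrix: %d proteins x %d proteome samples; %d present in >=1\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$summary$n_proteomes_present > 0)))
  invisible(x)
}

#' Proteins detected in at least one proteome sample
#'
#' The candidate universe for toxin triage: every protein reliably identified
#' (two-peptide rule) in at least one of the analyzed proteomes.
#'
#' @param presence a `PresenceMatrix`.
#' @return character vector of protein ids.
#' @export
candidate_universe <- function(presence) {
  stopifnot(inherits(presence, "PresenceMatrix"))
  presence$summary$protein_id[presence$summary$n_proteomes_present >= 1]
}

#' Average (or monoisotopic) mass of a peptide or protein chain
#'
#' Sum of standard residue masses plus one water. Average masses suit
#' low-resolution linear-mode MALDI measurements of intact chains in the
#' 1-15 kDa range; the monoisotopic variant is available for high-resolution
#' data.
#'
#' @param sequence uppercase amino-acid string (20-letter alphabet).
#' @param monoisotopic use monoisotopic residue masses (default FALSE).
#' @return mass in Da.
#' @export
average_mass <- function(sequence, monoisotopic = FALSE) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0)
    stop_fmt("sequence must be a single non-empty amino-acid string")
  aa <- strsplit(sequence, "")[[1]]
  tab <- if (monoisotopic) MONO_RESIDUE_MASS else AVERAGE_RESIDUE_MASS
  bad <- which(!(aa %in% names(tab)))
  if (length(bad) > 0)
    stop_fmt("unknown residue '%s' at position %d", aa[bad[1]], bad[1])
  sum(tab[aa]) + if (monoisotopic) WATER_MONO else WATER_AVERAGE
}

#' Match candidate masses against a MALDI peak list
#'
#' Assuming singly protonated ions ([M+H]+), a candidate sequence matches an
#' observed peak when |mass(seq) + m(H+) - mz| <= tolerance. All matches are
#' returned sorted by |delta|; a candidate may match several peaks and a peak
#' several candidates.
#'
#' @param candidates named character vector: protein id -> sequence.
#' @param peaks a `PeakList` (or data.frame with `mz`, `intensity`).
#' @param tolerance_da match tolerance in Da (default 2.0, suited to
#'   linear-mode acquisition).
#' @param monoisotopic use monoisotopic masses (default FALSE).
#' @return data.frame of class `MassMatch` with columns `protein_id`,
#'   `predicted_mass`, `observed_mz`, `delta`, `charge_assumed`.
#' @export
match_peaks <- function(candidates, peaks, tolerance_da = 2.0,
                        monoisotopic = FALSE) {
  if (tolerance_da <= 0) stop_fmt("tolerance must be > 0")
  peaks <- peak_list(peaks)
  empty <- data.frame(protein_id = character(), predicted_mass = numeric(),
                      observed_mz = numeric(), delta = numeric(),
                      charge_assumed = integer(), stringsAsFactors = FALSE)
  class(empty) <- c("MassMatch", "data.frame")
  if (length(candidates) == 0 || nrow(peaks) == 0) return(empty)
  proton <- if (monoisotopic) PROTON_MONO else PROTON_AVERAGE
  masses <- vapply(candidates, average_mass, numeric(1),
                   monoisotopic = monoisotopic)
  grid <- expand.grid(ci = seq_along(candidates), pi = seq_len(nrow(peaks)))
  delta <- masses[grid$ci] + proton - peaks$mz[grid$pi]
  hit <- abs(delta) <= tolerance_da
  if (!any(hit)) return(empty)
  out <- data.frame(protein_id = names(candidates)[grid$ci[hit]],
                    predicted_mass = unname(masses[grid$ci[hit]]),
                    observed_mz = peaks$mz[grid$pi[hit]],
                    delta = unname(delta[hit]),
                    charge_assumed = rep(1L, sum(hit)),
                    stringsAsFactors = FALSE)
  out <- out[order(abs(out$delta), out$protein_id, out$observed_mz), ]
  rownames(out) <- NULL
  class(out) <- c("MassMatch", "data.frame")
  out
}
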