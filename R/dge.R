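#' Differential-expression configuration
#'
#' Thresholds and normalization settings for the two-tissue comparison. The
#' defaults are deliberately stringent: a candidate gene is only called
#' differentially expressed at FDR below 0.001 together with at least a
#' four-fold change (|log2FC| >= 2).
#'
#' @param alpha FDR cutoff for the DE call (default 0.001).
#' @param min_lfc minimum |log2 fold change| for the DE call (default 2).
#' @param trim_m TMM trim fraction on M-values (default 0.30).
#' @param trim_a TMM trim fraction on A-values (default 0.05).
#' @param dispersion `"estimate_common"` to estimate a single common
#'   negative-binomial dispersion from the data, or a fixed numeric value
#'   (>= 0).
#' @return list of class `DGEConfig`.
#' @export
dge_config <- function(alpha = 0.001, min_lfc = 2, trim_m = 0.30,
                       trim_a = 0.05, dispersion = "estimate_common") {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop_fmt("alpha must lie in (0,1)")
  if (!is.numeric(min_lfc) || min_lfc < 0)
    stop_fmt("min_lfc must be >= 0")
  if (is.numeric(dispersion)) {
    if (dispersion < 0) stop_fmt("fixed dispersion must be >= 0")
  } else if (!identical(dispersion, "estimate_common")) {
    stop_fmt("dispersion must be 'estimate_common' or a non-negative number")
  }
  structure(list(alpha = alpha, min_lfc = min_lfc, trim_m = trim_m,
                 trim_a = trim_a, dispersion = dispersion),
            class = "DGEConfig")
}

# TMM factor for one sample against the reference, on raw counts.
# M-values are depth-normalized log-ratios, A-values average log abundance;
# both are doubly trimmed before the precision-weighted mean.
tmm_pair_factor <- function(obs, ref, trim_m, trim_a) {
  n_obs <- sum(obs)
  n_ref <- sum(ref)
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]
  ref <- ref[keep]
  if (length(obs) == 0) return(1)
  p_obs <- obs / n_obs
  p_ref <- ref / n_ref
  logR <- log2(p_obs / p_ref)
  absE <- (log2(p_obs) + log2(p_ref)) / 2
  # binomial precision of M at a common nominal depth: depends only on the
  # depth-normalized proportions, so pure depth changes leave factors intact
  v <- (1 - p_obs) / p_obs + (1 - p_ref) / p_ref
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * trim_m) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * trim_a) + 1
  hiS <- n + 1 - loS
  keep2 <- rank(logR) >= loL & rank(logR) <= hiL &
    rank(absE) >= loS & rank(absE) <= hiS
  if (!any(keep2)) return(1)
  f <- sum(logR[keep2] / v[keep2]) / sum(1 / v[keep2])
  if (!is.finite(f)) f <- 0
  2^f
}

#' Trimmed-mean-of-M-values (TMM) normalization factors
#'
#' Estimates per-sample relative RNA composition factors: the reference sample
#' is the one whose 75th-percentile count proportion is closest to the mean
#' across samples; for every other sample, genes with a zero in either sample
#' are excluded, per-gene M-values (depth-normalized log2 ratios) and
#' A-values (average log2 abundance) are doubly trimmed, and the factor is
#' 2 to the precision-weighted trimmed mean of M. Factors are rescaled so
#' their geometric mean is 1.
#'
#' @param counts a `CountMatrix` or a numeric matrix of raw counts.
#' @param trim_m M-value trim fraction (default 0.30).
#' @param trim_a A-value trim fraction (default 0.05).
#' @return named numeric vector of normalization factors, one per sample.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  m <- if (inherits(counts, "CountMatrix")) counts$counts else as.matrix(counts)
  if (ncol(m) < 2) stop_fmt("TMM needs at least 2 samples")
  lib <- colSums(m)
  if (any(lib == 0)) {
    bad <- colnames(m)[lib == 0]
    stop_fmt("sample(s) with all-zero counts: %s", paste(bad, collapse = ", "))
  }
  f75 <- apply(m, 2, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(m)), function(j) {
    if (j == ref) return(1)
    tmm_pair_factor(m[, j], m[, ref], trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(m)
  f
}

# Conditional negative-binomial log-likelihood of equal-library counts given
# their total, summed over genes, for one group. y: genes x replicates.
cond_loglik_group <- function(y, phi) {
  n <- ncol(y)
  if (n < 2) return(0)
  r <- 1 / phi
  t <- rowSums(y)
  sum(lgamma(y + r)) - nrow(y) * n * lgamma(r) +
    length(t) * lgamma(n * r) - sum(lgamma(t + n * r))
}

#' Estimate a common negative-binomial dispersion
#'
#' Maximizes the conditional negative-binomial log-likelihood of within-group
#' counts given the per-gene group totals, after scaling all samples to a
#' common effective library size (the geometric mean of effective sizes,
#' counts rounded to the nearest integer). Conditioning on totals removes the
#' per-gene mean as a nuisance parameter, leaving a one-dimensional likelihood
#' in the dispersion. Returns 0 when the likelihood is maximized at the
#' Poisson boundary.
#'
#' @param counts a `CountMatrix`.
#' @param factors TMM normalization factors (default: computed).
#' @return estimated dispersion, a single number >= 0.
#' @export
estimate_common_dispersion <- function(counts, factors = NULL) {
  stopifnot(inherits(counts, "CountMatrix"))
  if (is.null(factors)) factors <- tmm_factors(counts)
  eq <- equalize_libraries(counts, factors)
  groups <- split(seq_along(counts$samples), counts$meta$tissue)
  groups <- Filter(function(ix) length(ix) >= 2, groups)
  if (length(groups) == 0)
    stop_fmt("need >=2 replicates in at least one group to estimate dispersion")
  keep <- rowSums(eq$pseudo) > 0
  y_groups <- lapply(groups, function(ix) eq$pseudo[keep, ix, drop = FALSE])
  nll <- function(log_phi) {
    phi <- exp(log_phi)
    -sum(vapply(y_groups, cond_loglik_group, numeric(1), phi = phi))
  }
  opt <- stats::optimize(nll, interval = c(log(1e-8), log(20)), tol = 1e-6)
  phi_hat <- exp(opt$minimum)
  # boundary check: if the likelihood near phi = 0 is as good as the interior
  # optimum, report the Poisson limit
  if (phi_hat < 2e-8 || nll(log(1e-8)) <= opt$objective + 1e-8) return(0)
  phi_hat
}

#' Exact conditional negative-binomial test for a two-group count comparison
#'
#' Conditions on the per-gene total t = yA + yB after library-size
#' equalization: the sum of nA i.i.d. NB(mu, 1/phi) counts is NB with shape
#' nA/phi, so the conditional law of yA given t is a ratio of negative
#' binomial coefficients. The two-sided p-value is the total conditional
#' probability of all outcomes k whose probability does not exceed that of
#' the observed yA. At phi = 0 the conditional law is binomial(t, nA/(nA+nB)).
#'
#' @param yA group-A (proboscis) gene total after equalization.
#' @param yB group-B (body) gene total after equalization.
#' @param nA number of replicates in group A.
#' @param nB number of replicates in group B.
#' @param phi common dispersion (>= 0).
#' @return two-sided p-value in (0, 1].
#' @export
nb_exact_test <- function(yA, yB, nA, nB, phi = 0) {
  if (yA < 0 || yB < 0) stop_fmt("group totals must be non-negative")
  if (phi < 0) stop_fmt("dispersion must be >= 0")
  yA <- round(yA)
  yB <- round(yB)
  t <- yA + yB
  if (t == 0) return(1)
  k <- 0:t
  if (phi == 0) {
    lp <- stats::dbinom(k, t, nA / (nA + nB), log = TRUE)
  } else {
    r <- 1 / phi
    lp <- lgamma(k + nA * r) - lgamma(k + 1) + lgamma(t - k + nB * r) -
      lgamma(t - k + 1)
    lp <- lp - max(lp)
    lp <- lp - log(sum(exp(lp)))
  }
  p_obs <- lp[yA + 1]
  p <- sum(exp(lp[lp <= p_obs + 1e-10]))
  min(max(p, .Machine$double.xmin), 1)
}

# Scale counts to a common effective library size (geometric mean of
# effective sizes) and round to the nearest integer, so that the conditional
# arguments of the exact test and dispersion likelihood hold.
equalize_libraries <- function(counts, factors) {
  m <- counts$counts
  eff <- colSums(m) * factors
  common <- exp(mean(log(eff)))
  pseudo <- round(sweep(m, 2, common / eff, `*`))
  list(pseudo = pseudo, common_size = common, effective = eff)
}

#' Two-tissue differential expression with the exact conditional NB test
#'
#' The full DGE stage: TMM normalization, library-size equalization, common
#' dispersion (estimated or fixed), per-gene exact conditional NB test of
#' proboscis vs body totals, Benjamini-Hochberg adjustment across tested
#' genes, and the call rule `fdr < alpha AND |log2FC| >= min_lfc`. Genes with
#' zero counts in every sample are excluded from testing and reported with
#' call `"untested"`.
#'
#' @param counts a `CountMatrix` with both tissues present.
#' @param config a [dge_config()].
#' @return data.frame of class `DGEResult` with columns `gene_id`, `log2FC`
#'   (proboscis over body), `logCPM`, `p_value`, `fdr`, `call`; attribute
#'   `dispersion` carries the dispersion used.
#' @export
run_dge <- function(counts, config = dge_config()) {
  stopifnot(inherits(counts, "CountMatrix"), inherits(config, "DGEConfig"))
  tissue <- counts$meta$tissue
  ixA <- which(tissue == "proboscis")
  ixB <- which(tissue == "body")
  if (length(ixA) < 1 || length(ixB) < 1)
    stop_fmt("need at least one sample per tissue")
  factors <- tmm_factors(counts, config$trim_m, config$trim_a)
  phi <- if (is.numeric(config$dispersion)) config$dispersion
         else estimate_common_dispersion(counts, factors)
  eq <- equalize_libraries(counts, factors)
  tested <- rowSums(counts$counts) > 0
  nA <- length(ixA)
  nB <- length(ixB)
  yA <- rowSums(eq$pseudo[, ixA, drop = FALSE])
  yB <- rowSums(eq$pseudo[, ixB, drop = FALSE])
  lfc <- log2((yA / nA + 0.5) / (yB / nB + 0.5))
  logcpm <- log2((yA + yB + 0.5) / ((nA + nB) * eq$common_size) * 1e6)
  p <- rep(NA_real_, length(counts$genes))
  p[tested] <- vapply(which(tested), function(g)
    nb_exact_test(yA[g], yB[g], nA, nB, phi), numeric(1))
  fdr <- rep(NA_real_, length(p))
  fdr[tested] <- stats::p.adjust(p[tested], method = "BH")
  call <- rep("untested", length(p))
  de <- tested & fdr < config$alpha & abs(lfc) >= config$min_lfc & lfc != 0
  de[is.na(de)] <- FALSE
  call[tested] <- "not_de"
  call[de & lfc > 0] <- "up_proboscis"
  call[de & lfc < 0] <- "up_body"
  out <- data.frame(gene_id = counts$genes, log2FC = unname(lfc),
                    logCPM = unname(logcpm), p_value = unname(p),
                    fdr = unname(fdr), call = call,
                    stringsAsFactors = FALSE)
  attr(out, "dispersion") <- phi
  attr(out, "norm_factors") <- factors
  attr(out, "config") <- config
  class(out) <- c("DGEResult", "data.frame")
  out
}

#' Hypergeometric target-vs-background term enrichment
#'
#' For each annotation term, tests whether the target gene list (e.g. genes
#' upregulated in the proboscis) is enriched for the term relative to the
#' background (the rest of the transcriptome), using the hypergeometric upper
#' tail: the probability of drawing at least b term-annotated genes in n
#' draws from a universe of N genes of which B carry the term. Genes missing
#' from the annotation map count in n and N with zero terms.
#'
#' @param target character vector of target gene ids (non-empty).
#' @param background character vector of background gene ids; the test
#'   universe is the union of target and background.
#' @param annotations data.frame with columns `gene_id` and `term`, or a
#'   named list mapping gene id to a character vector of terms.
#' @return data.frame of class `EnrichmentResult` with columns `term`, `b`,
#'   `n`, `B`, `N`, `p_value`, `fdr`, `enrichment_fold`, sorted by p-value.
#' @export
enrich_terms <- function(target, background, annotations) {
  target <- unique(as.character(target))
  if (length(target) == 0) stop_fmt("target gene set must be non-empty")
  universe <- unique(c(target, as.character(background)))
  if (is.data.frame(annotations)) {
    if (!all(c("gene_id", "term") %in% names(annotations)))
      stop_fmt("annotations data.frame needs columns gene_id, term")
    ann <- annotations[annotations$gene_id %in% universe, , drop = FALSE]
  } else {
    ann <- data.frame(
      gene_id = rep(names(annotations), lengths(annotations)),
      term = unlist(annotations, use.names = FALSE),
      stringsAsFactors = FALSE)
    ann <- ann[ann$gene_id %in% universe, , drop = FALSE]
  }
  ann <- unique(ann[, c("gene_id", "term")])
  N <- length(universe)
  n <- length(target)
  terms <- sort(unique(ann$term))
  if (length(terms) == 0)
    return(structure(data.frame(term = character(), b = integer(),
                                n = integer(), B = integer(), N = integer(),
                                p_value = numeric(), fdr = numeric(),
                                enrichment_fold = numeric(),
                                stringsAsFactors = FALSE),
                     class = c("EnrichmentResult", "data.frame")))
  in_target <- ann$gene_id %in% target
  B <- as.integer(table(factor(ann$term, levels = terms)))
  b <- as.integer(table(factor(ann$term[in_target], levels = terms)))
  p <- stats::phyper(b - 1, B, N - B, n, lower.tail = FALSE)
  out <- data.frame(term = terms, b = b, n = n, B = B, N = N,
                    p_value = p, fdr = stats::p.adjust(p, method = "BH"),
                    enrichment_fold = (b / n) / (B / N),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, -out$enrichment_fold, out$term), ]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}
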