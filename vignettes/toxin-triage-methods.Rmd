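---
title: "Methods: proteotranscriptomic toxin triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteotranscriptomic toxin triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Nemertean worms lack a compact venom gland, so their toxins cannot be
sampled directly; candidates must be inferred by combining tissue-level
transcriptomics (which genes are biased toward the venom-delivering
proboscis or the mucus-producing body wall), secretome proteomics (which
predicted proteins are actually observed in which secretion), and homology
(which proteins resemble known toxin families). `nemtox` implements this
integration as a pipeline whose every stage is testable against simulated
ground truth.

# The count model and the exact test

Counts for gene $g$ in library $s$ are modelled as negative binomial with
mean $\mu_{gs}$ and dispersion $\phi$, so that
$\mathrm{Var} = \mu + \phi\mu^2$. The model assumes a single common
dispersion across genes — adequate for the desk-scale designs the package
targets (a dozen libraries, thousands of genes); tagwise or trended
dispersion is deliberately out of scope.

Three steps make the two-group comparison exact rather than asymptotic:

1. **TMM normalization.** Sequencing depth alone does not make libraries
   comparable when a few transcripts dominate one tissue, which is exactly
   the situation in a secretory organ. The trimmed mean of M-values
   estimates relative RNA composition: reference = sample whose
   75th-percentile count proportion is closest to the mean; genes zero in
   either sample are dropped; M-values (log2 ratio of depth-normalized
   proportions) are trimmed at 30% each side and A-values (mean log2
   abundance) at 5%; the factor is $2^{\bar M_w}$ with precision weights,
   rescaled so factors have geometric mean 1.

   *Numerical choice.* The precision weights are binomial variances
   computed from the depth-normalized proportions at a common nominal
   depth, not from each library's raw counts. The two weightings agree
   closely (within about 1–2% on factors under strong depth variation;
   the unit tests cross-check against edgeR at 2% relative tolerance), but
   only the proportion-based weights make a factor exactly invariant when a
   sample's counts are scaled by pure depth — an invariance we consider
   definitional for a composition estimator, and which the test suite
   asserts at 1e-6.

2. **Library equalization.** The conditional arguments below require equal
   library sizes. Counts are scaled to the geometric mean of the effective
   (TMM-adjusted) library sizes and rounded to the nearest integer — a
   deterministic, documented stand-in for quantile-based pseudo-count
   adjustment. Rounding error is negligible relative to biological
   variation at the count depths simulated.

3. **Exact conditional NB test.** Conditioning on the per-gene total
   $t = y_A + y_B$ removes the nuisance mean: since a sum of $n$ i.i.d.
   NB$(\mu, \phi)$ counts is NB with shape $n/\phi$,
   $P(Y_A = k \mid t) \propto \binom{k + n_A/\phi - 1}{k}
   \binom{t-k + n_B/\phi - 1}{t-k}$. The two-sided p-value sums the
   conditional probabilities of all outcomes whose probability does not
   exceed that of the observed count (ties included with a $1+10^{-10}$
   relative tolerance, so enumeration oracles agree to 1e-9). At
   $\phi = 0$ the law is binomial$(t, n_A/(n_A+n_B))$. Computation is a
   single $O(t)$ pass in log space per gene.

The common dispersion maximizes the summed conditional NB log-likelihood of
within-group counts given group totals over $\log\phi$; when the optimum is
not better than the $\phi \to 0$ boundary the Poisson limit 0 is returned.

**Call rule.** `FDR < 0.001` (Benjamini–Hochberg across tested genes) *and*
`|log2FC| >= 2`. The fold-change estimate adds 0.5 to each group's mean
pseudo-count before the ratio, which bounds estimates for genes observed in
only one tissue. Genes with zero counts everywhere are reported `untested`,
never dropped. BH was chosen as the FDR procedure because it is the default
of the DGE tools this stage emulates; both thresholds are configurable
(`dge_config`).

# Term enrichment

Target-vs-background enrichment uses the fixed-list hypergeometric upper
tail: with $N$ universe genes of which $B$ carry a term, and $n$ target
genes of which $b$ carry it, $p = P(X \ge b)$, BH-adjusted across terms,
with fold $= (b/n)/(B/N)$. The universe is the union of target and
background; genes absent from the annotation map count with zero terms
(the "rest of the transcriptome" framing). The ranked-list
minimum-hypergeometric variant was deliberately not implemented: the
pipeline always has explicit lists. GO terms are flat labels — no ontology
graph propagation.

# Proteome evidence

The two-peptide rule is applied per (protein, sample): presence requires at
least two *distinct* peptide sequences with q-value at or below that
sample's identification threshold. Distinctness is exact uppercase string
equality; in particular **isoleucine and leucine are treated as distinct**.
Search engines that cannot separate I/L from fragment masses may merge such
peptides; we prefer the deterministic, documented choice and note that it
can only make presence calls more permissive (two I/L-variant peptides
count as two). The different identification-FDR conventions of the two
upstream search tracks (PSM FDR 0.01 for LC–MS/MS, local FDR < 0.5% for
shotgun) are modelled as per-sample thresholds in the metadata, not as two
code paths.

Mass matching assumes singly protonated ions and average residue masses by
default (±2.0 Da tolerance), consistent with low-resolution linear-mode
MALDI acquisition of 1–15 kDa peptides; monoisotopic masses are available
under a flag. Sequences are matched exactly as given — whether they
represent mature, post-translationally processed chains is the caller's
responsibility.

# Classification

The four-way rule is a total function on (DE call, in mucus, in any
proboscis proteome), with **dual-function taking precedence**: presence in
both secretomes classifies a candidate as dual regardless of expression
bias. This resolves patterns the verbal rules leave open (e.g.
proboscis-upregulated but present in both secretomes); the dual rule as
stated is unconditional on DE status, so precedence follows it. Candidates
whose gene has no DGE row are classified with `de_call = untested`
(treated as `not_de`) and flagged — conservative and auditable. Whole-animal
presence contributes to candidacy (the detected universe) but to no class
rule, since only mucus and proboscis secretomes carry functional meaning.

# Lineage profiling

Only *named* internal nodes are assignable labels; the assignment of a
species set is the named clade with the fewest leaves whose leaf set
contains it, ties broken by closeness to the root. Sets whose MRCA is
unnamed therefore roll up to the nearest named ancestor. A set equal to
{focal species} is `species_unique`. If no named clade contains the set
(an unlabelled root), the fallback label `root` is reported rather than
guessing intent; backbone trees should name the clades they want reported
(the default backbone names Nemertea, Palaeonemertea, Neonemertea =
Pilidiophora + Hoplonemertea, Pilidiophora, Hoplonemertea, and
Antarctonemertes). Orthogroups must partition sequences; a toxin id in two
orthogroups is an error, not a silent choice.

# The synthetic-data generator

The generator is the package's acceptance surface: it emulates the study
design — 6 proboscis + 6 body libraries from six individuals, five proteome
samples (1 whole animal, 1 mucus, 3 proboscis), a ten-species backbone
tree — with every label recorded.

Key defaults and their rationale:

| parameter | default | why |
|---|---|---|
| `n_genes` | 2000 | desk-scale; enough genes for stable TMM/dispersion estimation |
| `phi` | 0.1 | typical biological-replicate overdispersion for invertebrate tissue RNA-seq |
| `fraction_de` | 0.1 | planted DE fraction, split 50/50 between tissues |
| `lfc_range` | [2, 6] | planted effects at and above the pipeline's own call threshold |
| `library_size_log_sd` | 0.3 | log-normal depth variation; equal depths would make TMM untestable |
| `baseline_meanlog/sdlog` | log 30 / 1.2 | right-skewed expression with realistic dynamic range |
| detection intercept/slope | −6 / 1.2 | logistic detection vs log expression: abundant proteins detected at ~0.8, background at ~0.1 |
| `peptide_lambda` | 3 | detected proteins get 1 + Poisson(3) distinct peptides; support includes 1 so the two-peptide rule is exercised |
| `qvalue_thresholds` | 0.01 / 0.005 | the two identification-FDR conventions |
| clade sharing probs | 29:6:13:2:9 / 59 | proportions of a hoplonemertean toxin repertoire's sharing pattern (focal-unique : genus : Hoplonemertea : Neonemertea : all) |
| `n_go_terms`, `go_terms_per_gene` | 40, 4 | term density such that a five-fold planted enrichment in a ~50–100-gene target list is statistically identifiable, which the recovery tests require |

Mucus detection is driven by *body* expression (the mucus is a body-wall
secretion), proboscis samples by proboscis expression, the whole-animal
sample by the across-tissue mean. True presence is defined as "detected
and ≥ 2 distinct peptides drawn", so the recorded truth is exactly what a
correct two-peptide implementation should recover — classification-recovery
tests therefore isolate the integration logic from detection noise. For
fully noiseless fixtures, `peptide_count_fixed = 3` and
`decoy_fraction = 0` remove the remaining stochasticity.

What the generator does **not** emulate: read-level artifacts (mapping
ambiguity, positional bias), correlated detection across peptides of one
protein, shared peptides between proteins (no protein-grouping problem),
I/L-ambiguous identifications, orthology-inference errors, and gene-tree /
species-tree discordance. Passing tests therefore demonstrate correctness
of the statistics and the integration rules under the stated model, not
robustness to upstream tool error on real data.

# Problem sizes and determinism

The shipped tests run the null-FDR study at 2,000 genes × 20 seeds, the
recovery study at 2,000 genes with planted |log2FC| = 4, oracle
equivalence on 200 random exact-test instances and 100 random
(tree, subset) clade instances — sizes chosen so the full suite completes
in well under a minute while keeping Monte-Carlo error small relative to
the asserted bands. Every generator is a pure function of (config, seed);
the pipeline summary contains no timestamps, so a fixed seed reproduces
byte-identical outputs, which the suite asserts.

# Known limitations

- Common dispersion only; genes with atypical variability are mis-served
  (by design, matching the emulated tool's classic exact-test path).
- The fold-change shrinkage (0.5 pseudo-count per group) is cruder than
  GLM-based shrinkage estimators; rankings are fine, extreme |log2FC|
  values for near-zero genes are bounded but not calibrated.
- The classifier consumes binary presence; peptide counts beyond the
  two-peptide threshold carry no weight.
- Minimal-clade assignment is presence-based labelling, not a loss-aware
  ancestral reconstruction (no Dollo parsimony).
- Average-mass matching ignores PTMs and isotope structure; at ±2 Da in a
  crowded 1–15 kDa window, matches are hypotheses, not identifications.
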