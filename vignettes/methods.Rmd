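---
title: "Discovering shared AML transcriptional programs and their clinical associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering shared AML transcriptional programs and their clinical associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Acute myeloid leukemia (AML) blasts are heterogeneous both across and within
patients, and that heterogeneity shapes how well cytotoxic T cells eliminate
them in co-culture. `amlprog` implements an analysis chain for longitudinal
single-cell co-culture experiments — several patients, AML cells and effector
T cells profiled at 0h and 24h of co-culture with replicate effector donors —
that (i) discovers *transcriptional programs* shared across patients, (ii)
scores the abundance of those programs in independent bulk RNA-seq cohorts,
(iii) associates abundance with killing sensitivity (elimination efficiency),
disease subtype and survival, and (iv) nominates receptor–ligand
interactions between AML programs and responding T cells.

Everything is exercised end-to-end on synthetic data with planted ground
truth, so each stage's behaviour is verifiable without access to any
deposited dataset.

## Two-tier program discovery

Global clustering of pooled single cells mostly recovers patient identity
and culture-induced shifts, not shared biology. The package therefore uses a
two-tier procedure:

1. **Tier 1 — within-sample clustering.** Cells of each patient × timepoint
   sample are clustered independently: PCA on the jointly selected highly
   variable genes (default 2,000 HVGs, 30 components), Ward agglomerative
   clustering on the embedding, and per-sample model selection by maximum
   mean silhouette width over k ∈ 2..8. Clustering within samples removes
   patient- and incubation-level variation by construction.
2. **Tier 2 — meta-clustering of centroids.** The mean normalised
   transcriptome of every within-sample cluster is computed over the HVG
   space, and these centroids are clustered hierarchically with correlation
   distance (1 − Pearson) and average linkage, cut at `k_programs`
   (default 5). Groups of centroids that recur across patients and
   timepoints are the shared programs; labels are ordered by total member
   cell count.

Deterministic agglomerative clustering (rather than a graph/community
method with random initialisation) was a deliberate choice: silhouette-based
model selection gives reproducible cluster counts, and the whole pipeline is
bit-reproducible given a seed, which the test suite relies on. The HVG space
is selected jointly across samples so that tier-2 centroids live in a
comparable coordinate system.

**Markers.** Each program is contrasted against all other assigned cells by
a per-gene two-sided Wilcoxon rank-sum test, with log2 fold change computed
on de-logged means (`log2(mean(expm1(in)) + ε) − log2(mean(expm1(out)) + ε)`,
ε = 1e−9) and Benjamini–Hochberg correction within program. A gene is an
*overexpressed marker* when log2FC > 0.25 and q < 0.05 — the conventional
single-cell defaults, configurable. For the sample sizes involved the test
uses the tie-corrected normal approximation; for groups of at most 8 cells
it switches to exact enumeration of the rank-sum distribution, which the
tests check against an independent enumeration oracle.

**Program-level QC.** A program is removed iff it has **fewer than 200
overexpressed markers AND more than 20% mean mitochondrial reads** — a
conjunction, so marker-poor but clean programs and marker-rich but
mitochondria-heavy programs both survive. Dropped programs keep audit rows;
their cells become unassigned. Mitochondrial genes are recognised by the
human "MT-" name prefix. Cell-level QC defaults are min 200 genes detected
and (in the pipeline) a permissive 75% mitochondrial ceiling: the permissive
cell threshold is intentional, so that a genuinely low-quality
*program* reaches tier 2 and is removed by the program-level rule rather
than silently at the cell level.

**Differentiation score.** A simplified transcriptional-diversity score:
per-cell gene counts are correlated with each gene's expression, the
per-cell mean of the 200 most count-correlated genes is min–max rescaled to
[0, 1], higher = less differentiated. This is a reimplementation of the
diversity idea only, not of any published tool, and is labelled as such.

## Outcome association in bulk cohorts

Program abundance in a bulk sample is the mean per-gene z-score (across
samples) over the program's signature genes (top 50 overexpressed markers by
fold change). This `zsig` method was chosen for transparency; the interface
accepts externally computed abundance matrices so deconvolution-style
estimators can be plugged in. Scores are z-standardised per program so
programs with different signature sizes are comparable when assigning each
sample's *dominant program* (argmax, ties to the lowest-indexed program).

Association statistics are deliberately standard: Spearman correlation with
elimination efficiency (exact p for n ≤ 9), Wilcoxon rank-sum subtype
enrichment with BH correction across the whole programs × categories grid
(one heatmap, one correction), Kaplan–Meier / log-rank by dominant program,
and Cox proportional hazards on continuous abundance with Efron tie handling
(the `survival` package's Newton–Raphson maximiser; the test suite verifies
the estimate against a grid-search partial-likelihood oracle). The
risk-adjusted mode adds a high-risk indicator as a second covariate.

## T-cell response and interaction scoring

Differential expression of T cells at 24h vs 0h, stratified by whether the
co-culture partner was killing-sensitive or -resistant, uses the same
Wilcoxon + BH machinery ("differentially expressed": q < 0.05 and
|log2FC| > 0.25). Genes uniquely overexpressed with sensitive partners are
tested for over-representation in reference signatures by the one-sided
hypergeometric tail with BH across signatures; over-representation of a
fixed gene list was preferred to rank-based enrichment because the input is
a fixed top-50 list, for which the hypergeometric test is exact and
deterministic.

Receptor–ligand pairs (multi-subunit complexes written `"A+B"`) are scored
in both orientations between an AML program's cells and T cells. For each
orientation the *expression fraction* (complexes require every subunit at
count > 0 in the same cell, so a complex's fraction never exceeds its
weakest subunit's) and the mean subunit log2FC are computed; pairs with both
sides upregulated are ranked by `(frac_a · frac_b) · (lfc_a + lfc_b)`. The
ranking formula is an explicit package invention — monotone in exactly the
two displayed quantities — and is isolated in one function so it can be
replaced.

## Killing assay

Elimination efficiency is
`EE% = (1 − count(with T cells) / count(alone)) × 100`. Classification uses
strict cutoffs: sensitive above 50, resistant below 25, boundary values
indeterminate. Negative EE (target outgrowth) is retained, not clipped, so
inhibitor-rescue experiments remain representable. Replicate effector donors
are summarised by median and IQR, with the class assigned from the median.

## The synthetic-data generator

The generator emulates the study design: 4 patients (half sensitive, half
resistant) × 2 timepoints × 2 replicate donors × 800 AML cells plus 250
T cells per sample, 2,000 genes. Counts are negative binomial
(gamma–Poisson, shared dispersion 0.5) with log-normal library sizes
(meanlog log 2500, sdlog 0.3), patient-specific per-gene multiplicative
baseline shifts (lognormal, sdlog 0.15), and 4 good planted programs
(150-gene signatures, 10% overlap between neighbouring signatures, 3× mean
uplift) mixed per sample on a simplex, plus one planted low-quality program:
a weak 20-gene signature and a mitochondrial uplift calibrated so its cells
average ~30% mitochondrial reads. All 24h cells receive a 50-gene activation
module (2×); one program's mixing weight is depleted at 24h (×0.4) so
composition shifts over time are testable. T cells of sensitive patients
gain a 100-gene response module at 24h; resistant-partner T cells do not,
planting the sensitive ≫ resistant DE-count asymmetry. Bulk cohorts are
log2 mixtures of per-program pseudo-bulk profiles with Gaussian noise; EE is
linear in the mixing proportions (positive coefficient on the P1-like
program, negative on the P3-like one, clipped to [−20, 100]), subtypes are
drawn with program-dependent odds, and survival times are exponential with
hazard ∝ exp(Σ β_p·proportion_p).

These defaults were fixed once, as what we consider a realistic desk-scale
emulation of such an experiment, and the test suite runs against them. What
the generator does **not** emulate — doublets, ambient RNA, cell-cycle
structure, batch chemistry, UMI saturation — bounds what passing tests can
say about real data: they demonstrate correctness of the procedures under
the stated generative model, not robustness to artefacts the model omits.

## Numerical and design notes

- Determinism: a single global seed fans out to stage seeds
  (`seed + 1000·stage`); reruns produce byte-identical output manifests
  (MD5 per artifact).
- Silhouette degenerate cases (identical cells, tiny samples) fall back to
  a single cluster with a warning rather than failing.
- Wilcoxon ties: tie-corrected variance with continuity correction,
  matching `wilcox.test`; exact enumeration handles ties via mid-ranks.
- Zero-variance genes z-score to 0 (logged) in bulk scoring; exact
  abundance ties resolve to the lowest-indexed program with margin 0.
- Problem sizes in the tests (12,800 AML cells at study scale; smaller
  configurations for module tests) were chosen so the full suite and the
  reproduction script each complete comfortably on a single CPU.
- Known limitations: tier-1 k is capped at 8; the abundance scorer is
  signature-based, not a deconvolution; the interaction score is a ranking
  heuristic, not a communication-probability model; the differentiation
  score is a simplified stand-in.
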