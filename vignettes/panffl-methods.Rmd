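---
title: "Scoring dysregulated TF–miRNA feed-forward loops across tumor types"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring dysregulated TF–miRNA feed-forward loops across tumor types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Transcription factors (TFs) activate or repress transcription; microRNAs
(miRNAs) repress their targets post-transcriptionally. When a TF and a
miRNA share a target gene and one of them also regulates the other, the
three molecules form a feed-forward loop (FFL) — a motif that buffers
expression noise and is recurrently rewired in cancer. `panffl` asks, for
a curated background network and matched tumor/normal expression data from
several tumor types: *which FFLs are dysregulated in which tumors, and
which of them recur across many tumor types (pan-cancer FFLs)?*

## The model

### Loop classes

On a typed directed network with TF, miRNA and gene nodes, a candidate
loop is a triple (TF, miRNA, gene) where both regulators target the gene.
The TF–miRNA relation fixes the class: **TF-FFL** (TF→miRNA), **miRNA-FFL**
(miRNA→TF), **FB-FFL** (both directions — a feed-back pair). Classes are
exclusive: a triple with mutual regulation is emitted once, as FB-FFL.
This makes the three class counts a partition of the total, which is how
the class-enrichment test expects them.

### Node and edge scores

For one tumor type with \(n\) matched pairs, every detected molecule gets
a differential-expression P-value \(p_i\) and the node score

\[ N_i = \Phi^{-1}(1 - p_i), \]

the standard-normal quantile of its significance (0 at \(p = 0.5\), about
8.2 at the clipping floor). Every loop edge gets a differential
co-expression score: Spearman correlations \(r_{tumor}\), \(r_{normal}\)
of the two endpoints, computed per condition on CPM-normalized counts, are
Fisher-transformed, \(F(r) = \tfrac12\ln\frac{1+r}{1-r}\), and their
difference standardized as

\[ D = \frac{F(r_{tumor}) - F(r_{normal})}
           {\sqrt{1.06/(n_{tumor}-3) + 1.06/(n_{normal}-3)}}, \qquad
   E_i = \Phi^{-1}\!\bigl(1 - 2(1 - \Phi(|D|))\bigr). \]

\(E_i\) depends on \(D\) only through \(|D|\): a gained or a lost
correlation both count as dysregulation. The composite loop score is

\[ S = \lambda \frac{\sum N_i}{k_N} + (1-\lambda) \frac{\sum E_i}{k_E},
   \qquad k_N = k_E = 3,\ \lambda = 0.5 . \]

An FB-FFL has four regulatory edges but only three distinct molecule
pairs, so \(k_E\) stays 3 and the TF–miRNA pair is scored once.

### Empirical significance

The null distribution of \(S\) is built from random molecule triples —
one detected TF, one miRNA, one gene, drawn uniformly with replacement —
scored with the same machinery over the same three pair positions,
whether or not any regulation exists (default 100 000 triples;
simulations in this package use 2 000–10 000). The empirical P-value is
the fraction of null scores strictly above the observed \(S\); loops with
\(P < 0.05\) are called dysregulated in that tumor. A loop whose TF,
miRNA or gene fails the expression filter is *untestable* in that tumor,
reported distinctly and never counted as non-significant. Because every
score — real or null — is computed from the same tumor's data, global
shifts (for example the composition bias CPM inherits when a few
high-count molecules change) affect both sides equally and largely cancel
in the empirical P.

Two deliberately open choices are exposed as flags: `null_mode`
(`"role"`, the default, vs `"uniform"` triples ignoring roles) and the
empirical-P variant (`"paper"`, which can return exactly 0, vs
`"pseudocount"`, \((N_{>S}+1)/(N_p+1)\)). Role-respecting sampling keeps
the null comparable to real loops, which is why it is the default. No
multiple-testing correction is applied to loop P-values; the pan-cancer
aggregation consumes the raw \(P < 0.05\) calls.

### Pan-cancer aggregation

Loops dysregulated in at least `min_tumors = 5` tumor types are
pan-cancer FFLs. The size of that set is tested by shuffling, within each
tumor, which tested loops carry that tumor's flags (per-tumor counts
preserved exactly, 1000 replicates). Class enrichment of the pan-cancer
set uses the upper-tail hypergeometric \(P(X \ge k)\) including the
observed value — with the published counts (18 TF-FFLs among 26
pan-cancer loops, 244 among 505) this evaluates to 0.023. Annotation
enrichments (cancer genes, drug targets) are two-sided Fisher tests;
anticancer-drug (ATC L01) enrichment reuses the hypergeometric kernel;
hub/bottleneck comparisons are one-sided Wilcoxon rank-sum tests on
degree and betweenness from the background network.

## Differential expression

The upstream study delegated DE calling to edgeR; here the DE stage is
pluggable. The built-in test is an exact negative-binomial two-group
test: libraries are scaled to their geometric-mean size, per-molecule
dispersions estimated by method of moments and shrunk toward the common
(median) value with a prior weight of 10 residual degrees of freedom
(negative estimates clamp to the Poisson limit and are flagged), and the
two-sided P-value is the probability mass of group totals no more likely
than the observed split, conditional on the overall total. The
`external` method accepts any engine's per-molecule P-values and log2
fold changes from a TSV instead. Pairing metadata is used for
bookkeeping only — the test is two-group, matching the upstream design.

A molecule is *detected* when its CPM exceeds 1 in at least half of all
samples (`ceiling(n/2)`, so 19 of 38). DE calls use FDR < 0.05
(Benjamini–Hochberg within each assay, genes and miRNAs separately, as
they come from separate count matrices) and |log2FC| > 1, with a 0.5
pseudo-count on mean CPM in the fold change.

On null simulations the built-in test is well calibrated (fraction of
P < 0.05 within 0.05 ± 0.01 and Kolmogorov–Smirnov distance from
uniformity around 0.02–0.05 at ~1000 molecules). Two caveats: the
moment-based dispersion plug-in ignores its own estimation noise, which
leaves a small mid-range dip in the null P distribution, and CPM
normalization (no TMM) makes *node* P-values sensitive to strong
composition shifts — mostly cancelled downstream by the permutation null,
but visible if the DE table is used in isolation.

## Numerical choices

* Probabilities entering any \(\Phi^{-1}\) are clipped to
  \([10^{-16}, 1-10^{-16}]\), bounding all scores at about ±8.22 and
  preventing infinities at \(D = 0\) (where the edge P-value is exactly 1).
* \(|r|\) is clipped to \(1 - 10^{-12}\) before the Fisher transform.
* \(|D| < 10^{-8}\) is treated as exactly 0: near the clipped floor the
  quantile transform is steep, and differences that small are
  floating-point noise from the order of rank operations.
* Spearman correlations use average ranks for ties; a constant vector has
  no defined correlation — it contributes \(r = 0\) and is flagged.
* The exact NB test sums its conditional distribution over a
  \([10^{-13}, 1-10^{-13}]\) quantile window rather than the full support.
* Power-law fits regress \(\log_{10}\) count on \(\log_{10}\) degree over
  non-empty bins of the raw integer histogram (no log-binning), mirroring
  the functional form \(y = a x^b\) usually reported for such networks;
  fits are skipped (flagged) with fewer than 3 distinct degrees.
  Betweenness is computed on the directed graph, unnormalized — all
  downstream comparisons are rank-based, so only consistency matters.

## The synthetic-data generator

`generator_config()` defaults describe the package's standard simulation
study: 50 TFs, 50 miRNAs, 200 genes; 200 planted loops of which 20 carry
effects; 50 matched pairs; NB dispersion 0.1 with log-normal baseline
means (median 300); planted node effects of |log2FC| = 2 (positive for TF
and gene, negative for the repressing miRNA); planted edge effects
shifting the within-loop Spearman correlation from 0 in normal to 0.8 in
tumor, induced by a Gaussian copula on latent trivariate normals mapped
through the NB quantile function; per-sample library factors uniform in
[0.75, 1.5] so library sizes stay within twofold and CPM filtering is
deterministic for fixture seeds. Calibration and uniformity checks use a
no-effect variant, with the DE-uniformity check run at ~1000 tested
molecules (60/60/1800 nodes) because the KS bound is not statistically
meaningful at a few hundred.

Two generator design choices matter for interpretation. First, the 20
effect loops live on *reserved* molecules that no other edge touches, so
planted truth is unambiguous and sensitivity/false-positive rates are well
defined; the price is that planted loops have minimal degree, so
hub/bottleneck enrichment — a real-data property — is *not* reproduced in
simulation (the statistics are exercised on separately constructed
groups). Second, background edges use degree-preferential attachment
(smoothing `pa_strength`); at curated-network scale (600/500/2600 nodes,
7000 background edges, `pa_strength = 0.3`) the degree distribution fits
a power law with \(R^2 > 0.8\), the regime reported for the real network.
The generator does not attempt batch effects, GC bias, isoform structure
or realistic miRNA target multiplicity — passing tests show the method's
statistical behavior under its own model assumptions, not robustness to
those artifacts.

With the default effect sizes the planted loops sit far above the null
(node scores near the clipping bound, edge scores around 5), so the
end-to-end recovery check (sensitivity ≥ 0.9, FPR ≤ 0.08 at
\(N_p = 10^4\)) has a wide margin; the binding checks are the null
calibrations.

## Problem sizes used by tests and scripts

Unit tests run on 10–30 node-per-role networks with 8–30 pairs and
200–3000 permutations; the acceptance-style checks use the default
configuration above with 10 000 permutations, the ~1000-molecule null for
DE uniformity, and a six-tumor cohort (20 pairs each, 2000 permutations)
for the aggregation path. The `analysis/` scripts rerun the same cohort
end to end and write their tables under `results/`.

## Known limitations

* The curated background network and the TCGA-scale expression data of
  the original study are licensed/controlled and are not bundled; the
  package reproduces the in-paper combinatorial quantities exactly and
  the statistical pipeline on synthetic data, not the study's full
  empirical tables (the loaders accept the real files when available).
* The built-in DE test is a calibrated stand-in for edgeR, not a
  reproduction of it; rankings agree closely on simulated data but exact
  P-values differ. Use the `external` method to reproduce an edgeR-based
  analysis.
* Whether the upstream permutation scheme respected molecule roles, and
  which normalization fed its Spearman correlations, is not documented;
  the defaults here (role-respecting triples, CPM) are stated choices,
  switchable where they are genuinely ambiguous.
* Correlations are computed per condition across samples (unpaired);
  the matched design is used only to balance group sizes.
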