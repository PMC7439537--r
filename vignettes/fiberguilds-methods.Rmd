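---
title: "Methods: guild detection and SCFA response prediction in fiber intervention studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: guild detection and SCFA response prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fiberguilds)
```

# The analytical problem

A fermentable dietary fiber reshapes the gut microbiota not one species at a
time but through consortia: primary degraders open complex polysaccharides,
cross-feeders consume the released fragments, and fermenters convert them to
short-chain fatty acids (SCFAs). `fiberguilds` operationalises this view for
a parallel two-arm trial (treatment fiber vs a non-fermentable control;
samples at baseline, week 1 and week 6): it detects groups of OTUs whose
treatment-induced shifts co-vary across subjects (co-abundance response
groups, CARGs), stratifies subjects by their temporal propionate
trajectory, and screens microbiota and diet features for their ability to
predict SCFA responses.

# Compositional foundation

Sequencing counts are compositional: only relative information is
interpretable. All inference therefore happens on the centered log-ratio
scale, `clr(x)_j = ln((x_j + delta) / g(x + delta))` with `g` the geometric
mean, which maps compositions to unconstrained coordinates where Euclidean
geometry (the Aitchison distance) is meaningful.

* **Pseudocount `delta`.** Zeros are replaced additively with `delta = 0.5`
  on the count scale (a half-count, the conventional minimal perturbation);
  for tables that arrive as relative abundances the same half-count is
  applied at an assumed depth (default 16,000 reads, the study's
  rarefaction target), i.e. `0.5/16000` is added. Both are configurable;
  CLR rows always sum to zero to 1e-9.
* **Filtering.** OTUs are kept when their mean relative abundance across
  *all* samples (both arms, all timepoints) is at least 0.15%. Filtered
  tables are deliberately not re-closed: they are subcompositions, and each
  downstream operation decides whether closure matters (CLR re-normalises
  internally; CARG abundances sum member OTUs so staying bounded by 1 is
  the desired semantics).
* **Rarefaction.** α-diversity (Shannon, richness) is computed on counts
  subsampled without replacement (multivariate hypergeometric) to a common
  depth; the depth defaults to the minimum library size because the study's
  fixed 16,000-read target is only meaningful for full-scale data.

# CARG detection

For each subject with both timepoints, the shift matrix holds
`clr(W6) − clr(BL)` per OTU. OTUs enter the clustering when a two-sided
one-sample Wilcoxon signed-rank test of their shifts against zero gives
unadjusted p < 0.1 — a deliberately permissive screen whose purpose is to
exclude clearly inert taxa, not to control error. Pairwise Spearman
correlation of shift vectors is converted to the distance `1 − rho` in
[0, 2] and clustered by complete linkage.

## Cutting the tree: a selection-aware null

The tree is traversed top-down; at each internal node the two child
clusters are compared by the PERMANOVA pseudo-F on the OTU-level distance
matrix, and a split is accepted at p < 0.05 (uncorrected, by design — the
split log records every test so users can audit).

The reference distribution needs care. The two children at a node were
chosen by complete linkage to be maximally separated, so the classical
label-permutation null — shuffle OTU group memberships, recompute F — is
answering the wrong question: it would declare "two clusters" even when the
node's OTUs are perfectly exchangeable, because any data-driven best split
of noise beats a random relabeling. In simulations with homogeneous
exchangeable correlation the label-permutation cut splits a single guild
into several CARGs most of the time.

We therefore test against the null hypothesis that the node is *one guild*:
exchangeable correlation at the node's own mean Spearman rho. Each Monte
Carlo replicate draws that many exchangeable shift vectors
(`x_j = sqrt(r) z + sqrt(1 − r) e_j`, rho converted to the Pearson scale by
`r = 2 sin(pi rho / 6)`), rebuilds the `1 − rho` distance matrix and its
complete-linkage tree, and scores *that* tree's root split — the null
statistic passes through the same selection step as the observed one. With
this null, planted guilds (within-guild correlation 0.8, between 0) are
recovered with adjusted Rand index 1 and homogeneous clusters stay whole at
the nominal rate. The literal label-permutation null remains available
(`shifts = NULL`) but warns.

Conventions: a 1-vs-1 node is never tested (PERMANOVA is degenerate there)
and is emitted as a single two-member CARG; singletons created by an
accepted split become their own CARG; CARGs are numbered by descending mean
member shift so CARG1 is the strongest riser. CARG relative abundance is
the sum of member OTUs' relative abundances, computed before any statistic.

## The co-response network

For every screened OTU pair the Spearman correlation of shift vectors is
permutation-tested (default 1000 permutations of one vector's subject
order) and edges are retained at |rho| ≥ 0.5 and BH q < 0.05. One numerical
choice matters: a per-pair permutation p has a floor of 1/(n_perm + 1),
and BH across several hundred pairs can essentially never clear q < 0.05 at
that resolution. Because the Spearman null distribution is
distribution-free — for a given number of subjects it is identical for
every pair — the null draws of all pairs are pooled, giving resolution of
roughly 1/(n_perm × n_pairs) under the identical permutation scheme. The
null-control property (fraction of retained edges on independent data ≤
0.05) holds under pooling and is part of the acceptance suite.

# SCFA responses and responder stratification

Total SCFA is acetate + propionate + butyrate (μmol/g wet feces); each
percentage is the share of that total; branched SCFA is isobutyrate +
isovalerate; the propionate:butyrate ratio is reported as missing when
butyrate is zero. A subject is a **W6-responder** when propionate keeps
rising late in the intervention (Δ(W6−W1) > 0) and a **W6-nonresponder**
when it falls; an exact tie is labelled indeterminate and excluded from the
two-group tests, since the sign rule does not cover it. The rule is
scale-invariant. Stool-diary AUC uses the linear trapezoid over the seven
weekly 0–4 scores (bounded in [0, 24]); interior gaps are linearly
interpolated, missing endpoints are errors because extrapolation would
fabricate data.

# The predictability screen

Each screen cell is one ordinary least squares model of a response
(typically an SCFA shift) on 1–2 predictors from one block, always adjusted
for the dose/sex covariate — dose and sex are perfectly confounded by the
design (25 g/day females, 35 g/day males), so a single binary covariate
represents both. Blocks of many features (all OTUs, diet questionnaires)
are PCA-reduced to PC1–PC3 first; loadings are returned so top contributors
can be reported.

* **Selection.** The best single predictor (adjusted R²) seeds a size-2
  search by sequential replacement: swap one member for any non-member
  while the fit improves; the best model of each size competes by adjusted
  R². On random instances (n = 30, 10 features) this agrees with exhaustive
  search over sizes 1–2 on ≥ 95% of cases (tested). Numerically collinear
  pairs (condition number > 1e8) fall through to the next-best subset.
* **Inference.** Each cell reports the overall F-test p (and per-predictor
  t-test p values, since figures in this literature show both), with BH-FDR
  across all cells of one screen invocation and significance at q < 0.05.
  Selection makes the cell p anti-conservative; the FDR family is the whole
  screen, which is the unit a reader inspects.
* **Ranking.** AICc = n ln(RSS/n) + 2k + 2k(k+1)/(n−k−1), k counting
  intercept, covariate, predictors and the residual variance. Within each
  response, relative AICc = 100 × AICc / max(AICc), so 100 marks the worst
  model and smaller is better. The ratio formula presumes positive AICc;
  if any value is non-positive the grid is first shifted so its minimum is
  1 (logged) — an invented but order-preserving rule.

# The synthetic study

The generator states one world and keeps it fixed: 31 subjects split 16/15
across arms (stratified by sex, mirroring the trial's completion numbers),
100 OTUs of which four guilds of 8/6/5/5 carry treatment effects of +2.0,
+1.2, +0.8 and −0.8 CLR units at week 6, within-guild shift correlation
0.8, between-guild 0, sequencing depth 16,000, responder fraction 0.5.
Baseline log-abundances follow a heavy-tailed log-normal spectrum with
persistent per-subject effects; counts are closed by multinomial sampling.
A log-normal subject susceptibility scalar (sigma 0.4) makes response
magnitudes individual. Propionate at week 6 is baseline plus a linear
combination of the subject's true guild shifts (betas 2, 1, 0, 0) plus
noise (sigma 2 μmol/g); the week-1 value is then placed on the side of
week 6 dictated by the subject's archetype, so the responder rule labels
are exact by construction while the planted regression link lives on the
Δ(W6−BL) scale the MLR screen uses. Responder archetypes also shape the
guild-shift trajectory (responders build up: 0.5 → 1.0 of the full effect;
nonresponders overshoot and decay: 1.0 → 0.4), echoing the two temporal
patterns seen in fiber trials.

What a green test does *not* establish: the generator draws Gaussian
shifts, so it cannot speak to heavy-tailed per-OTU outliers, compositional
artefacts beyond multinomial closure, sequencing batch effects, or diet
measurement error — its Gaussian diet block is a placeholder with realistic
correlation only. Recovery results (ARI ≥ 0.8 at 40 subjects) degrade
gracefully at the real trial's n = 15 treated subjects; that regime is
exercised in the worked example, not asserted.

# Reproducibility and numerical conventions

Every stochastic routine takes an explicit seed; pipeline artifacts carry
JSON sidecars with stage, seed, parameters and input hashes, and reruns are
byte-identical. PERMANOVA offers exact enumeration for two small groups
(used by the acceptance suite to cross-check the sampled permutation p).
Rank tests use exact distributions when ties and sample size allow,
otherwise the tie-corrected normal approximation. Dunn's pairwise z after a
Friedman omnibus is Bonferroni-multiplied over pairs and capped at 1; a
fully tied Friedman input returns p = 1 rather than NaN. Incomplete
subjects are dropped listwise per test with counts logged — no imputation
anywhere.

# Known limitations

The CARG cut tests nodes sequentially without multiplicity control (a
stated design choice; expect a ~5% false-split rate per tested node). The
exchangeable-correlation node null assumes a single common factor within a
node; strongly nested guild structure could be conservative. The
predictability screen's cell p values inherit selection bias from the
subset search; q values are comparative, not confirmatory. The pipeline is
deliberately single-threaded and desk-scale.
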