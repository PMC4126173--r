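---
title: "Classifying ILD sensitivity functions: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying ILD sensitivity functions: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ildtaxa)
```

## The problem

Neurons in the central nucleus of the inferior colliculus (ICc) encode the
azimuthal position of high-frequency sounds mainly through the interaural
level difference (ILD): the dB difference between the sound levels at the
two ears. An ILD sensitivity function samples a neuron's spike count per
stimulus at a grid of ILDs — here 13 levels from −30 to +30 dB in 5 dB
steps, with positive ILDs meaning the contralateral ear is louder. The
field traditionally sorts these curves by eye into four ideal types —
sigmoidal EI, sigmoidal IE, peaked, and insensitive — with
laboratory-specific criteria. `ildtaxa` implements an objective three-step
alternative: benchmark normalizations on synthetic prototypes, reduce
dimensionality by covariance PCA, and cluster hierarchically with
data-driven algorithm selection, yielding a taxonomy of template curves.

On the EI/IE convention used throughout: an **EI** cell is excited by the
ipsilateral ear and inhibited by the contralateral one, so its response is
largest at negative ILDs (ipsilateral ear louder) and *decreases* along the
ILD axis. An **IE** cell is the mirror image and increases with ILD. Since
ideal-type figures in the literature rarely carry numeric axes, this
orientation is stated here prominently and is also what
`classify_ild_function()` implements.

## Step 0 — synthetic data

Two generators stand in for data that cannot be distributed.

**Prototype bench** (`make_prototypes()`): nine panels of idealised curves
on a 0–100 spikes/stimulus scale — sigmoids varying amplitude, cut-off and
slope (A–C), peaked curves varying amplitude, position, and position plus
width (D–F), peak-to-sigmoid and peak-to-flat blends (G, H), and constants
(I). The qualitative feature varied per panel is fixed; the parametric
forms are package choices: logistic `m/(1+exp(-(x-x0)/s))`, Gaussian
`m*exp(-(x-x0)^2/(2w^2))`, convex blends with weights 0.25/0.5/0.75, and
variant grids `m ∈ {25,50,75,100}`, `x0 ∈ {−10,0,+10}` dB,
`s ∈ {2.5,5,10}` dB. `perturb_ild()` applies the realism perturbation in
three steps: 13 uniform draws in ±6% per curve, added after scaling by the
full-scale amplitude (so ±6 spikes for a 100-spike scale), then a monitor
step clamping at a small positive floor (0.1) so every value stays valid
for all seven normalizations, including the logarithmic one. The draw is
per level per curve (13 numbers each), not one draw per curve.

**Surrogate survey** (`simulate_survey()`): 208 cells in seven planted
groups of 61/19/36/25/21/11/35 members, each a noisy copy of one of seven
templates spanning the classes the pipeline should distinguish (IE and EI
sigmoids, a peak-to-sigmoid transition, broad/narrow peaks, an "arisen"
peak on a plateau, and a flat curve). Each cell gets a multiplicative
amplitude factor drawn uniformly from 0.85–1.15 and additive Gaussian
noise with SD equal to 6% of its amplitude (truncated below at 0.1),
mirroring the bench perturbation scale. The amplitude spread was fixed at
±15% after a pilot sweep: with much wider spreads (real ICc surveys range
over roughly 0–190 spikes/stimulus) the amplitude direction dominates the
PC-score geometry and planted groups are no longer recoverable by *any*
distance choice, which would make the generator useless as a test bed.
This is the main respect in which passing tests understate the difficulty
of real data: real surveys carry wide amplitude variation, unequal and
unknown group counts, and curves that genuinely straddle class boundaries.
Recovery of planted labels (median adjusted Rand index 1.0 over 10 seeds
at the default noise) demonstrates pipeline correctness, not expected
field performance.

## Step 1 — normalization selection

`normalize()` implements seven methods; all per-cell statistics (mean, SD,
sum, max) are taken over that cell's 13 values, and only the global-max
method references the whole matrix. Under the per-vector reading, the unit
total probability mass method (UTPM), `V = X·μ/ΣX`, reduces exactly to
`X/13`: a uniform rescaling. This is the only reading consistent with the
observations that UTPM perfectly preserves curve shapes and that
UTPM-normalized and raw data give identical PCA variance percentages; a
grand-mean variant is available behind `utpm_mu = "grand"`. The uniform
`1/13` rescaling compresses the count scale by `1 − 1/13 = 92.31%`.

`bench_evaluate()` scores each method per panel by min/max range, a
shape-preservation score, and a compression ratio. The shape score is the
Pearson correlation between raw and normalized values stacked over the
whole panel, not per curve: per-curve correlation is blind to the
destruction of *relative* amplitudes (dividing each curve by its own max
maps a 25- and a 100-spike curve onto each other), which is precisely the
failure mode that disqualifies the per-cell max, SD, z-score, mean
and log methods on multi-amplitude panels.

`select_method()` is lexicographic: (a) no failed panels and stacked shape
score ≥ 0.999 everywhere; (b) prefer methods whose reference is local to
the cell (or constant) over matrix-global ones — a single extreme cell
should not rescale every other cell, and a global reference changes
whenever the survey grows; (c) smallest worst-case normalized magnitude;
(d) lowest method id. On the default bench the survivors of (a) are the
two uniform rescalings (global max and UTPM), and (b) resolves the choice
to UTPM. A pure "smallest normalized max" criterion would instead pick the
global max, whose only advantage is the cosmetic [0, 1] range; locality
was judged the scientifically meaningful discriminator and is the
package's documented choice.

## Step 2 — dimensionality reduction

`fit_pca()` computes the 13×13 covariance of ILD-level variables across
cells with 1/N scaling, `A = (1/N) Σ (x_k − μ)(x_k − μ)ᵀ`, solves
`A·υ = λ·υ`, and projects `y = υᵀ(x − μ)`. The 1/N convention changes raw
eigenvalues but not variance percentages `100·λᵢ/Σλ`
(`variance_percentages()`, scale-invariant by construction). Columns are
centered; eigenvector signs are fixed by making each column's
largest-magnitude loading positive so that score files are reproducible.
PCA is done on the 13 level-variables (13 eigenvalues), not on the 208×208
cell-space dual.

`select_n_components()` implements four rules. Explained variance returns
the smallest k whose cumulative percentage reaches the threshold (default
95%). Kaiser's rule on covariance PCA uses λ > mean(λ) by default, because
the classical λ > 1 cutoff presumes correlation-matrix PCA and is
scale-dependent here; `kaiser_cutoff = "one"` restores the classical rule.
The scree elbow is located as the largest second difference of the
descending eigenvalue sequence — a deliberately simple, deterministic
reading of "the bending point". Horn's parallel analysis simulates 200
i.i.d. Gaussian null matrices matched in shape and per-column variance and
keeps eigenvalues above the 95th percentile of their null distribution;
replicates, percentile and seed are configurable. The pipeline retains
k = 3 by default (the explained-variance choice on the surrogate survey,
where PC1–PC3 carry ≈ 97% of the variance), converting the 208×13 matrix
into a 3×208 score matrix.

## Step 3 — cluster analysis

`pairwise_distances()` offers six condensed metrics: Euclidean,
standardized Euclidean (per-dimension unbiased variances), Minkowski
(order p), Mahalanobis (full-sample covariance; pseudo-inverse with a
warning when singular), city block, and cosine (`1 − u·v/|u||v|`). Note
that Minkowski with the default p = 2 duplicates Euclidean, and on PC
scores — whose covariance is diagonal by construction — Mahalanobis
coincides with standardized Euclidean, so the 6×4 grid contains two pairs
of identical rows; both are kept for completeness of the comparison.

`linkage()` wraps agglomerative merging for single/average/complete/Ward
linkage; Ward uses the Lance–Williams update on squared dissimilarities
with square-root heights (the legacy toolbox convention) and is applied to
any metric, including cosine, where it is a faithful-reproduction choice
rather than a variance-decomposition guarantee. `cophenetic_ccc()` scores
a tree by the correlation between original and dendrogram-implied
distances, and `ccc_grid()` evaluates all 24 combinations, breaking ties
by the documented metric-then-linkage order. In the degenerate case of
zero distance variance with a tree that reproduces the distances exactly,
the CCC is reported as 1 rather than 0/0.

`inconsistency()` computes, for every merge, the z-score of its height
against all link heights within `depth` levels below it (the merge itself
counts as level one); windows with a single link or zero spread score 0.
The default depth is 3. `cut_tree()` cuts either to an exact cluster count
k or at an inconsistency threshold, in which case clusters are the maximal
subtrees whose internal links all lie at or below the threshold. Both
modes are first-class: visually chosen cluster counts and automated
inconsistency cuts are both standard practice, so `k` and
`inconsistency_threshold` are exposed symmetrically and neither is
privileged. Merge tie-breaks
are deterministic, and cluster ids are assigned by first member
appearance, so relabeling under row permutation is exact (adjusted Rand
index 1 in the test suite).

## Taxonomy

`cluster_templates()` averages member curves into per-cluster templates;
`classify_ild_function()` assigns each template a label with relative
(scale-invariant) thresholds, applied in order:

1. **INSENSITIVE** if modulation depth `(max − min)/max` < 0.25;
2. **SIGMOID_EI / SIGMOID_IE** if at least 90% of consecutive steps share
   one direction, where steps smaller than 5% of the range count as
   consistent with either direction (so a sigmoid's flat tails do not
   break monotonicity); the direction of net change selects EI
   (decreasing) vs IE (increasing);
3. **PEAKED** if an interior maximum falls back by at least half the range
   on *both* flanks (prominence 0.5) — the half-range requirement keeps
   transitional curves with one high shoulder out of the pure peak class;
4. otherwise a **TRANSITION** label by best correlation against
   peak-to-sigmoid and peak-to-flat reference blends, with
   TRANSITION_OTHER below correlation 0.7.

All four thresholds are package-defined defaults (`class_rule_params()`),
configurable and documented here because the field's traditional
classifications are visual and carry no agreed numeric cutoffs. Mirroring
a curve along the ILD axis swaps EI and IE and preserves
the other labels; uniform positive scaling changes nothing.

## Numerical choices and degenerate inputs

Zero rows are hard errors for the methods that divide by row statistics
(named by row); the log method rejects non-positive entries unless an
explicit epsilon is supplied. A constant matrix yields an all-zero
eigenvalue PCA flagged with a warning rather than an error. Tiny negative
eigenvalues and cosine distances are clipped to zero. All randomness
(perturbation, surveys, Horn nulls) is seeded explicitly, and
`run_pipeline()` is byte-deterministic given config and seed.

## Problem sizes

The surrogate survey is the study-sized 208×13 matrix; a full pipeline run
(24-combination CCC grid included) takes well under a second. The test
suite's property checks use 5–60 item instances where brute-force oracles
(exhaustive lowest-common-merge cophenetic distances, minimax single-link
paths, double-loop Minkowski) are exact and cheap, and 10-seed recovery
sweeps at the defaults.

## Known limitations

The pipeline inherits PCA's linearity: curve families separated only by
nonlinear features may project onto overlapping score regions. CCC-based
algorithm selection favours trees that preserve global distances, which on
some geometries prefers average linkage over the cut-friendlier Ward. The
surrogate survey's equal-amplitude discipline is idealised, as discussed
above. Bartlett's sphericity test, non-linear dimension reductions (ICA,
kernel PCA, LDA) and rendered dendrogram/Voronoi figures are out of scope;
trees and scores are exported as merge tables, Newick and delimited text
for external plotting.
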