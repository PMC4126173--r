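# ildtaxa

Objective classification of neuronal **interaural level difference (ILD)
sensitivity functions** — spike-count curves sampled at 13 ILDs from −30 to
+30 dB (5 dB steps; positive = contralateral ear louder), as recorded from
auditory midbrain (ICc) neurons. Instead of sorting curves by eye into the
four classical types (sigmoidal EI, sigmoidal IE, peaked, insensitive),
`ildtaxa` derives a taxonomy of template curves from the data with a
three-step pipeline:

1. **Normalization selection.** Seven candidate normalizations (mean
   correction, global max, per-vector max, per-vector SD, log₂-mean, unit
   total probability mass, z-score) are scored on a synthetic test bench of
   nine prototypical ILD function panels perturbed by ±6% of full scale.
   The unit total probability mass (UTPM) method, `V = X·μₙ/ΣXₙ` — which
   with per-vector statistics is exactly `X/13` — wins: it is the
   shape-preserving rescaling with no cross-cell coupling.
2. **Dimensionality reduction.** Covariance PCA per
   `A = (1/N) Σ (xₖ−μ)(xₖ−μ)ᵀ`, `A·υ = λ·υ`, `y = υᵀ(x−μ)`, with variance
   percentages `100·λᵢ/Σλ` and four component-count rules (scree elbow,
   Kaiser, Horn's parallel analysis, explained variance). Three components
   suffice, turning the N×13 matrix into a 3×N score matrix.
3. **Cluster analysis.** Agglomerative clustering of the PC scores, with
   the distance metric (6 candidates) and linkage (4 candidates) chosen by
   the maximal cophenetic correlation coefficient over the 24-cell grid,
   and the dendrogram cut either at a cluster count or by the
   inconsistency coefficient (per-merge z-score of link heights within a
   depth-3 window). Cluster means become template ILD functions, each
   classified against the canonical types.

Because the original 208-cell recordings are not publicly archived, the
package ships a first-class synthetic module: nine-panel prototype
generation with the three-step ±6% perturbation, and surrogate surveys
planting the seven-cluster composition (61/19/36/25/21/11/35 of 208) so
that every stage — and the pipeline end to end — is testable.

## Worked example

```r
library(ildtaxa)

sim <- simulate_survey(seed = 1)          # 208 cells, 7 planted groups
rep <- run_pipeline(sim$dataset, normalization = "utpm", n_pc = 3, k = 7)
print(rep)
```

```
ILD taxonomy report: 208 cells, utpm normalization
  PC1-3 explain 96.836% (71.916 / 17.487 / 7.433)
  clustering: seuclidean + average, CCC = 0.88399
  k = 7 clusters, counts 61/19/36/25/21/11/35
  classes: SIGMOID_IE, SIGMOID_EI, TRANSITION_PEAK_SIGMOID, PEAKED, PEAKED, PEAKED, INSENSITIVE
  83.2% of cells in non-insensitive clusters
```

Reading the output: the first three principal components of the
UTPM-normalized (÷13) matrix carry 96.8% of the variance, so the 3×208
score matrix is a faithful reduced representation. Among the 24
metric×linkage combinations, standardized-Euclidean distance with average
linkage preserves the pairwise structure best (cophenetic correlation
0.884). Cutting the dendrogram at seven clusters recovers the planted
membership counts exactly, and averaging each cluster yields seven
templates: the four canonical ILD types plus transitional forms, with 83%
of cells in ILD-sensitive (non-insensitive) clusters. Against the planted
labels the adjusted Rand index is 1.0.

## The analysis workflow

The numbered drivers under `analysis/` run the same study as a narrative
sequence, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R             # prototypes + surrogate survey
Rscript analysis/02_normalization_bench.R  # seven-method bench, selects UTPM
Rscript analysis/03_pca.R                  # variance table, rule comparison
Rscript analysis/04_clustering.R           # CCC grid, dendrogram, k = 7 cut
Rscript analysis/05_taxonomy.R             # templates, classes, report.json
```

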