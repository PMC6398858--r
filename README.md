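# markerclust

Unsupervised subtyping of patient cohorts from blood-based biomarker
panels, with downstream stability assessment, marker profiling and
permutation-corrected brain-phenotype interaction analysis.

The scientific setting is the heterogeneity of Alzheimer's disease:
patients at the same clinical stage (cognitively normal, mild cognitive
impairment, dementia) may differ in underlying biology. The package
clusters subjects on plasma-marker profiles — a modality *not* used for
staging, so subgroups are not a rediscovery of severity — and then asks
whether brain phenotypes (e.g. regional MRI volumes) relate differently
to diagnosis inside each subgroup. It is written for biostatisticians
and imaging-genetics researchers working with tabular cohort exports
(subjects × markers, subjects × region volumes, per-subject metadata).

## The model

For markers $x_{im}$ (min-max scaled), each marker contributes $P = 15$
Gaussian kernels with adaptive bandwidths
$\epsilon_{ijm} = \sigma(\mu_{im}+\mu_{jm})/2$, where $\mu_{im}$ is the
mean distance to the $k$ nearest neighbours in marker $m$ and
$(k,\sigma)$ ranges over a 3 × 5 grid. A row-stochastic similarity
matrix $S$, kernel weights $w$ on the simplex and an orthonormal
$A \in \mathbb{R}^{N\times C}$ are learned by alternating minimisation
of

$$-\sum_q w_q \langle K_q, S\rangle
  + \gamma\,\mathrm{tr}(A^\top(I-S)A)
  + \mu \sum_q w_q \log w_q
  + \beta\lVert S\rVert_F^2,$$

whose trace term forces a $C$-block structure on $S$ (the rank
constraint on the graph Laplacian $I - S$). The learned similarity is
embedded with t-SNE (supplied as a precomputed affinity) and labelled by
k-means; summing each marker's kernel weights gives its importance.
Around the estimator: bootstrap cluster stability with optimal Jaccard
matching against random and Euclidean k-means baselines; per-cluster
marker profiles validated by one-way ANOVA; and three Mann-Whitney
comparison schemes (whole-cluster, diagnostic-group,
diagnostic-interaction) corrected by a permutation null that shuffles
cluster labels within diagnostic strata, preserving every cluster size
and cluster × diagnosis cell count exactly.

A synthetic-cohort generator plants known cluster structure, an
independent diagnosis mixture and cluster × diagnosis interaction
effects on region volumes, so every stage is testable without access to
restricted cohort data.

## Worked example

```r
library(markerclust)

coh <- generate_cohort(cohort_config(n_subjects = 150, n_markers = 60,
                                     n_informative = 10, n_regions = 10,
                                     seed = 1))
fit <- cimlr(coh$markers, clusters = 4, seed = 1)
print(fit)
#> Multi-kernel similarity clustering
#>   150 subjects, 60 markers, 900 kernels; C = 4
#>   converged after 21 iterations (objective -2.93664)
#>   cluster sizes: 44, 38, 35, 33
```

The fit recovers the planted subgroups (2 of 150 subjects misassigned):

```r
table(fitted = fit$labels, truth = coh$true_cluster)
#>       truth
#> fitted  1  2  3  4
#>      1  0  0  0 44
#>      2 38  0  0  0
#>      3  0  0 35  0
#>      4  2 31  0  0
```

Marker importances concentrate on planted informative markers
(`marker_054`, `marker_044`, `marker_056`, … are all in
`coh$informative_markers`):

```r
head(marker_importance(fit), 3)
#>       marker importance rank
#> 1 marker_054  0.7941861    1
#> 2 marker_044  0.1067289    2
#> 3 marker_056  0.0242298    3
```

Model selection scores every candidate count with two heuristics; both
prefer the planted 4:

```r
estimate_clusters(coh$markers, c_range = 2:6, seed = 1)
#> Cluster-number estimate
#>  clusters silhouette   wss curvature
#>         2     0.2112 334.5     5.831
#>         3     0.2885 303.8     4.460
#>         4     0.3497 277.7    30.228
#>         5     0.2546 281.7    -4.628
#>         6     0.2377 281.1    31.710
#>   separation set: {3, 4}; elbow set: {4, 6}
#>   suggested C = 4
```

The planted cluster × diagnosis interaction on a brain volume is
recovered by the diagnostic-interaction scheme, with the observed
Mann-Whitney p-value corrected against the 5% quantile of the
strata-preserving permutation null:

```r
phen <- normalize_volumes(coh$volumes, coh$icv)
compare_phenotype(phen[, names(coh$interaction_regions)[1]],
                  coh$true_cluster, coh$diagnosis,
                  scheme = "diagnostic_interaction",
                  cluster = coh$interaction_regions[[1]],
                  group = "MCI", n_perm = 500, seed = 2)
#> Permutation-corrected Mann-Whitney (MCI in cluster 1 vs MCI elsewhere)
#>   observed p = 0.0003863; 5% null quantile = 0.05733; SIGNIFICANT
```

`run_pipeline(dir, config = cohort_config())` chains all stages —
simulate (optional), read and preprocess the CSVs, learn the
similarity, report the cluster-count scores, bootstrap stability,
marker profiles and interaction tables — writing CSV outputs and a JSON
manifest that makes the run byte-reproducible.

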