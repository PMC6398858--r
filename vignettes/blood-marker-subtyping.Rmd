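---
title: "Subtyping patients from blood-marker profiles: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtyping patients from blood-marker profiles: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerclust)
```

## The problem

Neurodegenerative diseases such as Alzheimer's disease are heterogeneous:
patients at the same clinical stage can differ in which biological
processes drive their condition. One way to probe that heterogeneity is
to cluster patients on a modality that is *not* used to stage the
disease — here, a panel of blood (plasma) markers — and then ask whether
the resulting subgroups relate differently to disease phenotypes such as
regional brain volumes across the diagnostic stages (cognitively normal,
mild cognitive impairment, dementia). Clustering on blood markers rather
than on the imaging phenotypes avoids rediscovering disease severity:
if the subgroups were driven by stage, their diagnosis mixtures would be
skewed, which is checked, not assumed.

`markerclust` implements that full pipeline: similarity learning and
clustering, cluster-count selection, bootstrap stability, marker
profiling and permutation-corrected phenotype comparisons, together with
a synthetic-cohort generator so that every stage can be validated
against a known ground truth.

## The similarity-learning model

Let $x_{im}$ be marker $m$ of subject $i$, min-max scaled per marker.
Each marker contributes $P = 15$ Gaussian kernels with adaptive
bandwidths,

$$K_{mp}(i,j) = \frac{1}{\epsilon_{ijm}\sqrt{2\pi}}
  \exp\left(-\frac{(x_{im}-x_{jm})^2}{2\epsilon_{ijm}^2}\right),
\qquad
\epsilon_{ijm} = \sigma\,\frac{\mu_{im}+\mu_{jm}}{2},$$

where $\mu_{im}$ is the mean distance from subject $i$ to its $k$
nearest neighbours in marker $m$, and $(k,\sigma)$ ranges over a grid of
$3 \times 5$ parameterisations. The model then learns a row-stochastic
similarity matrix $S$, nonnegative kernel weights $w$ on the simplex and
an auxiliary orthonormal matrix $A \in \mathbb{R}^{N\times C}$ by
minimising

$$-\sum_{q} w_q \langle K_q, S\rangle
  + \gamma\,\mathrm{tr}\!\left(A^\top (I-S) A\right)
  + \mu \sum_q w_q \log w_q
  + \beta \lVert S\rVert_F^2 .$$

The first term aligns $S$ with the weighted kernel evidence; the trace
term pushes the graph Laplacian of $S$ towards $C$ vanishing
eigenvalues, i.e. a $C$-block (cluster) structure; the entropy term
keeps more than one kernel active; the Frobenius term bounds the scale
of $S$. The weights are the interpretable output: summing a marker's 15
kernel weights gives its importance for the clustering.

### Optimisation

`cimlr()` alternates three exact subproblem solutions from a
deterministic start ($w$ uniform, $S$ the row-normalised average
kernel):

1. **A-step** — the $C$ eigenvectors of $I - (S+S^\top)/2$ with smallest
   eigenvalues (the trace term's minimiser under $A^\top A = I$);
2. **w-step** — the closed-form entropy-regularised update
   $w_q \propto \exp(\langle K_q, S\rangle/\mu)$;
3. **S-step** — per row, the Euclidean projection of
   $\big(\sum_q w_q K_q + \gamma A A^\top\big)_i / (2\beta)$ onto the
   probability simplex.

A detail worth recording: some descriptions of this scheme write the
S-step with the pairwise squared distances
$\lVert a_i - a_j\rVert^2$ in place of the inner products
$\langle a_i, a_j\rangle$. The two differ by the row norms
$\lVert a_j \rVert^2$, which are not constant within a row, so only the
inner-product form is the exact row minimiser; we use it because exact
steps make the objective provably non-increasing across cycles, which
the test suite asserts.

Two structural choices stabilise the model on realistic inputs:

* **No self-edges.** $S_{ii}$ is fixed at zero. The diagonal of every
  Gaussian kernel is its largest entry, so with a free diagonal the
  simplex projection concentrates each row's mass on itself and the
  learned graph drifts towards the identity.
* **Per-kernel spectral normalisation.** Each kernel is rescaled as
  $D^{-1/2} K D^{-1/2}$ (its row sums) before weight learning
  (`kernel_bank(normalize = "spectral")`). The
  $1/(\epsilon\sqrt{2\pi})$ prefactor otherwise couples a kernel's
  overall magnitude to the marker's local density, and the w-step then
  ranks kernels by scale rather than by agreement with $S$. With
  `normalize = "none"` the raw density values are used, which is useful
  for inspecting the kernels themselves but degrades marker ranking.

### Defaults and their rationale

* $\sigma \in \{30, 35, 40, 45, 50\}$: the reference bandwidth
  multipliers. They give smooth, long-range kernels; combined with
  spectral normalisation this works markedly better on panels where
  only a few markers are informative than sharp unit-scale bandwidths
  (`sigma_grid("compact")`), because smooth noise-marker kernels are
  nearly uniform and average out instead of imprinting spurious
  neighbourhoods.
* $k$: neighbourhood sizes default to 10.1%, 15.1% and 16.8% of the
  cohort, the fractions that reproduce the reference sizes
  $\{30, 45, 50\}$ at $N = 298$. Absolute sizes transplanted to a small
  cohort would exceed the size of a cluster and erase local structure.
* $\gamma$ is auto-scaled as $\mathrm{mean}(Kw)\cdot N/C$ so the
  block-structure gradient matches the kernel term's at the start;
  $\beta$ defaults to $0.8\times$ the mean off-diagonal of the average
  kernel; $\mu$ (entropy) defaults to $10\times$ the standard deviation
  of the initial inner products $\langle K_q, S_0\rangle$, keeping a
  soft spread of weight over the best-matching kernels. Cluster
  recovery is insensitive to $\mu$ over two orders of magnitude; the
  choice mainly sets how sharply importances concentrate.
* Convergence: relative objective change below `tol = 1e-5`, at most
  `max_iter = 50` cycles; typical fits converge in 6–10 cycles.

### Embedding and labels

The symmetrised, sum-normalised $S$ is handed to t-SNE as the
precomputed joint-affinity distribution (never recomputed from raw
features), and k-means with 50 restarts labels the 2-D embedding. The
t-SNE optimiser is the reference recipe (gradient descent with
momentum, adaptive gains, early exaggeration) with a spectral
initialisation, so the embedding is deterministic without a seed.
`embed = FALSE` instead labels the rows of $A$ — the spectral
representation — which gives the same partitions on well-separated data
at a fraction of the cost; the bootstrap stability loop uses it.

## Choosing the number of clusters

The unweighted average kernel provably hides the planted structure on
realistic panels: with 10 informative markers out of 60, its Laplacian
shows only two or three depressed eigenvalues on four-cluster data, so
any heuristic reading that spectrum alone under-counts. Both heuristics
in `estimate_clusters()` therefore score *full fits*, one per candidate
$C$:

* **Separation**: the silhouette of each candidate's partition under a
  common dissimilarity derived from the sparsified average kernel
  (top-20 neighbours per subject, symmetrised). Over- and
  under-partitioning both cut through or merge similarity blocks and
  score lower.
* **Elbow**: the within-cluster dispersion of each candidate's
  partition in scaled marker space, scored by the discrete curvature of
  the dispersion curve.

Each heuristic reports its top-2 candidate set; the caller decides,
conventionally by the intersection. On planted 2- and 4-cluster cohorts
(150 subjects, 60 markers, 10 informative, seeds 1–10) both heuristics'
sets contained the planted count in 20 of 20 cohorts.

## Bootstrap stability

`cluster_stability()` resamples $N$ subjects with replacement, refits
the chosen method on the resample, collapses duplicates to unique-id
sets per cluster, and matches candidate to reference clusters by the
assignment maximising total Jaccard (exact bitmask dynamic programming;
ties broken deterministically). Reference clusters are first restricted
to the subjects present in the resample, so out-of-sample subjects do
not mechanically depress the index; Jaccard is computed on sets, not
multisets, because the index is defined on sets. Degenerate resamples
(fewer distinct subjects than clusters) are redrawn and counted. The
chance floor is the `"random"` method — uniform labels matched the same
way — whose mean the suite cross-checks against an independent direct
simulation; `"kmeans"` provides the classical Euclidean baseline.
`n_boot` defaults to 100.

## Marker profiles

A marker's importance is the sum of its 15 kernel weights (nonnegative,
summing to 1 across markers). Profiles are described on the min-max
scaled values: per cluster and marker, mean, SD and direction relative
to the population mean, validated by a one-way fixed-effects ANOVA
across clusters (`stats::oneway.test` with equal variances) at the
reporting threshold $p < 0.001$. No multiple-testing correction is
applied beyond that threshold, matching the pipeline this package
reproduces; the threshold is a screen on markers already selected by
the weights, not a discovery procedure.

## Phenotype interactions

Three comparison schemes probe how clusters relate to a phenotype
(typically ICV-normalised region volumes; any numeric per-subject
phenotype table works, e.g. region-averaged cortical thickness):

* `whole_cluster` — cluster members vs everyone else;
* `diagnostic_group` — one diagnosis vs another, within a cluster;
* `diagnostic_interaction` — one diagnosis inside the cluster vs the
  same diagnosis outside it: the probe for profile-by-stage
  interactions.

Groups are compared with a two-sided Mann-Whitney test (exact when
tie-free and the combined sample is below 25, tie-corrected normal
approximation with continuity correction otherwise; no mid-p). Because
clusters differ in size, the raw p-value is corrected against a
permutation null: cluster labels are shuffled *within each diagnostic
stratum* — the unique scheme preserving every cluster size and every
cluster-by-diagnosis cell count exactly — and the observed p-value is
declared significant when it falls at or below the 5th percentile
(`alpha`) of the permuted p-value distribution. Stratified shuffling is
applied uniformly in all three schemes (an unstratified option exists);
permuted replicates with an empty group record $p = 1$ and are counted.
Within the permutation loop p-values come from a rank-sum fast path that
reproduces `wilcox.test` exactly (asserted over 300 random cases),
keeping 200-phenotype calibrations inside a minute. Volumes enter rank
tests ICV-normalised but not min-max scaled; since the test is
rank-based, any positive per-column rescaling leaves its p-values
unchanged, so the order of those two normalisations is immaterial.

## The synthetic cohort generator

`generate_cohort()` emulates a baseline dementia cohort: 298 subjects,
172 plasma markers on arbitrary raw scales (random per-marker location
and scale, so min-max scaling is exercised nontrivially), diagnosis
mixture 52/161/85 (CN/MCI/AD) drawn *independently* of the planted
cluster, four clusters in proportions 82/77/61/78, and demographics
(age, sex, education, APOE4, MMSE) drawn per diagnosis from the
published baseline characteristics of the emulated cohort.

Ten informative markers carry cluster mean shifts of 3 noise-SDs with a
signed $\pm 1$ signature per cluster. Signatures are redrawn until every
pair of clusters differs on at least a third of the informative markers:
unconstrained random signatures often differ on only one or two markers,
collapsing two clusters into a near-merged pair, whereas the blood
profiles being emulated differ broadly across their top markers. Region
volumes get a per-region baseline, monotone CN→MCI→AD shrinkage on a
fixed half of regions (effect 1 noise-SD per stage; noise 5% of the
baseline volume), and on four "interaction" regions the shrinkage is
amplified 2.5-fold for one driver cluster — giving each comparison
scheme a recoverable signal. ICV is lognormal. One master seed drives
fixed sub-streams (clusters +1, diagnosis +2, markers +3, volumes +4,
demographics +5), so cohorts are byte-reproducible.

What the generator does *not* emulate — and therefore what passing
tests cannot certify about real data: correlated marker panels beyond
the planted block, longitudinal visits, missingness mechanisms, assay
batch effects, and non-Gaussian marker distributions. Results on real
cohorts additionally depend on preprocessing choices the generator
bypasses.

## Numerical and degenerate-input conventions

* Min-max scaling maps constant columns to zero with a warning (the
  formula is undefined there; zero preserves zero entries), and scaling
  parameters come from the analysis cohort itself — a single-cohort
  design with no held-out reference.
* Zero kernel bandwidths (duplicated values) borrow the smallest
  positive bandwidth of the marker; entirely constant markers produce
  uniform kernels that carry no information and lose their weight.
* KNN ties are resolved by stable subject order; mean-of-k distances
  make the choice among tied neighbours irrelevant.
* The Jaccard index of two empty sets is defined as 0 with a warning
  (reachable only through degenerate resamples).
* Cluster labels are renumbered by decreasing cluster size after
  k-means so that numbering is stable across runs.
* All randomised stages accept seeds; derived sub-seeds stay below
  $2^{31}$.

## Problem sizes used by the validation suite

The test suite and the acceptance script validate at the emulated study
scale where the claim depends on it — kernel cardinality with 172
markers, cluster recovery and ANOVA power at $298 \times 172$ — and on
reduced cohorts elsewhere: cluster-number selection on $150 \times 60$
cohorts (2- and 4-cluster, three seeds each), bootstrap stability at
$100 \times 25$ with 50 replicates, permutation calibration with 200
null phenotypes at 200 permutations, ANOVA size on 1000 null markers.
These sizes are the package's validation design; the generator accepts
arbitrary dimensions.

## Known limitations

* The optimisation is alternating minimisation of a non-convex
  objective: it finds a constrained stationary point, not a certified
  global optimum; the deterministic initialisation makes it
  reproducible.
* Dense $N \times N$ kernels put the practical ceiling near
  $N \approx 10^4$ subjects; the full 2580-kernel bank at $N = 298$
  occupies about 1.8 GB.
* Bootstrap stability refits use the spectral labelling path rather
  than t-SNE + k-means for tractability; on well-separated data the
  partitions coincide, on marginal data the reported stability refers
  to the spectral path.
* The permutation correction controls size per comparison; no
  family-wise or FDR control is applied across phenotypes, matching
  the reproduced design.
* Vertex-wise cortical-surface statistics are out of scope; surface
  measures enter only as precomputed per-region phenotypes.
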