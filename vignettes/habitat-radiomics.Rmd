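---
title: "Habitat radiomics for tumor grade: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat radiomics for tumor grade: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
models at each stage, the parameters that matter and their defaults, what the
synthetic cohort does and does not emulate, and the choices made where the
design was genuinely open.

## The pipeline in one paragraph

Tumor voxels on parenchymal-phase contrast-enhanced CT are clustered per
patient into intensity habitats with a Gaussian mixture model; the Bayesian
information criterion chooses the number of clusters over K = 2..10. Radiomic
features are extracted from the whole tumor (VOI_e) and each habitat (VOI_1 =
low density, VOI_2 = high density) after resampling to 1×1×1 mm and 25-level
discretization. Features unstable under re-delineation (intra- or
inter-observer ICC ≤ 0.75) are discarded; redundant features (Spearman
|r| > 0.9) are pruned; LASSO with stratified 5-fold cross-validation picks the
candidates; their coefficient-weighted sum is the radscore, dichotomized at
the Youden-optimal cutoff into risk groups whose overall survival is compared
by log-rank. Four classifiers (RF, LR, DT, SVM) predict the binary grade
(WHO/ISUP 1–2 = low vs 3–4 = high) from each region's candidates. Finally, a
weighted gene-coexpression analysis finds the expression module most
correlated with the radscore, its hub genes and its enriched annotation terms.

## Habitat segmentation

**Model.** Per patient, mask-voxel descriptors are modelled as a K-component
Gaussian mixture fitted by EM: random restarts (default 5) each initialized by
a k-means run from randomly sampled centres; convergence when the relative
log-likelihood change falls below `tol = 1e-6` (at most 200 iterations); full
covariances with an eigenvalue floor of `1e-6` times the mean data variance,
so near-singular components are floored rather than fatal. The log-likelihood
is asserted non-decreasing at every iteration. `BIC = p·ln n − 2·ln L` with
`p = (K−1) + Kd + Kd(d+1)/2`; the arg-min over the scanned K wins, ties going
to the smaller K. Components are relabelled by ascending mean raw intensity,
fixing the cross-patient correspondence (label 1 = low-density habitat)
without any pooled fitting.

**Voxel descriptors.** The default is raw intensity alone. Local-neighborhood
descriptors (mean and standard deviation over a radius-1 cube, available via
`descriptors = c("intensity", "local_mean", "local_sd")`) look attractive,
but neighborhoods that straddle a habitat boundary produce a third, genuinely
mixture-like "bridge" population in feature space; BIC then counts it, and
the selected K reflects geometry rather than tissue classes. With
intensity-only descriptors the fitted mixture matches the data-generating
view of a habitat — a voxel-level intensity population — and the two-habitat
structure is recovered as K = 2. This is the one place the package
deliberately departs from the obvious richer default, and it is configurable.

**Open point.** With per-patient fitting, a population-level "optimal K" is a
summary (we report the modal selected K across patients); pooled fitting or
supervoxel dictionaries are out of scope.

## Feature extraction

Images are resampled trilinearly (masks and label maps nearest-neighbour) to
`target_spacing` (default 1×1×1 mm). Within each region, intensities are
discretized to `n_gray_levels = 25` fixed-width bins over the region's own
min–max range; a constant region maps to level 1 and yields degenerate but
finite features (variance 0, entropy 0, uniformity 1, GLCM contrast 0).

The bank has 76 features per region: 17 first-order statistics (population
moments; entropy/uniformity on the 25-level histogram), 9 shape features
(voxel-count volume, face-counted surface area, sphericity
`π^(1/3)·(6V)^(2/3)/A`, maximum 3-D diameter over surface voxels, PCA axis
lengths `4·√λ`, flatness), 18 GLCM features (symmetric co-occurrence over the
13 unique distance-1 directions, features averaged over directions), 16 GLRLM
features (runs per direction, averaged) and 16 GLSZM features (zones =
26-connected equal-level components). `filters = "log"` re-extracts the
intensity and texture families from a Laplacian-of-Gaussian-filtered image
(+67 features). Larger reference banks (~1000+ features from stacked wavelet
filters) are intentionally not replicated; the families here are the
information-bearing core, and each one is verified against brute-force
pair/run/zone enumeration oracles to 1e-10 in the test suite.

Subregions below `min_subregion_voxels = 10` — or so scattered that no voxel
pair co-occurs — are flagged, carry `NA` features, and their patients are
excluded by the widener (`pivot_features`), mirroring the exclusion of
patients whose subregions cannot be segmented.

## Reproducibility filter

ICC form: two-way random effects, absolute agreement, single measurement —
ICC(2,1) = `(MSR − MSE) / (MSR + (k−1)MSE + k(MSC − MSE)/n)` from the
subject × rater ANOVA. This is the standard radiomics choice; it is declared
rather than silently assumed. The filter computes, per feature, the ICC
between the primary delineation and (a) the same observer's repeat and (b) a
second observer's delineation, on the 20-patient repeat subset (configurable),
and retains a feature only when **both** ICCs strictly exceed 0.75. Zero
between-subject variance yields a warning and a value ≤ 0, never an error:
agreement is undefined when subjects are indistinguishable, which is itself a
reason to drop a feature.

## Selection, radscore and risk groups

Normalization is linear min–max to [0, 1] with training-set bounds applied
unchanged to any later split (values outside [0, 1] are allowed — clamping
would leak test information into the geometry). The redundancy filter drops,
within any pair at Spearman |r| > 0.9, the feature with the larger mean
absolute correlation to the remainder — a deterministic victim rule (features
processed in name order) that keeps the member carrying more unique
information.

LASSO uses squared-error loss on the 0/1 grade label by default (the
cross-validation curve is then a mean-squared-error curve; `family =
"binomial"` gives logistic LASSO), a glmnet-generated log-spaced lambda path
from the all-zero boundary downward, stratified folds (`cv_folds = 5`), and
`lambda.min`. Features enter pre-scaled, so the path is run unstandardized
with a tight convergence threshold (1e-12); the solution satisfies the L1
subgradient (KKT) conditions to < 1e-6, which the acceptance tests check
against an independent residual computation.

The radscore is `intercept + Σ βᵢ·xᵢ` (the affine LASSO predictor; keeping
the intercept makes the score scale-free with respect to class prevalence).
The Youden cutoff scans midpoints of adjacent sorted unique training scores
(plus one candidate below and above the range), maximizes
`J = sens + spec − 1` under the rule high-risk ⇔ score ≥ cutoff, and breaks
ties toward the lower cutoff. The whole chain — bounds, retained set,
coefficients, cutoff — is frozen after training; prediction never refits
(asserted by serialization checksum in the tests).

## Classifiers and evaluation

Hyperparameters are pinned, documented defaults rather than tuned values: RF
500 trees; LR is unpenalized maximum-likelihood logistic regression (`glm`) —
the natural R formulation, preferred here over an L2-penalized import from
other ecosystems; DT is an rpart gini tree with default pruning; SVM uses an
RBF kernel at cost 1 with decision values as ranking scores. Positive class =
high grade throughout; precision/recall/F1 are reported for the positive
class (`average = "weighted"` available). AUC is trapezoidal over all score
thresholds and equals Mann–Whitney pair counting exactly; the split is
stratified 7:3 with test size `ceiling(0.3·n)` allocated to strata by largest
remainder (186 → 130/56, grade proportions preserved within one patient).

## Survival analysis

Kaplan–Meier product-limit curves and the log-rank test (hypergeometric
variance, 1 df) compare risk groups formed by applying the training-derived
cutoff to each split. Clinical-table comparisons follow the conventional
gates: chi-square without continuity correction for categorical variables,
Fisher's exact test when any expected cell is below 5; Student's t when both
groups pass Shapiro normality at α = 0.05, Mann–Whitney U (midranks, normal
approximation) otherwise. The Shapiro gate and the no-continuity-correction
choice are documented conventions, not claims of optimality.

## Coexpression analysis

Unsigned adjacency `|cor|^β`; the soft threshold is the smallest β in 1..20
whose connectivity distribution fits a power law with R² ≥ 0.8 (log-binned
frequency vs mean connectivity over ~10 bins), falling back to the max-R² β —
a signed network is a configuration away but the unsigned default matches the
common protocol when the interesting correlation's sign is unknown. TOM
follows `TOM_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i,k_j) + 1 − a_ij)`.

Modules come from average-linkage clustering of `1 − TOM`, cutting at the
height (scanned over the midpoints between consecutive merge heights — a
linear height grid misses the narrow band where modules resolve, because TOM
dissimilarities concentrate near 1) that maximizes the number of clusters of
at least `min_module_size = 100` genes, ties toward the lower height.
Undersized clusters are grey; surviving modules take standard color aliases
in descending size order. This documented height scan replaces the reference
dynamic tree-cut heuristics deliberately: it is reproducible in a few lines
and recovers planted modules at desk scale (adjusted Rand index ≥ 0.8 in the
acceptance tests).

Module eigengenes are unit-norm first principal components of the
standardized module expression, sign-oriented toward positive mean member
correlation. Module–trait p-values use the exact t transform (df n−2); the
selected module minimizes p against the primary trait (radscore), ties to
larger |r|. Hub genes are the two highest-degree genes in the module-induced
subgraph of a user-supplied interaction edge list, falling back (with a
warning) to intramodular connectivity from the adjacency; ties break
lexicographically. Enrichment is a one-sided hypergeometric upper tail per
annotation term with Benjamini–Hochberg correction, reporting the top five
terms with p < 0.05 — generic over any term→gene table; no GO/KEGG catalogs
are bundled and no online database is queried.

## The synthetic cohort

`cohort_spec()` defines the study conditions; `generate_cohort()` realizes
them under one master seed fanned into per-patient sub-seeds, so any subset
is bit-reproducible.

* **Imaging.** Ellipsoidal tumors (semi-axes 6–10 mm) on a 28³ grid at 1 mm
  spacing. Habitat geometry is a smoothed Gaussian field thresholded at the
  low-density fraction (default 0.5/0.5) — spatially contiguous blobs, not
  i.i.d. voxel labels, so texture features see structure. Habitat intensities
  are Gaussian (means 80/160, sd 12, in CT-like units) plus a spatially
  correlated texture field (sd 4, smoothing 1.2 voxels). High-grade patients
  get `grade_effect = 6` added to the low-density habitat's texture sd — the
  planted grade signal, expressed as local variance/granularity rather than a
  mean shift. Background parenchyma is N(95, 18): enhancing tissue *between*
  the habitat means, so delineation error blends into the tumor mixture
  instead of forming a spurious third component.
* **Heterogeneity.** Per-patient random effects (intensity-mean jitter sd 6,
  lognormal sd and texture multipliers, logit jitter of the habitat fraction)
  make the cohort heterogeneous. This matters for the ICC stage: agreement is
  measured relative to between-subject variance, and a cohort of clones would
  make every feature look irreproducible.
* **Re-delineation.** Repeat masks flip each boundary voxel with probability
  `repeat_perturb = 0.15` (random dilation/erosion) — a morphological
  perturbation standing in for human re-contouring.
* **Survival.** Exponential event times with hazard
  `0.02·exp(0.8·latent_risk)` per month and uniform censoring on (0, 60)
  months; the latent risk is grade plus noise. Exponential + uniform
  censoring keeps every quantile analytically checkable.
* **Expression.** 600 genes × n samples; three planted modules of 150/120/100
  genes (each ≥ the 100-gene module minimum), member genes =
  0.8·factor + N(0, 1). The first module's factor is constructed to have
  *exactly* the target sample correlation with the supplied trait (default
  −0.31, the sign mirroring an inverse radscore–module association); other
  factors are orthogonalized against the trait. Background genes are pure
  noise and should end up grey.

**What passing tests do and do not show.** The generator validates the
machinery: that BIC recovers a planted two-population mixture, that the
selection chain finds planted discriminative features, that module detection
recovers planted coexpression, that risk groups separate survival when the
hazard truly depends on risk. It does not emulate CT physics, scanner noise,
partial-volume effects, real biological covariance structure, or cohort
idiosyncrasies — so agreement here says the code is correct, not that any
particular real-data effect size will be reproduced.

## Problem sizes and numerical choices

The test suite and acceptance checks use deliberately small instances chosen
as representative rather than imposing: 20 default-spec tumors for the K
recovery property; 50 random 6×6×6 regions for the texture oracles (tol
1e-10); 100 random 6×2 tables for the ICC oracle (tol 1e-10); 25 repeats of a
planted 3-of-30 LASSO recovery at n = 150; enumeration-oracle equality at
1e-12 for AUC, Youden, log-rank, Fisher and hypergeometric tails; 10 seeds of
3-module expression at n = 100 samples for coexpression recovery; and a
20-patient, K ∈ {2,3}, 3-fold pipeline configuration for the end-to-end
determinism check (two runs must produce identical output checksums).
Degenerate inputs are pinned throughout: constant regions, single-voxel
masks, single-class labels, zero-variance genes, all-grey clusterings, empty
edge lists — each either returns the documented degenerate value or fails
with a named error.

## Known limitations

* Per-patient GMM on intensity alone cannot represent habitats defined purely
  by texture at equal density; the descriptor set is configurable but the
  K-selection behaviour was only characterized for the default.
* The feature bank is a curated core, not a full reference-platform
  enumeration; absolute feature values are not expected to match any other
  implementation's conventions (e.g. different direction weighting or
  histogram edges), only the definitions tested by the oracles.
* The height-scan module cut optimizes the count of large modules; it will
  merge nested sub-modules a dynamic branch-shape cut might split.
* The Shapiro gate for t vs Mann–Whitney is a convention; near the α = 0.05
  boundary the chosen test can flip between similar datasets.
* Min–max normalization is sensitive to single-patient outliers in the
  training split.
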