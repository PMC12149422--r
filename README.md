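# habitomics

Habitat (subregion) radiomics and radiogenomics for predicting the
histological grade of clear cell renal cell carcinoma (ccRCC) from
contrast-enhanced CT.

Whole-tumor ("VOI_e") radiomics averages over biologically distinct tissue
compartments. Habitat radiomics instead partitions the tumor into internally
homogeneous voxel populations and quantifies each one separately: in ccRCC,
a low-density subregion (VOI_1) and a high-density subregion (VOI_2), with the
texture of the low-density habitat carrying most of the grade signal. This
package implements that analysis end to end for researchers in quantitative
imaging and radiogenomics:

1. **Habitat segmentation** — per-patient Gaussian mixture model on tumor
   voxels, the number of clusters K selected by the Bayesian information
   criterion, `BIC = p·ln n − 2·ln L`, scanned over K = 2..10; clusters are
   relabelled by ascending mean intensity so that label 1 is always the
   low-density habitat.
2. **Feature extraction** — volumes resampled to 1×1×1 mm, intensities
   discretized to 25 gray levels, then 76 IBSI-style features per region
   (first-order, shape, GLCM, GLRLM, GLSZM; an optional Laplacian-of-Gaussian
   filter bank adds 67 more).
3. **Reproducibility filter** — intra- and inter-observer ICC(2,1) from
   repeat delineations; a feature is kept only if **both** ICCs exceed 0.75.
4. **Selection and radscore** — min–max normalization to [0, 1] with
   training-set bounds, Spearman redundancy pruning (|r| > 0.9), LASSO with
   stratified 5-fold cross-validation (lambda minimizing mean CV loss), a
   linear radscore `intercept + Σ βᵢ·xᵢ`, and the Youden-index cutoff
   (maximizing sensitivity + specificity − 1) dichotomizing patients into
   high/low risk.
5. **Grade classifiers** — random forest, logistic regression, decision tree
   and RBF-SVM on the candidate features of each region, evaluated by
   accuracy, precision, recall, F1 and trapezoidal ROC/AUC on a stratified
   7:3 train/test split (186 patients split 130/56).
6. **Survival** — Kaplan–Meier curves and the log-rank test between radscore
   risk groups; chi-square/Fisher and t/Mann–Whitney comparisons for the
   clinical table.
7. **Radiogenomics** — weighted coexpression network (soft threshold by
   scale-free fit, topological overlap matrix, average-linkage modules of
   ≥ 100 genes), module eigengene–radscore correlation, top-2 hub genes, and
   hypergeometric term enrichment with BH correction.

Every stage is driven by a synthetic-cohort generator that plants the
structure the analysis assumes (two intensity habitats, a grade-linked
texture effect, risk-linked exponential survival, coexpression modules with a
trait-linked factor), so the full pipeline runs and is tested without any
external imaging or expression data.

## Worked example

```r
library(habitomics)

spec   <- cohort_spec(n_patients = 30, seed = 11)
cohort <- generate_cohort(spec)
cohort
#> Synthetic cohort: 30 patients ( 14 high-grade ), 14 deaths

segment_habitats(cohort$volumes[[1]], k_range = 2:10, seed = 1)
#> Habitat map: K = 2 selected by BIC over K in { 2, 3, 4, 5, 6, 7, 8, 9, 10 }
#>   subregion sizes: 1156, 1481 | mean intensities: 78.9, 155.7

cfg <- pipeline_config(out_dir = "habitomics_demo", spec = spec,
                       icc_n_patients = 10, cv_folds = 3, seed = 11)
run <- run_pipeline(cfg)

run$selection$radscore_model
#> Radscore model: 1 features selected by LASSO (lambda = 0.0195 )
#>   VOI1_glcm_correlation                    +1.2510
#>   intercept -0.0773 | Youden cutoff 0.4734 (sens 1.00, spec 1.00)

subset(run$metrics, region == "VOI1" & split == "internal_test")
#>  region model         split accuracy precision recall f1 auc
#>    VOI1    RF internal_test    1.000         1      1  1   1
#>    VOI1    LR internal_test    1.000         1      1  1   1
#>    VOI1    DT internal_test    1.000         1      1  1   1
#>    VOI1   SVM internal_test    0.556         0      0  0   1

run$coexpression$assignment
#> Coexpression modules: blue (115), brown (102), grey (234), turquoise (149)
#> Selected module: turquoise (r = -0.328, p = 7.64e-02 vs primary trait)
```

Reading the output: BIC selected two habitats for the example tumor; the
low-density subregion (VOI_1, mean intensity 78.9) is separated from the
high-density one (155.7). The training-only selection chain reduced the VOI_1
bank to one candidate (a GLCM correlation feature), whose radscore separates
grades perfectly at this small, strongly planted simulation scale — held-out
AUC saturates at 1 (the SVM's thresholded class labels collapse to one class
at n = 21 training patients while its ranking stays perfect, a familiar
small-sample artifact). The planted coexpression module (149 genes,
"turquoise") is recovered and shows the expected negative eigengene–radscore
correlation near −0.31. The run directory contains every stage's CSV/JSON
output plus `manifest.json` with per-file MD5 checksums; re-running the same
config reproduces the checksums exactly.

A command-line wrapper for full runs ships in
`inst/scripts/habitomics-run.R`:

```sh
Rscript inst/scripts/habitomics-run.R --n 186 --seed 7 --out run_dir
```

## Limitations

The synthetic cohort is a desk-scale phantom: Gaussian intensity mixtures
with smoothed-field habitat geometry, not CT physics. Cohort-specific results
from real ccRCC data (particular AUC values, radscore cutoffs, named modules
or hub genes) are outside what the simulation can or tries to reproduce; see
the methods vignette (`vignettes/habitat-radiomics.Rmd`) for the model,
parameter meanings and design decisions.
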