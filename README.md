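# otoshape

Wavelet-based otolith contour shape analysis for fish population
discrimination.

Otoliths (fish ear stones) accrete throughout life, and their outline
records both heredity and environment.  In anadromous fish the outline
differs among natal rivers, so contour shape can assign individuals to
rivers, test population structure, and expose shape morphotypes —
misclassification rates then serve as a proxy for straying.  `otoshape`
implements the complete analysis chain used in wavelet-based otolith
stock-identification studies, for ecologists and fisheries scientists
working from binary otolith silhouettes or digitised outline polygons.

## Method

For each otolith:

1. **Signature.** The outline (left-otolith convention, sulcus up,
   rostrum right; right otoliths are mirrored) is resampled to 512 points
   at equal arc spacing.  The signature is the centroid distance
   r(s) divided by its mean, rotated so index 1 is the farthest point
   from the centroid.
2. **Wavelet features.** The signature is decomposed with the undecimated
   *à trous* transform and the B3-spline kernel (1, 4, 6, 4, 1)/16 under
   periodic boundaries, giving nine detail scales d₁..d₉ plus a smooth
   with exact additivity x = smooth + Σ dⱼ.  Scale 4 is the per-otolith
   feature vector.
3. **Morphospace.** Covariance PCA of the features; components retained
   by the broken-stick rule (λᵢ/Σλ > bᵢ = (1/p)Σⱼ₌ᵢ..ₚ 1/j, leading run);
   Pearson screening of score–size correlations; allometric correction by
   pooled within-group slopes, y′ = y − b(x − x̄), which removes the
   shared size trend while preserving group differences.
4. **Inference.** One-way PERMANOVA on Manhattan distances
   (pseudo-F = (SSₐ/(a−1))/(SS_w/(N−a)), permutation p with 9,999
   relabellings by default; Bonferroni-corrected pairwise tests), and a
   SMOTE-balanced single-hidden-layer perceptron evaluated by
   leave-one-out cross-validation, reported as a confusion matrix with
   overall accuracy, Cohen's kappa and per-class accuracy.
5. **Morphotypes.** Ward ("ward.D") clustering of the adjusted scores,
   tree cutting at k morphotypes, composition tables by population and by
   rostrum/antirostrum class, silhouette profiles over k.

A synthetic otolith generator (base ellipse plus von-Mises angular bumps
for rostrum, notch, antirostrum and posterior angularity) plants known
population structure — including the 11-river, 1,141-fish American shad
design with its latitudinal upper/lower-rostrum gradient — so the whole
pipeline is testable without access to specimens.

## Worked example

```r
library(otoshape)
specs <- list(
  population_spec("N", 20, shape_params(rostrum_elevation =  0.3),
                  between_individual_sd = 0.03, seed = 1),
  population_spec("S", 20, shape_params(rostrum_elevation = -0.3),
                  between_individual_sd = 0.03, seed = 2))
ds  <- generate_metapopulation(specs, seed = 1)
fit <- otoshape(ds, otoshape_control(n_perm = 999, k_morphotypes = 2,
                                     min_retained = 1, silhouette_range = 2:4,
                                     classifier = classifier_config(
                                       hidden_units_grid = c(3, 6),
                                       repeats = 5, inner_folds = 3)),
                seed = 1)
summary(fit)
```

```
otoshape fit: 40 otoliths, 2 populations
  retained components (broken stick): 2 (91.4% of variance)
  PERMANOVA: pseudo-F = 63.496, p = 0.001
  LOOCV: mean accuracy 1.000, mean kappa 1.000
  morphotypes: k = 2

Variance fractions of retained components:
[1] 0.7715 0.1420

Confusion matrix (mean over repeats; rows = predictions):
          reference
prediction  N  S
         N 20  0
         S  0 20

accuracy 1.0000, kappa 1.0000, n = 40
```

Two populations differing only in rostrum elevation (an "upper" vs
"lower" rostrum, ±0.3 rad) separate completely: the broken stick keeps
two components carrying 91% of the wavelet-feature variance, PERMANOVA
rejects homogeneity at the smallest attainable p (0.001 with 999
permutations), and LOOCV classifies all 40 otoliths correctly.  With
identical populations the same pipeline returns chance-level accuracy —
see `tests/testthat/test-acceptance.R`.

The package also ships the published leave-one-out confusion matrix of an
11-river American shad survey (1,141 fish) as a worked example for the
metric definitions:

```r
confusion_metrics(shad_confusion_matrix())
#> accuracy 0.9089, kappa 0.8945, n = 1141
#> per-class accuracy (%):
#>    STL    MER    HUD    DEL   RAPP    YOR    JAM    NEU     CF    SAN    STJ
#>  84.71  92.45  93.88 100.00  95.35 100.00 100.00  95.51  90.83  92.21  82.13
```

## Package layout

* `R/synthetic.R` — shape model, population specs, metapopulation and
  rasterisation (`generate_contour()`, `generate_population()`,
  `generate_metapopulation()`, `render_binary_image()`).
* `R/contour.R` — extraction, orientation, resampling, signature
  (`extract_contour()`, `canonical_orientation()`,
  `resample_equidistant()`, `shape_signature()`, `otolith_length()`).
* `R/wavelet.R` — `atrous_decompose()`, `select_scale()`,
  `mean_contour_decomposition()`.
* `R/morphospace.R` — `pca_covariance()`, `broken_stick_retain()`,
  `size_correlation()`, `allometric_residuals()`.
* `R/permanova.R` — `manhattan_distances()`, `permanova_global()`,
  `permanova_pairwise()`.
* `R/classify.R` — `standardize_fit_apply()`, `smote_oversample()`,
  `train_mlp()`, `loocv_classify()`, `confusion_metrics()`,
  `pc_importance()`.
* `R/morphotypes.R` — `ward_cluster()`, `cut_tree()`,
  `morphotype_composition()`, `silhouette_profile()`.
* `R/pipeline.R`, `R/io.R` — the `otoshape()` fit with
  print/summary/plot/predict methods, manifests and CSV/JSON formats.

The methods vignette (`vignettes/otolith-shape-analysis.Rmd`) documents
the model, parameter choices, numerical conventions and limitations.
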