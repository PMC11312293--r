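# msiband

Offline mutual-information band selection for multispectral image cubes,
plus the texture-based tissue-grading pipeline the selection serves.

## The problem

Multispectral microscopy of stained biopsy slides produces cubes of tens
of co-registered spectral bands (visible and near-infrared).  Adjacent
bands are often nearly redundant: they inflate feature-extraction and
classification time and can dilute a classifier's discrimination.
`msiband` identifies the informative band subset **once, offline**, from
a sample of images, so that all later images from the same acquisition
setup can be processed on the reduced cube.

## The method

For adjacent bands $A, B$ the package estimates, from quantized intensity
histograms,

$$MI(A,B) = H(A) + H(B) - H(A,B),$$

in bits.  High adjacent MI flags redundancy.  Selection scans the
adjacent-pair MI sequence: pairs at or above a threshold accrete maximal
*redundancy runs* of consecutive bands, each run keeps only its
maximum-entropy member, and bands in no run are kept.  The per-image
selections from a class-stratified sample of ~25 images are combined by
strict-majority vote into the final retained set.  Lowering the threshold
monotonically shrinks the retained set.

Downstream, the package provides LBP, uniform rotation-invariant LBP,
LPQ and rotation-invariant LPQ descriptors (normalized per-band
histograms, concatenated across retained bands) and an RBF-SVM harness
with repeated stratified 70/30 holdout, per-shuffle nested `(cost,
gamma)` grid search, and group-aware splitting that keeps patches of one
slide in one fold.  A synthetic-cube generator with planted redundancy
and class-specific micro-texture makes every stage testable without the
original (request-only) histopathology data.

## Worked example

```r
library(msiband)

# synthetic dataset: 4 tissue grades x 10 cubes, 64x64, 6 base bands and
# two planted near-duplicate bands (after bands 1 and 4)
ds <- generate_dataset(synth_config(
  n_images_per_class = 10, n_base_bands = 6, height = 64, width = 64,
  duplicate_groups = list(list(source = 1, n_copies = 1, sd = 0.01),
                          list(source = 4, n_copies = 1, sd = 0.01)),
  band_corr = 0.5, seed = 42))

# adjacent-band MI profile of one cube (32-bin quantization for 64x64 planes)
adjacent_mi_profile(ds$cubes[[1]], histogram_config(32))
#> mi_profile: 7 adjacent-band pairs (32 bins, bits)
#>   MI range [0.139, 3.400], mean 1.089

# offline consensus selection at a 2-bit threshold
sel <- select_bands_consensus(ds$cubes,
  selection_config(mi_threshold = 2, n_sample_images = 25, seed = 7),
  histogram_config(32))
sel
#> band_selection: 6 of 8 bands retained (MI threshold 2 bits)
#>   retained: 0 2 3 4 6 7
#>   consensus over 25 sample image(s), majority fraction 0.50

# rotation-invariant LPQ features on the retained bands, then the
# repeated-holdout SVM evaluation
fx <- feature_matrix(ds$cubes, texture_config("rlpq", window = 7),
                     retained = sel$retained)
holdout_evaluate(fx, config = classifier_config(
  c_grid = 2^seq(-5, 5, 2), g_grid = 2^seq(-5, 5, 2),
  n_shuffles = 10, seed = 1))
#> evaluation_report: 10 shuffle(s), 28 train / 12 test per shuffle
#>   mean accuracy: 99.17% (range 91.67 - 100.00)
#>   modal hyperparameters: cost 0.03125, gamma 0.03125
#>   classes: adenoma, carcinoma, hyperplastic, normal
```

The MI profile shows two pairs far above the rest (the planted
duplicates, ~3.4 bits vs ≤ 1.1 for ordinary neighbours); the consensus
drops exactly one band from each duplicate pair (8 → 6 bands, here the
perturbed copies 1 and 5 lose to their higher-entropy partners), and the
reduced cube still grades the four classes at 99% mean holdout accuracy.

The two experiment wrappers mirror the standard study designs:
`run_compare()` (multispectral vs RGB accuracy per descriptor) and
`run_sweep()` (threshold × LPQ-window accuracy grid with a no-selection
baseline column).  A thin CLI over the same functions lives in
`inst/cli/msiband.R` (subcommands `simulate`, `select-bands`,
`extract-features`, `classify`, `run-compare`, `run-sweep`).

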