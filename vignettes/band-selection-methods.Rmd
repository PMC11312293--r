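---
title: "Mutual-information band selection for multispectral texture classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutual-information band selection for multispectral texture classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msiband)
```

## The problem

Multispectral microscopy of stained biopsy slides yields image cubes of
tens of co-registered bands spanning visible and near-infrared
wavelengths.  Bands acquired at neighbouring wavelengths are often close
to copies of one another: processing all of them multiplies feature
extraction and classification cost without adding information, and
redundant inputs can even degrade a classifier.  `msiband` implements an
offline band-selection procedure driven by the mutual information (MI)
between adjacent bands, together with the texture-classification pipeline
the selection serves (LBP/LPQ descriptor families and a repeated-holdout
RBF-SVM harness).

## The selection model

For two bands $A$ and $B$, quantized to discrete intensity levels, the
package estimates

$$MI(A,B) = H(A) + H(B) - H(A,B)
          = \sum_{a,b} p_{AB}(a,b)\,
            \log_2 \frac{p_{AB}(a,b)}{p_A(a)\,p_B(b)},$$

with all entropies taken from (joint) histograms of the quantized planes.
Both forms are implemented — the entropy form is the estimator, the
double-sum form is kept in the test suite as an independent oracle; they
agree to $10^{-9}$ bits.

Selection scans the adjacent-pair MI sequence of a cube left to right.
Pairs at or above the MI threshold accrete maximal *redundancy runs* of
consecutive bands; each run contributes exactly one surviving band, the
one with maximal entropy (the highest-information member), ties breaking
toward the lower index.  Bands in no run are retained.  Because lowering
the threshold only grows runs, the number of retained bands is
non-increasing as the threshold decreases.

One image does not decide: the procedure runs on a class-stratified,
seeded sample of about 25 images and a band is kept only if it survives
in strictly more than half of them (both the sample size and the
majority fraction are configurable).  The vote matrix is retained in the
result for audit.  The consensus is meant to be computed once per
acquisition setup and reused for every later image.

### Design choices in the selection

The redundancy semantics of a *chain* of high-MI pairs is genuinely
open: a pair above threshold marks two bands as mutually redundant, but
when pairs (i, i+1) and (i+1, i+2) are both above threshold there are
several defensible readings.  We collapse maximal consecutive runs to a
single max-entropy representative, which is the only reading we found
consistent with both "keep the highest-entropy band among redundant
neighbours" and the monotone decrease of band counts with the threshold.
A consequence (flagged, not hidden): a band dropped mid-run can never be
rescued by a later low-MI pair.

The entropy used for tie-breaking is the per-image band entropy under
the same quantization as the MI values — introducing a second estimator
for the same quantity would only create inconsistencies.

## Quantization and its bias

Neither the bin count nor the logarithm base is canonical; the package
defaults to **256 bins per band and base-2 logarithms** (bits), the
dominant convention in MI-based image registration.  Every band is
min-max rescaled to the bin range independently, so the estimator is
invariant to per-band affine intensity changes; a constant band occupies
one bin and has zero entropy.

Histogram MI is biased upward when the joint histogram is sparse: with
$K$ bins per band, the bias is roughly $(K-1)^2 / (2 N \ln 2)$ bits for
$N$ pixels, and catastrophically larger once $K^2 \gg N$ (with 256 bins
a 64×64 plane pair shows several bits of spurious MI between independent
bands).  The 256-bin default therefore presumes full-frame images
(320×256 and larger).  All desk-scale experiments and tests in this
package run on 64×64 synthetic cubes and use **32 bins**
($K^2 = 1024 \ll 4096 = N$, residual bias ≈ 0.17 bits), and the
independence checks at 128×128 use 32 bins for the same reason.  This is
a property of the estimator, not of the selection algorithm, and is the
reason `histogram_config()` is an explicit argument everywhere.

## Texture descriptors

Four descriptors are provided, all as normalized per-band histograms:

* **LBP** (P = 8, R = 1): 8-neighbour threshold code per pixel, 256
  bins.  Ties (neighbour equal to centre) count as 1.  The ring is read
  clockwise from the top-left neighbour; the histogram is global (no
  block/cell partition by default, since no particular cell geometry is
  canonical and global histograms keep the feature length at 256 per
  band).
* **Uniform rotation-invariant LBP**: codes with at most two circular
  bit transitions map to their popcount, the rest to a shared bin — 10
  bins, exactly invariant to 90°/180°/270° rotations.
* **LPQ**: sign-quantized phase of a windowed Fourier transform at four
  low frequencies ($a = 1/\text{window}$, uniform window), 256 bins.
  The DC term is excluded and only signs are kept, so the descriptor is
  exactly invariant to gain and offset changes.  Coefficients are
  whitened by default (isotropic exponential correlation model,
  $\rho = 0.9$, the reference default) before quantization.  Pixels
  whose window does not fit in the plane are excluded — this makes the
  valid region explicit and lets the direct-DFT oracle in the tests
  reproduce codes exactly.
* **Rotation-invariant LPQ**: a per-pixel characteristic orientation is
  first estimated from the signs of the imaginary parts of STFT
  coefficients on a circle of 36 frequencies; the LPQ code is then
  extracted in the rotated frame (window resampled bilinearly).  With
  the orientation forced to zero it reduces bit-exactly to plain LPQ.
  Rotation invariance is approximate (orientation estimation and
  resampling both discretize), which is why the tests assert rotation
  *robustness* — rotated copies of a texture must be closer in
  chi-square distance than different textures — rather than exactness.

One numerical guard is worth recording: on degenerate neighbourhoods
(e.g. constant planes) every STFT coefficient is an exact zero computed
as a sum of cancelling terms, and its floating-point residue has an
arbitrary sign that varies with pixel position.  Coefficients below
$10^{-9}$ of the window's intensity mass are therefore snapped to zero
before sign quantization, making the degenerate code deterministic
(a constant plane yields a single code) without affecting any
non-degenerate coefficient.

Cube descriptors fuse per-band histograms by concatenation (default) in
band order.  Concatenation keeps band provenance — selection visibly
shrinks the feature vector, and the descriptor of a band subset is
exactly a column slice of the full descriptor, which the sweep harness
exploits to avoid recomputing features per threshold.  A `mean` fusion
is available where a fixed-length descriptor is needed.  Whether one
fused descriptor per cube or per-band classification is the better
protocol is not settled; fusion is the package's choice and is
configurable.

## Classification harness

An RBF-kernel C-SVM, evaluated by repeated stratified holdout: for each
of `n_shuffles` (default 50) shuffles, a 70/30 split, per-feature
min-max scaling fit on the training fold, a `(cost, gamma)` grid search
(powers of two, $2^{-5}..2^{5}$ by default) by stratified 5-fold
cross-validation *inside the training fold*, a final fit and a test-fold
accuracy.  The mean over shuffles is the reported accuracy.  Ties in the
grid resolve toward the smallest cost, then the smallest gamma, so the
search is deterministic.

Two protocol decisions deserve justification:

* **Group-aware splits.**  The 4-patch dataset enlargement puts four
  patches of the same slide into the dataset; letting them straddle the
  train/test boundary leaks slide-level texture and inflates accuracy.
  By default patches sharing a slide (the `source_id` minus its patch
  suffix) stay in one fold; `group_aware = FALSE` reproduces naive
  splitting.
* **Nested vs global search.**  Protocols that report a single
  `(c, g)` pair per method imply one global grid search; that search
  sees data later used for testing.  The default is the leak-free nested
  search; `search = "global"` provides the compatibility mode.

Internally the harness precomputes the pairwise squared-distance matrix
of the scaled features once per fit set and evaluates every grid point
as an elementwise `exp` of it (kernlab's precomputed-kernel interface).
This is exactly the RBF SVM — just without recomputing kernels per grid
point — and it is what keeps a 6×6 grid × 5 folds × 10 shuffles
evaluation in the tens of seconds.

## The synthetic generator

Because the study-scale histopathology cubes are not redistributable,
every stage is validated on synthetic cubes whose relevant statistics
are controlled:

* **Class texture**: an oriented sinusoid (orientation, frequency,
  noise level per class recipe) plus Gaussian pixel noise.  The default
  four "grades" differ in both orientation (0°/45°/90°/135°) and
  frequency (0.08–0.35 cycles/px), so they remain separable under
  rotation-invariant descriptors.  Each band gets an independent random
  phase, so bands share texture statistics but not pixel values.
* **Band correlation**: the per-band noise fields follow an AR(1) chain
  with coefficient $\rho$ (`band_corr`); mean adjacent MI rises
  monotonically with $\rho$, emulating the smoothly correlated profiles
  of real acquisitions ($\rho = 0.9$ default).
* **Known redundancy**: duplicate bands are a source band plus
  perturbation of chosen sd, inserted immediately after their source
  (MI is computed between adjacent bands, so redundancy must be
  adjacent to be discoverable).  The returned ground-truth map drives
  recovery tests.  At 32-bin quantization on 64×64 planes, perturbation
  sds of 0.005/0.02/0.035/0.07 put the duplicate-pair MI at roughly
  3.8/3.1/2.6/1.8 bits, which is how the threshold-ladder experiments
  arrange counts that genuinely change across thresholds in the
  2.5–3.25 bit range.

What the generator does *not* emulate: stain variability, optical blur
differences between bands, spatial nonstationarity, class-dependent
band signatures (class signal lives in texture, not in spectra), or
inter-patch correlation within a slide beyond sharing a recipe.
Passing tests on this generator show the algorithmic contracts hold —
recovery of planted redundancy, monotonicity, leak-free evaluation —
not that any particular accuracy will transfer to real tissue.

## Problem sizes used in validation

The bundled experiments are deliberately desk-scale: 64×64-pixel cubes,
9–12 base bands with 3–4 planted duplicate groups, 4 classes × 40 cubes,
rotation-invariant LPQ at window 7, 10 holdout shuffles, and a
$2^{-5}..2^{5}$ (step 4×) hyperparameter grid.  On these conditions the
pipeline reaches ≈ 97% mean holdout accuracy with all 12 bands, slightly
higher on the 9 consensus-selected bands, and ≈ 25% with permuted
labels; the `scripts/acceptance.R` script recomputes all of these from
scratch.

## Known limitations

* Redundancy is only detected between *adjacent* bands; a band
  duplicated far away in the spectral order is invisible to the method
  (by design — it mirrors the acquisition physics).
* Consensus monotonicity across thresholds is guaranteed per image; the
  majority vote preserves it in all realistic vote patterns but it is
  not a theorem.
* The 256-bin default is inappropriate for planes much smaller than
  ~200×200 pixels (see the bias discussion); choose bins so that
  `n_bins^2` is well below the pixel count.
* TIFF output is integer-only (8/16-bit); continuous cubes round-trip
  losslessly through ENVI float64 instead.
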