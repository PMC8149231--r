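---
title: "Immune-optimized texture classification of ultrasound liver images: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune-optimized texture classification of ultrasound liver images: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

B-mode ultrasound renders the echo amplitude of tissue as pixel
brightness. The interference of sub-resolution scatterers produces
*speckle*, and the statistics of that speckle carry diagnostic
information: normal liver parenchyma shows fine, dense, uniform speckle;
cirrhotic liver shows coarse, unevenly distributed echoes; malignant
tissue is irregular, with a widened gray-level range. `immunotexture`
turns those qualitative axes into a 30-dimensional texture feature
vector per region of interest (ROI) and classifies the three tissue
states with a radial-basis-function SVM whose hyperparameters *and*
feature subset are selected jointly by a clonal-selection immune
algorithm.

The pipeline is: (1) grayscale conversion and paired-ROI validation,
(2) feature extraction on 1×1 cm analysis windows, (3) immune-algorithm
optimization of the SVM, (4) evaluation under a five-group rotation
protocol against three baselines.

## Preprocessing and paired ROIs

Scans are reduced to 8-bit grayscale (BT.601 luminance weights for RGB
input). The display/QC chain offers a median despeckle filter
(3×3 default; median chosen as the standard edge-preserving speckle
filter), a percentile contrast stretch (defaults 1–99 to resist
outliers; histogram equalization available behind a switch) and Otsu
binarization for visual inspection. Two choices deserve emphasis:

- **Binarization is QC only.** The mask highlights the echogenic
  anatomy; no feature is computed from it.
- **Feature extraction despeckles but does not stretch.** The width of
  the gray-level distribution is itself one of the three diagnostic
  axes (widened in malignancy), and a per-ROI stretch would normalize
  it away. Keeping the native dynamic range also gives the normal
  class its concentrated intensity histogram, which is what makes its
  angular second moment the highest of the three classes.

Each image carries two rectangles: A1 inside the lesion and A2 in
normal parenchyma. `validate_roi_pair()` checks the placement
principles — no overlap, equal depth (row-centre difference within
`depth_tol`, default 10 px, the linear-probe reading of "same depth"),
and each side long enough for at least one 1×1 cm analysis window at
the image's pixel spacing (default 0.1 mm/px, so 100 px). Placement
itself is manual, as in clinical practice; the package validates, it
does not segment.

## Texture features

ROIs are tiled into non-overlapping 1×1 cm windows and per-window
features are averaged (windows of a homogeneous ROI are near-i.i.d.
draws of the same texture, so the mean reduces variance without mixing
tissue states).

**Cooccurrence statistics.** Intensities are quantized into 32
equal-width bins over [0, 255] (32 balances gray resolution against
count sparsity in a 100×100 window; configurable 2–64). For offset
(d, θ) the cooccurrence matrix counts unordered pixel pairs
symmetrically — the common convention; the raw pair count T is kept on
the object so the convention is auditable. Entropy is computed with
the conventional minus sign (so H ≥ 0, in bits, base 2), the angular
second moment as the sum of squared probabilities (the standard
definition of the energy the name refers to; the unsquared sum is
identically 1 after normalization), and contrast as the inertia
Σ(i−j)²P(i,j). Offsets d = 1 at all four angles plus d = 2 at 0°/90°
fill the feature budget with both scales of neighbor structure; this
particular set is a documented reconstruction, not a canonical list.

**Fourier ring energies.** The DC-removed power spectrum of the window
is partitioned into four equal-width radial bands; band energies are
normalized by total energy. Fine speckle pushes energy outward, coarse
speckle concentrates it near DC. Only the first three fractions enter
the feature table: the four sum to one, so the fourth is redundant, and
dropping it is what makes the full table exactly 30 columns
(18 cooccurrence + 3 Fourier + 9 fractal).

**Wavelet-fractal vector.** The window is split once with the
orthonormal 2-channel Haar bank into LL/LH/HL/HH; the LH band (low-pass
abscissa, high-pass ordinate) is split again with a separable
3-channel uniform bank into a 3×3 grid. We use the 3-point DCT-II
filters (low/band/high) as the real-valued uniform bank — a complex
DFT-modulated bank would make its two non-DC channels redundant
conjugates on real images. The feature vector holds the fractal
dimensions of the raw window, LL, LH, and six level-2 subimages — the
cells whose column channel is not purely low-pass, in raster order
(a reconstruction; the six-band subset is not uniquely determined by
the decomposition's indexing). Window sides must be even and ≥ 64; the
3-channel stage truncates to the largest multiple of three (100 px
windows lose one boundary row/column).

## The fractal estimator

The fractal dimension of an intensity surface is estimated from
*differential box spans*: for box sizes s ∈ {2, 4, …, side/4} the
surface (rescaled to [0, 255]) is tiled into s×s cells and the mean
span (cell max − min) recorded. For an ideal self-affine surface the
mean span grows as c·s^H with D = 3 − H. On a *sampled* grid, however,
a cell's span misses the sub-sample excursions of the underlying
surface — an approximately scale-independent deficit. We measured the
consequence directly: the classical box-count slope (which also adds a
guaranteed floor box per cell) compresses the estimates of surfaces
with known dimension 2.2–2.8 into 2.03–2.34. The estimator therefore
fits

  span(s) = c·s^H − a

by least squares over a grid of H values (the deficit a absorbing the
missing sub-sample roughness) and reports D = 3 − H, clipped to
[2, 3]. A constant grid returns exactly 2; with fewer than three box
sizes (grids down to 8×8, e.g. level-2 subimages) the deficit term is
dropped and the two-point slope used. Calibration: an inclined plane
reads 2.0; spectrally synthesized fractional Brownian surfaces with
H ∈ {0.2, 0.5, 0.8} read within ≈ 0.1 of 3 − H (the test suite checks
±0.15 over 20 seeds at 128×128). The fBm synthesizer shapes white
Gaussian noise with spectral amplitude f^−(H+1) on a domain twice the
requested side and crops, so FFT periodicity cannot saturate
large-scale spans.

## The immune optimizer

An antibody is a binary string of 32 fields × n bits (default n = 8).
Fields decode through the uniform grid map
x = d + (u−d)/(2ˡ−1)·Σⱼ aⱼ2^(j−1): fields 1–2 give log₂C and log₂r over
the standard RBF search box C ∈ [2⁻⁵, 2¹⁵], r ∈ [2⁻¹⁵, 2³]; each of
fields 3–32 screens one feature in when its decoded value in [0, 1]
reaches 0.5. Equal-width fields are the reading consistent with a
32·n-bit chromosome holding "two parameters and thirty screens"; an
antibody whose mask would be empty has one random feature field forced
on. Affinity is the five-fold cross-validated accuracy of the decoded
SVM on the screened columns, using the dataset's stored stratified
folds, so repeated evaluations are deterministic.

Each cycle: the best antibody is cloned 30×, every other 10× (the
study protocol: 5 antibody groups, replication rates 10 and 30, cycle
cap 500); clones mutate by independent bit flips at rate 1/n — the
operational form of "longer field encodings mutate each bit more
rarely" — and parents are left unmutated (only clones hypermutate; the
alternative is not specified anywhere, and mutating parents would
break elitism). Selection is per-lineage elitist: each parent is
replaced by the best of itself and its own clones, so the population
returns to 5 and the best affinity is monotone non-decreasing. The
density-based suppression of the general immune-network formulation is
deliberately not implemented: the concrete three-step algorithm this
package operationalizes does not use it.

Convergence is exported as objective = 1 − best affinity against the
cycle number, which decreases fast over the first cycles and flattens
as the search turns local; plotting the complementary error (rather
than the accuracy) matches the conventional descending convergence
curve for a maximized affinity.

## Classifiers and evaluation protocol

All algorithms are scored with the same five-group rotation: samples
are split into five class-stratified groups, each used once for
testing. Feature standardization (and PCA, when used) is fitted on the
four training groups only — the test suite asserts that perturbing
test-fold values never changes the training-side preprocessing. The
evaluation count reported for every algorithm is the number of SVM (or
prototype-model) trainings, the shared cost unit: a g×g grid search
costs g²·5, the immune optimizer costs 5 fits per affinity evaluation.

The plain-SVM baseline searches a 15×15 log₂ grid over the same (C, r)
box as the optimizer so evaluation counts are comparable. Multi-class
handling is one-vs-one, the e1071/libsvm default. The stand-alone
immune-algorithm baseline is a clonal-selection nearest-prototype
classifier — class-tagged prototype vectors, affinity = −Euclidean
distance, antigen-directed hypermutation of the best-matching
prototype — a synthetic stand-in (the reference gives no construction),
initialized at the class centroid so that with one prototype and no
refinement passes it reduces exactly to nearest-centroid. PCA+SVM
projects standardized training folds onto the leading components
(default 10) before the SVM.

## The speckle simulator

`generate_speckle_image` draws an i.i.d. complex Gaussian scatterer
field, low-pass filters it with a Gaussian kernel at the class's
correlation length (fully developed speckle: the envelope magnitude of
a circular complex Gaussian field is Rayleigh), multiplies by a slow
multiplicative gain field (heterogeneity), optionally carves an
irregular hypoechoic blob (radial cosine-perturbed ellipse at random
position, depth 0.35–0.65), and maps linearly onto the class gray
range. Default images are 256×256 at 0.1 mm/px — four 1×1 cm analysis
windows.

Default class recipes encode the three qualitative axes, with the
malignant class deliberately hardest (largest within-class parameter
jitter plus the blob):

| class | corr. length (px) | heterogeneity | gray range | jitter |
|---|---|---|---|---|
| normal | 1.2 | 0.03 | 70–150 | 0 |
| cirrhosis | 3.5 | 0.35 | 25–215 | 0.10 |
| cancer | 2.8 | 0.45 | 10–255 | 0.25 (+ blob) |

These were fixed from the qualitative descriptions (fine/dense/uniform;
coarse/uneven; irregular/widened range) before end-to-end evaluation
and define the study conditions for all dataset-level tests: the
narrow normal range yields the highest angular second moment, the
cancer range the largest intensity spread, and the per-class accuracy
ordering normal ≥ cirrhosis ≥ cancer.

What the simulator does *not* emulate: beamforming and point-spread
anisotropy, depth-dependent attenuation and focal gain, sector-probe
scan conversion, anatomical structures (vessels, ducts) other than a
single lesion blob, and inter-patient variability beyond the recipe
jitter. Passing tests on synthetic data therefore demonstrate the
internal consistency and discriminative machinery of the pipeline, not
clinical performance; headline accuracies on real scans cannot be
reproduced without a clinical corpus.

## Numerical choices and problem sizes

- GLCM quantization 32 levels; entropy base 2; symmetric pair counting
  with T recorded.
- Degenerate guards: constant images are returned unchanged by the
  stretch, rejected by Otsu, read fractal dimension exactly 2, and
  produce zero ring energies.
- The optimizer's RNG is fully derived from the config seed; affinity
  caching plus fixed folds make runs bit-reproducible.
- Dataset-level tests and the acceptance script use 100 images per
  class (the study's design size) with a 15-generation,
  0.98-target-affinity optimizer configuration — on this synthetic
  problem the search converges within a few cycles, so the 500-cycle
  cap of the protocol is exercised on cheap surrogate landscapes
  instead (500 full cycles with elitism asserted per generation).
  Fractal calibration uses 128×128 surfaces and 20 seeds.

## Known limitations

- The level-2 wavelet band subset and the (d, θ) offset list are
  documented reconstructions; other defensible choices exist.
- The box-span fractal estimator's deficit correction assumes a single
  dominant roughness scale regime; strongly multi-fractal surfaces are
  summarized by one number regardless.
- The prototype immune baseline is a constructed stand-in, and its
  accuracy should be read only relative to the other algorithms on the
  same data.
- With 8 bits per field the (C, r) grid resolution is ~0.08 in log₂
  units; raise `bits_per_field` for finer tuning at proportional cost.
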