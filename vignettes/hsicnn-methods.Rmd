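---
title: "Spectral-spatial classification of H&E liver tissue: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-spatial classification of H&E liver tissue: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Hepatocellular carcinoma is usually confirmed from hematoxylin-and-eosin
(H&E) stained biopsy slides. A visible/near-infrared hyperspectral
microscope records, for every pixel of such a slide, a transmittance
spectrum across hundreds of narrow bands rather than three broad color
channels. Stained tissue absorbs in characteristic ways — eosin produces a
well-known transmittance dip near 540 nm and liver tissue shows a second
dip near 650 nm — so the spectral axis carries chemical information that an
RGB rendering compresses away. `hsicnn` implements a complete pipeline for
exploiting that information: radiometric calibration of raw cubes, patch
tiling with blank-glass rejection, alternative spectral representations, a
compact volumetric convolutional classifier trained with a class-balanced
focal loss, and an evaluation protocol built for heavily imbalanced,
case-structured data.

## The classifier

The network is four identical blocks — a same-padded convolution with ReLU
activation, 3×3×3 max-pooling with stride 2, then batch normalization —
with filter counts 4, 8, 16, 32, followed by global average pooling, a
512-unit ReLU dense layer, 10% dropout, and one sigmoid output giving the
probability that a patch is tumor ("unhealthy" is the positive class). In
the 3D variant the cube is a single-channel volume and kernels slide along
both spatial axes and the spectral axis, so local spectral shapes (dips,
slopes) are learned jointly with texture. The 2D twin folds the bands into
input channels and convolves over space only; it sees the same information
but cannot form local spectral features. For a 100×100×270 input the
stride-2 SAME poolings reduce the spectral depth 270 → 135 → 68 → 34 → 17
(each extent maps to its ceiling half), and global average pooling emits a
32-vector. `propagate_shapes()` reproduces this table for any input size.

Two boundary variants need conventions. An RGB-style 3-band cube cannot be
halved spectrally four times, so for inputs with at most 3 bands the 3D
variant caps the spectral kernel extent at the band count and uses spectral
pooling stride 1 — the minimal change that keeps the topology intact.
The 2D variant's flattened feature count differs from the 3D variant's;
only the layer structure, filter counts, and head are shared.

### Loss

Training minimizes the class-balanced focal loss. With `p` the predicted
positive probability and `y ∈ {−1, 1}` the truth, `p_t = p` if `y = 1` and
`1 − p` otherwise, and the per-sample loss is

    FL(p_t) = − a_t (1 − p_t)^γ log(p_t),

where `a_t` is `α` for positives and `1 − α` for negatives. `γ = 0`
recovers (balanced) cross-entropy; `γ > 0` down-weights well-classified
examples so that abundant easy tumor patches cannot drown out the rare
healthy class. Both `focal_loss()` and its analytic logit gradient are
exact, clamped at `p_t ∈ [1e−7, 1 − 1e−7]` to keep the logarithm finite;
the gradient is verified against finite differences in the test suite.
Defaults are `γ = 2`, `α = 0.5` — with strong focusing, the weighting
factor matters much less, because easy positives are already suppressed.

### Optimization and batch normalization

Adam with `β₁ = 0.9`, `β₂ = 0.999` and learning rate 0.001. The reference
schedule is 100 epochs at batch size 128; the desk profile (the default,
used throughout the tests) is 15 epochs at batch 32. Batch-norm inference
statistics are re-estimated every epoch as the sample-weighted average of
that epoch's batch moments instead of a slow exponential moving average:
with only a few dozen optimizer steps, an EMA initialized at (0, 1) is
still dominated by its starting point when training ends, which makes
evaluation-mode predictions collapse toward the majority class while
training-mode accuracy looks perfect. Per-epoch re-estimation removes that
artifact deterministically.

The convolution and pooling kernels are compiled code (an im2col unfold
followed by a BLAS matrix product); everything else is vectorized R. A
deliberately slow direct-summation oracle, `conv3d_reference()`, evaluates
the sextuple sum literally and is used only to verify the fast path —
the two implementations agree to better than 1e−5 relative error on random
tensors, and all analytic gradients are checked against central
differences.

## Representations compared

Four spectral representations feed the same topology:

* **Full cube** — all bands in the analysis window.
* **Band sampling** — `sample_bands(x, k)` keeps indices `0, s, …,
  (k−1)s` with stride `s = ⌊B/k⌋`; the sampling phase starts at 0 since a
  constant sampling frequency fixes only the stride.
* **Incremental PCA** — `fit_pca()` treats every training pixel as one
  length-B observation and digests them in 4096-spectrum chunks through a
  rank-update SVD, so memory stays bounded for arbitrarily large training
  sets. Components are kept while their explained-variance ratio is at
  least 0.1% (or an exact count, e.g. PCA-9/PCA-3, may be requested). The
  model is fitted on training-split pixels only and then applied,
  never refitted, to validation and test data. Component signs are fixed
  by making each component's largest-magnitude coefficient positive, so
  fits are deterministic.
* **Synthesized RGB** — each channel is the spectrum averaged under a
  Gaussian window with means 630/540/480 nm (R/G/B) and a 25 nm standard
  deviation. Weights are normalized to unit sum per channel so a
  spectrally flat pixel maps to itself; the normalization is a convention
  this package fixes, as the Gaussian description alone leaves it open.

## Tiling and blank rejection

Sample images are tiled into non-overlapping S×S patches anchored at the
top-left corner, remainder discarded. Slides contain unstained glass,
which transmits brightly; a patch dominated by glass carries no signal. A
pixel counts as blank when its band-averaged calibrated transmittance
exceeds a two-class Otsu threshold computed per source image (glass vs
stain is a bimodal problem, and the threshold is unsupervised and
image-local, so computing it per image leaks nothing across splits).
Patches with strictly more than 50% blank pixels are removed; a patch at
exactly 50% is kept. Blank fractions are always measured on the
pre-reduction cube and the keep/drop decision is transferred to the
reduced representation — PCA scores have arbitrary sign, so a brightness
threshold in reduced space would be meaningless.

## Calibration and I/O

Raw push-broom counts become transmittance through the standard flat-field
form `(raw − dark) / (white − dark)`, clipped to [0, 1]. White references
may be full frames or per-line (rows × bands) averages; both broadcast.
Pixels where the references coincide (within 1e−8 of the white dynamic
range) raise an error rather than dividing. Cubes travel as ENVI rasters
(binary raster + ASCII header carrying the per-band wavelength grid); all
three interleaves are read, BSQ/float64 is written so round-trips are
bit-exact, and the band window (400–800 nm by default upstream of this
package's concerns) is cropped with inclusive endpoints — the cube's own
header wavelengths are always treated as ground truth rather than an
assumed uniform grid.

## The phantom: what it emulates, and what it does not

Real annotated hyperspectral liver slides are not freely redistributable,
so the package ships a synthetic generator that reproduces the
*statistical structure* the method relies on, at desk scale by default:
64×64-pixel sample images on a 30-band grid over 400–800 nm, scaled down
from 1000×2000-pixel, 270-band originals (both remain configurable).

* **Components.** Five endmembers: blank glass (near-flat, brighter than
  any tissue at every band), and cell/background endmembers for each
  class. Tissue spectra are smooth baselines minus Gaussian dips at 540
  and 650 nm. Nuclei are non-overlapping disks 12–18 px in diameter — the
  size a 40× setup at 0.55 µm/px measures for liver nuclei — placed at
  ~1.2 nuclei per 1000 tissue pixels; a glass strip covers 12.5% of the
  width; band-wise Gaussian noise (SD 0.02) is added and values clipped
  to (0, 1].
* **Class contrast.** The tumor-vs-normal difference is a band-alternating
  component under a smooth envelope that vanishes at both window edges,
  with the row space of the RGB synthesis matrix projected out, scaled to
  a peak contrast δ (default 0.25). Three consequences are built in by
  construction rather than tuned: (i) the two classes are metamers under
  the package's own RGB synthesis, so an RGB model cannot separate them
  and any spectral model's advantage over RGB is structural; (ii) the
  per-band contrast survives constant-stride band sampling in proportion
  to the number of retained bands, so classification quality is monotone
  in band count; (iii) a single retained band at 400 nm carries no
  contrast at all, giving the sweep a clean floor. δ is a free parameter
  of the generator — the true inter-class effect size in real tissue is
  not derivable from published materials — and the default is chosen so
  that a pixel-level nearest-endmember classifier already separates
  classes comfortably, guaranteeing the phantom carries the signal the
  network is supposed to find. Setting δ = 0 yields the negative control:
  spectrally identical classes on which any end-to-end result must be
  statistically indistinguishable from chance.
* **Cohort layout.** Thirty cases — 3 healthy, 27 tumor — with two sample
  images each, divided into three case-disjoint splits of 1 healthy + 9
  tumor cases (so 2 + 18 samples per split, 60 in total), mirroring the
  severe imbalance of a real liver microarray cohort.

What passing tests on the phantom do **not** show: robustness to staining
variability, scanner drift, focus artifacts, nucleus morphology and
chromatin texture differences between grades, spatially correlated noise,
or any real-tissue effect size. Spatial texture is deliberately identical
across classes by default so that spectral information is isolated; a
density knob exists to add spatial contrast, but no claim about real-data
performance follows from phantom results.

## Evaluation protocol

All metrics derive from patch-level pooled confusion counts with tumor as
the positive class: accuracy, precision, recall, F1, and the Matthews
correlation coefficient. MCC is the headline number — with a 9:1 class
ratio a trivial always-tumor classifier already reaches 90% accuracy and
perfect recall, while its MCC is 0. Degenerate denominators use the
standard conventions (precision/recall/F1 are 0 on an empty denominator;
MCC is 0 when any factor under its root vanishes). Patch-level pooling is
a choice: published per-split figures in this area are sometimes not the
harmonic mean of their own precision/recall, suggesting per-case
averaging; this package reports pooled patch-level metrics and exposes the
per-case table for anyone who prefers the other aggregation.

Splits are always by case, never by image or patch; a case identifier
appearing on both sides of a fit raises a hard `leakage_error` rather than
a warning. `rotate_splits()` produces the three cyclic role rotations
(train→val→test→train) used to check that results do not depend on one
lucky split. The decision threshold is 0.5 with a strict inequality
(probability exactly 0.5 is called healthy); no calibration is applied.

## Numerical choices and degenerate inputs

* Probability clamp 1e−7 inside the loss; BN epsilon 1e−5; He
  initialization for conv/dense weights; BN starts at identity.
* Max-pooling SAME padding follows the ceil-division convention with the
  smaller pad in front; argmax ties resolve to the first element scanned,
  making pooling deterministic.
* Band-window endpoints are inclusive ("between 400 and 800 nm" read as a
  closed interval), which makes a prefix selection of a uniform grid.
* All randomness (weight init, shuffling, dropout, phantom rendering,
  split draws) flows from explicit integer seeds; identical seed and
  configuration reproduce results bit-for-bit on the same BLAS.
* The incremental PCA refuses to fit fewer observations than requested
  components; empty band windows, oversized patches, mismatched
  wavelength counts, and degenerate calibration references each raise a
  typed condition rather than propagating NaNs.

## Problem sizes used in the shipped tests

The test suite and the reproduction script run entirely at desk scale:
30-band 64×64 phantoms, 32×32 patches (so 80 patches per split), 15
epochs at batch 32, with 3 split rotations, a 5-seed negative control,
and a 3-seed × 5-variant representation sweep. These sizes were chosen as
the smallest at which every qualitative property of the method — signal
recovery, band-count monotonicity, the spectral-over-RGB advantage, and
rotation stability — is comfortably expressed on a single CPU. The
paper-faithful scale (100×100×270 patches, 100 epochs, batch 128) is a
configuration flag away but is a GPU-sized computation.

## Known limitations

* The training engine is single-threaded CPU code built for desk-scale
  inputs; im2col memory grows with patch volume, so the full-scale
  profile needs a machine with commensurate memory and patience.
* No data augmentation, transfer-learning baselines, stain
  normalization, or hyperparameter search beyond the γ/α/S/variant grids.
* The phantom's optics are phenomenological (endmember + Gaussian noise),
  not a physical simulation of staining chemistry or the imaging train.
* Checkpoints serialize with R's native format plus a JSON sidecar; they
  are not portable to other frameworks.
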