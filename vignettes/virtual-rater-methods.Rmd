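---
title: "Virtual raters: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual raters: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virtrater)
```

## The problem and the method

Volumetric assessment of brain tumors in multi-channel MRI is notoriously
rater-dependent: two experts segmenting the same glioma differ both in where
they draw boundaries (systematic inclusion criteria) and from session to
session (intra-rater variability).  A *virtual rater* (VR) stabilizes this
by combining a machine-learning model trained on the pooled historical
annotations of several human raters with the instantaneous annotations of
one human rater for the case at hand.  One VR accompanies each human rater;
because all VRs share most of their training data, their assessments agree
far more with each other than the humans do, while each still reflects its
human's input on the current case.

The pipeline implemented here is:

1. **Features** (`assemble_feature_stack()`): from the four co-registered
   modalities (nT1w, ceT1w, T2w, FLAIR) plus the ceT1w − nT1w subtraction
   channel, a two-scale filter bank (Gaussian smoothing, Laplacian of
   Gaussian, difference of Gaussians, gradient magnitude, structure-tensor
   and Hessian largest eigenvalues at scales 1.0 and 3.5 voxels) produces
   5 + 5 × 12 = **65 feature channels** per voxel.
2. **Classifier** (`train_forest_matrix()`, `predict_probabilities()`): ten
   random forests of ten trees each are trained on the labeled voxels and
   merged into a single 100-tree forest (literal tree concatenation via
   `randomForest::combine`); the per-class vote fraction is the voxel's
   pseudo-probability.
3. **Post-processing** (`postprocess_segmentation()`): Gaussian smoothing of
   each class probability channel with σ = 1.2 voxels, voxelwise argmax
   (ties to the lowest class id), and removal of connected components
   smaller than 1000 voxels (26-connectivity; strictly smaller, so an
   exactly-1000-voxel component survives).
4. **Virtual-rater pooling** (`assemble_training_pool()`,
   `run_virtual_rater_lopo()`): for a held-out patient, training pools all
   raters' and runs' annotations of every *other* patient plus only the
   current rater's annotations (all runs) of the held-out patient.
5. **Fusion** (`staple_fuse()`): multi-category STAPLE estimates a
   probabilistic consensus segmentation and per-rater confusion matrices by
   EM, used to build reference segmentations from whatever rater
   segmentations are available.
6. **Metrics** (`dice()`, `icc1_oneway()`, `fisher_combine()`,
   `class_volumes()`, `rano_classify()`, `rano_product_2d()`): agreement and
   response assessment, including the gross tumor volume (GTV, the merged
   tumor-related classes), its longitudinal percent change dGTV, and the
   bidimensional surrogate measurement.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| feature scales | 1.0, 3.5 voxels | filter-bank smoothing scales (grids are 1 mm isotropic, so voxels = mm) |
| forests × trees | 10 × 10 | sub-forests trained on the full set with derived seeds, then merged |
| σ (probability smoothing) | 1.2 voxels | regularizes the pseudo-probability maps before argmax |
| min component | 1000 voxels | removes spurious specks after argmax |
| sampling caps | 200 / 1000 | training voxels per tumor class / normal tissue |
| dropout P | 1 (off) | probability that an annotation instance is available for training |
| response cutoffs | +25 % / −50 % | progression / partial response on dGTV (inclusive); alternative volumetric cutoffs +40 % / −65 % |

Choices the underlying description leaves open, decided here:

- **One eigenvalue channel per tensor filter.** In 3D the structure tensor
  and Hessian each have three eigenvalues, but the stated stack size of 65
  is only consistent with one entry per filter × scale; the largest
  eigenvalue is used.  The structure tensor takes gradients at half the
  nominal scale and integrates at the nominal scale; the
  difference-of-Gaussians uses G(σ) − G(1.5 σ).
- **Boundary handling** is symmetric reflection everywhere; with a
  normalized symmetric kernel the smoothing operator is doubly stochastic,
  so the global mean is preserved exactly and probability maps stay
  normalized after channelwise smoothing.
- **Pseudo-probabilities are vote fractions.** Trees are fully grown, so
  leaf class distributions are pure and the vote fraction equals the mean
  leaf posterior.
- **Removed components become background** (the scheme's normal-tissue
  class), not their second-best class; filtering operates per class
  independently (`filter_scope = "foreground"` merges first instead).
- **STAPLE details**: stationary class prior equal to the mean observed
  class frequencies; initial confusion diagonal 0.99999; convergence on the
  mean absolute change of the consensus posteriors (10⁻⁶) or 100
  iterations; consensus argmax ties to the lowest class id.  Hard argmax
  labels (not posteriors) are used when a consensus serves as training
  reference.  The EM log-likelihood is asserted non-decreasing on every
  run.
- **Dropout** applies to historical annotation records only — the current
  rater's annotations of the held-out patient are the VR's defining input
  and always stay.

## What the phantom emulates (and what it does not)

`phantom_spec()` builds four-channel studies on a small isotropic grid: a
brain ellipsoid of normal tissue inside a zero-intensity exterior, a CSF
region, and a nested tumor (non-enhancing core ⊂ enhancing rim ⊂ edema)
whose radii grow by a per-timepoint factor (default 1.2, i.e. +73 % GTV per
step).  Class intensities are Gaussian around per-class means chosen so
that contrast enhancement (ceT1w > nT1w) occurs only in the enhancing rim,
edema is FLAIR-bright, and CSF is T2-bright but FLAIR-suppressed; a
multiplicative product-of-cosines bias field and additive Gaussian noise
(sd 4 intensity units against a 25-unit enhancement contrast) complete the
model.

Simulated raters (`rater_model()`) displace each class boundary by a
systematic signed bias plus a per-case Gaussian jitter — implemented as
sub-voxel level-set shifts of the Gaussian-smoothed region indicator — and
confuse classes inside a one-voxel boundary shell (by default edema vs
normal tissue, the classic edema/gliosis ambiguity).  Scribbles are sampled
without replacement from the one-voxel erosion of each labeled region
(high-confidence annotations never touch boundaries); each rater places at
least 20 scribbles per visible class, as a human annotating every category
would.

Deliberately **not** modeled: MR physics (Rician noise, partial volume,
sequence simulation), registration error, skull stripping, and anatomical
realism of shapes.  Passing tests on these phantoms therefore demonstrate
the *mechanics and the comparative behavior* of the protocol (VR agreement
above human agreement, variance shrinkage, graceful dropout degradation) —
not clinical-grade segmentation accuracy on real scans.

## Calibration of the simulated raters

The rater-noise knobs are free parameters.  They were fixed once by
measuring pairwise *human* GTV Dice on small cohorts (no virtual raters in
the loop): opposing biases of ±0.2 voxels with jitter sd 0.35 put simulated
inter-rater agreement at 0.82 ± 0.11, the mid-0.8 regime reported for human
experts on gliomas.  All downstream experiments use these values unchanged.

## Scaled-down study conditions

The phantom experiments run on 32³ grids with 8 patients × 2 timepoints and
2 raters × 2 runs (the problem sizes used throughout the tests and
examples).  Two parameters scale with the grid rather than carrying over
literally:

- **Minimum component size 50** (instead of 1000): the whole phantom GTV is
  ~1.2k voxels, against clinical GTVs of tens of thousands of mm³; 50 keeps
  the tumor-to-threshold volume ratio comparable and stays below the
  smallest simulated structure (the ~130–180-voxel non-enhancing core).
- **Pooling caps for sparse scribbles** are applied once per class on the
  pooled training set (tumor classes 200, other non-background classes 200,
  normal tissue 1000).  For dense annotations the caps are per record, as
  in the original protocol (`subsample_dense_labels()`).

## Numerical choices and degenerate inputs

- All voxel coordinates are 0-based; world units enter only through the
  NIfTI voxel spacing.
- Sub-seeds for every (patient, timepoint, rater, run, stage) cell derive
  from the master seed by a platform-independent polynomial hash
  (`derive_seed()`), so any cell can be regenerated in isolation and full
  pipeline reruns are hash-identical.
- `dice(∅, ∅)` is defined as 1 (two empty segmentations are identical).
- Fisher's method rejects p = 0 rather than silently clipping.
- Argmax and STAPLE consensus ties resolve to the lowest class id.
- Classes absent from training carry explicit zero-probability channels so
  the class scheme survives the round trip.
- A class whose eroded region is empty yields zero scribbles with a logged
  message, not an error.
- The bidimensional measurement searches diameter endpoints over all voxel
  centers of the in-plane component (convex hull only beyond 600 voxels,
  where the longest diameter is provably on the hull); the perpendicular
  tolerance is ±5°, and a one-voxel extent is added to each diameter so a
  single-voxel lesion measures 1 mm × 1 mm.

## Known limitations

- The easy-regime ceiling: scribbles are interior-only, so the classifier
  never sees boundary voxels; at 32³ resolution about one voxel of boundary
  uncertainty remains, capping VR-vs-truth GTV Dice near 0.95 even with
  noise-free channels and perfect raters.  This does not affect the
  *comparative* claims (VR-vs-VR agreement), which is what the protocol is
  about.
- The one-way ICC and Fisher combination assume independent series; no
  dependency correction is applied.
- STAPLE is the standard stationary-prior multi-category variant; spatially
  varying priors and robust variants are out of scope.
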