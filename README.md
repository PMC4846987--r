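# virtrater

Reproducible volumetric assessment of brain tumors with **virtual raters**.

Tumor volumetry in multi-channel MRI (native and contrast-enhanced T1w,
T2w, FLAIR) is the basis of response assessment in neuro-oncology, but it
is rater-dependent: experts disagree systematically about boundaries and
with themselves across sessions.  A *virtual rater* (VR) combines a
random-forest pixel classifier trained on the pooled historical annotations
of several human raters with the instantaneous sparse annotations
("scribbles") of one human rater for the case at hand — one VR per human.
Because the VRs share most of their training data, their assessments agree
far more with each other than the human raters do, while still honoring
each human's input.

The package implements the full protocol end to end:

- **Features**: per-voxel stack of the 4 modalities + the ceT1w − nT1w
  subtraction + a two-scale filter bank (Gaussian smoothing, Laplacian of
  Gaussian, difference of Gaussians, gradient magnitude, structure-tensor
  and Hessian largest eigenvalues at scales 1.0 and 3.5) — **65 channels**.
- **Classifier**: 10 random forests × 10 trees merged into one 100-tree
  forest; vote fractions as per-class pseudo-probabilities.
- **Post-processing**: channelwise Gaussian smoothing (σ = 1.2 voxels) →
  argmax → removal of connected components < 1000 voxels.
- **Virtual-rater pooling**: leave-one-patient-out training on all raters'
  annotations of the other patients plus the current rater's annotations of
  the held-out patient; optional annotation-instance dropout with
  probability 1 − P.
- **STAPLE fusion**: multi-category EM consensus with per-rater confusion
  matrices.
- **Metrics**: Dice, Pearson, one-way ICC (McGraw & Wong case 1), Fisher's
  method, per-class volumes and GTV, longitudinal percent change (dGTV),
  RANO-style bidimensional product, and volumetric response classification
  (+25 % progression / −50 % partial response, inclusive; alternative
  40/65 cutoffs).
- **Phantoms**: a synthetic multi-channel MRI generator with nested tumor
  geometry, known ground truth and simulated imperfect raters, so every
  stage is testable without any external data.

## Worked example

Simulate a cohort of 8 phantom patients (2 timepoints, 32³ voxels) rated
twice by two noisy simulated raters, build both virtual raters by
leave-one-patient-out pooling, and compare pairwise GTV agreement:

```r
library(virtrater)

ex <- vr_agreement_experiment(n_patients = 8, n_timepoints = 2,
                              grid_vox = 32, seed = 1)
summarise_agreement(ex)
#> # A tibble: 2 × 4
#>   kind  mean_dice sd_dice n_pairs
#>   <chr>     <dbl>   <dbl>   <int>
#> 1 human     0.848 0.0951       64
#> 2 vr        0.991 0.00568      16
```

The simulated human raters — boundary bias ±0.2 voxels, jitter sd 0.35,
calibrated to the mid-0.8 Dice regime typical of experts on gliomas —
agree at 0.848 ± 0.095 across 64 inter-rater GTV comparisons.  Their two
virtual raters agree at 0.991 ± 0.006: the mean is higher *and* the spread
collapses, which is the protocol's central claim.  `plot_agreement(ex)`
draws the comparison; `ex$gtv` holds the per-study GTVs (truth, humans,
VRs) for ICC and dGTV analyses, e.g. `plot_dgtv(ex$gtv)`.

Individual stages compose just as well:

```r
ph    <- generate_phantom(phantom_spec(), timepoint = 0)
stack <- assemble_feature_stack(ph$image)   # 65 channels
length(stack$channels)
#> [1] 65

rano_classify(c(10, 25, -50), response_thresholds())
#> [1] "stable"      "progression" "partial_response"
```

A thin command-line front end over the same functions lives at
`inst/cli/virtrater.R` (`simulate`, `features`, `train`, `predict`,
`postprocess`, `fuse`, `vr-run`, `vr-dropout`, `evaluate`), configured by a
strict YAML schema (`run_config()`); every artifact gets a JSON provenance
record.

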