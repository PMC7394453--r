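---
title: "Correcting susceptibility distortion from a single blip: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting susceptibility distortion from a single blip: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(b0synth)
```

## The problem

Echo-planar diffusion MRI accumulates phase along one image axis — the
phase-encoding (PE) axis — slowly enough that off-resonance from magnetic
susceptibility differences at tissue/air interfaces displaces signal along
that axis.  The displacement at a voxel is

    shift (voxels) = polarity x field (Hz) x total readout time (s)

Where the field gradient compresses voxels the signal piles up (bright
bands next to voids); where it stretches them the image thins out.  Tools
like topup invert this warp, but they need either a second acquisition with
the opposite blip polarity or a measured field map.  Many archives have
neither: one distorted b0 and a T1-weighted anatomical image is all there
is.

`b0synth` follows the synthesis route: a 3D U-Net learns to produce an
*undistorted* b0 — T1 geometry, diffusion contrast — from the pair
(normalized T1, normalized distorted b0).  The synthetic volume is then
declared to be an infinite-bandwidth acquisition (readout time 0, hence
zero distortion) and paired with the real distorted b0 for displacement
field estimation and unwarping.  The two-row acquisition-parameters table
that encodes this trick (an arbitrary positive readout in the first row,
an exact 0 in the second) is emitted alongside, so an external topup can
replace the in-package estimator bit-compatibly.

Everything is testable at desk scale because the clinical corpora are
replaced by a physics-based simulator whose ground truth (tissue labels,
field, displacement) is retained.

## The forward model and the simulator

`simulate_subject()` composes four stages:

1. **Phantom** (`make_phantom`): an ellipsoidal head with nested shells —
   CSF rim, gray shell, white core, CSF ventricles — whose boundaries are
   modulated by smooth random perturbations so no two subjects share
   geometry.  T1 contrast is white > gray > CSF on the 0–150
   normalized-T1 convention; b0 contrast has CSF brightest, so the
   volume's 99th intensity percentile lands in CSF.  Per-tissue Gaussian
   noise scaled by a global `noise_sd` gives intra-tissue texture.
2. **Field** (`make_field`): white noise smoothed at the configured
   correlation length (default 8 voxels), tapered to zero at the head
   boundary, standardized so the within-mask SD is amplitude/3 (seed-stable
   distortion energy), clipped to the +/- amplitude bound, plus localized
   high-amplitude hotspots near the inferior-frontal and temporal mask
   boundary where real heads concentrate off-resonance.  Outside hotspots
   the induced shift gradient is kept above the invertibility margin
   `1 + d(shift)/d(axis) > 0.05` (at the nominal readout `readout_ref`) by
   local smoothing; hotspots are exempt, which is precisely what makes
   them pile up signal.
3. **Displacement** (`field_to_displacement`): the linear EPI relation
   above; a readout of 0 gives the zero field identically.
4. **Distortion** (`apply_distortion`): a mass-preserving *pushforward* —
   every source voxel's intensity is linearly splatted to
   `index + shift` along the PE axis.  Per-line sums are conserved to
   float precision by construction and pileup emerges naturally where the
   map compresses.  The correction stage uses the complementary
   *pullback* with Jacobian modulation, so the two adjoint models provide
   an independent consistency check on each other.

Scanner noise is applied to the phantom intensities *before* the
pushforward.  Magnitude-image noise in a real scanner enters after spatial
encoding, but placing it before the splat makes every stored blip exactly
the pushforward of the stored truth — per-line mass conservation between
saved volumes then holds exactly and is a testable contract rather than an
approximation.  At the simulated SNR the statistical difference between
the two orderings is negligible for every quantity the package reports.

Defaults (48^3 grid at 2.5 mm isotropic, +/-50 Hz amplitude, correlation
length 8 voxels, readout 0.05 s, so bulk shifts of ~1 voxel SD and peaks
near 2.5 voxels) were chosen once as representative of moderately
distorted adult brain EPI; the field amplitude in particular is a
simulator choice exposed in configuration, not a literature-derived
constant.

## Preprocessing

* **Gain matching** (`match_gain`): when the undistorted truth comes from
  a separate acquisition its receiver gain differs; the truth is rescaled
  so masked medians agree.
* **T1 normalization** (`normalize_t1`): the fixed 0–150 range maps
  linearly to [-1, 1]; values above 150 are clipped at +1 (the convention
  only defines the range; bounded inputs are preferable for the network).
* **b0 normalization** (`normalize_b0_pair`): the 99th percentile of the
  *distorted* b0 maps {0, p99} to {-1, +1} with *no* upper clipping —
  pileup may legitimately exceed +1, which is exactly why a min/max
  scaling is unstable.  The same p99 scales every paired volume (the
  truth, a second blip) so intensities remain comparable.  For dual-blip
  samples the percentile is computed over the pooled blip intensities;
  the two blips never differ by more than sampling noise there, and one
  shared value guarantees one shared scale.
* **Working grid** (`to_working_grid`): trilinear resampling onto a
  2.5 mm isotropic grid with the forward/inverse affine pair stored;
  voxels that fall outside the source field of view are recorded in a
  validity mask, and `make_sampling_mask` intersects all validity masks
  into the loss mask so the network never trains on unresampleable
  regions.  The phantom is generated directly on the working grid, so in
  simulation this stage is an identity with an all-ones mask; real data
  additionally needs bias-field correction and template registration by
  external tools, which are out of scope here.
* **Smoothness matching** (`smooth_to_match`): the synthesized b0 returns
  from the working grid slightly blurred by interpolation; before field
  estimation the distorted b0 is smoothed to match, searching sigma in
  [0, 1.5] voxels to equalize a Laplacian-energy statistic.  The kernel
  family and the statistic are package choices; any monotone smoothness
  functional would serve.

## Network, loss, training

The synthesizer is a 3D U-Net: two input channels, one output channel,
two convolutions per level, 2x average pooling down, nearest upsampling
with a projection convolution and skip concatenation up.  Instance
normalization replaces batch normalization because the batch size is 1;
leaky rectification (slope 0.01) replaces plain ReLU so the
mostly-negative background still carries gradient.  The engine is written
in R: convolutions are im2col gathers through precomputed neighbour index
tables plus BLAS matrix products, and the backward pass is the exact
adjoint (verified against finite differences to ~1e-9 relative error in
the test suite).

The loss is dispatched per sample.  A single-blip sample contributes the
masked MSE between synthesis and truth.  A dual-blip sample feeds both
blips through the same weights and contributes
`(MSE1 + MSE2)/2 + MSE_diff`: the averaged truth term penalizes bias, the
difference term penalizes disagreement between the two syntheses
(variance).  The algebra is asserted against independent arithmetic on
random tensors.

Training follows a fixed schedule: Adam at learning rate 1e-4 with betas
(0.9, 0.999), weight decay 1e-5, 100 epochs by default, 5-fold
cross-validation partitioned *by subject* (sessions never straddle
folds) after a withheld test set is carved out.  After each epoch the
masked validation truth-MSE is recorded and the weights from the
minimum-validation epoch are kept, one network per fold; inference
averages the fold members voxelwise before de-normalization.  The
difference term is excluded from the validation metric so single- and
dual-blip validation subjects are scored on the same scale.  Everything
is seeded: weight draws, shuffles, and the simulator, so curves reproduce
bit-identically on one device.

## Field estimation and unwarping

`estimate_field` minimizes

    sum_mask [ push(b0_ref; d) - b0_d ]^2 + lambda * sum ||grad d||^2

over the voxelwise shift `d` (voxel units along the PE axis), where
`push` is the same mass-preserving splat the simulator uses and `b0_ref`
is the synthesized (zero-readout) reference.  Three numerical choices
matter:

1. **Initialization by 1D mass transport.**  Along each PE line the
   pushforward is exactly a transport of positive mass, so matching the
   cumulative intensity profiles of reference and distorted lines (the
   monotone rearrangement between the two line measures) yields a
   closed-form per-line displacement estimate.  This global, basin-free
   initialization is what lets the local optimizer work on displacement
   magnitudes well beyond a voxel.  Lines with negligible mass start at
   zero.
2. **Scale-space, not decimation.**  Block-averaging along the PE axis
   destroys the very signal being estimated (sub-voxel to few-voxel
   shifts), so the pyramid blurs both images with Gaussians (factor f
   gives sigma f/2 along the PE axis, f/4 transverse) while the field
   stays at full grid resolution; each level widens the quadratic basin
   for the warm start of the next.
3. **Damped Gauss-Newton.**  The splat's Jacobian with respect to each
   voxel's shift has exactly two nonzeros, so the normal equations
   (JtMJ + lambda L + mu I) are sparse; they are solved by
   Jacobi-preconditioned conjugate gradients, with Levenberg damping mu
   adapted so that only cost-decreasing steps are accepted — the
   per-level cost trace is non-increasing by construction.

The smoothness weight defaults to lambda = 0.01 (images are internally
scaled by the distorted volume's 99th percentile so the residual is O(1)).
The value was fixed by an L-curve on the simulation suite: recovery error
against the known truth field is flat between roughly 0.003 and 0.03 and
rises steeply above 0.1, where the regularizer visibly shrinks the
estimate (masked SD of the recovered field falls below the truth's).
It is a per-run constant, never auto-tuned per subject, for determinism.

`unwarp` applies the estimated correction as the pullback
`x -> x + d(x)` with Jacobian intensity modulation `1 + dd/dx`, clamped
below at 0.05: inside pileup cores the forward map is non-invertible and
the true Jacobian crosses zero; the clamp keeps the modulation positive
and bounded there at the cost of not fully resolving intensity in those
few voxels.

`correct_subject` chains smoothness matching, estimation and unwarping,
and writes the two-row acqparams table for external-tool use.

## Evaluation

Mutual information between a b0 and the T1 — 64 equal-width bins per
image over the masked intensity ranges by default, natural logarithm — is
the geometric-similarity proxy: distortion misplaces tissue relative to
the T1 and lowers MI, correction restores it.  Absolute MI values depend
on the estimator (bin count, mask, units) and are not comparable across
implementations; the package therefore only ever interprets within-run
contrasts (corrected vs uncorrected on the same mask and bins).  Masked
MSE against the gold standard — in simulation, the true undistorted b0 —
measures correction plus contrast accuracy jointly.  `evaluate_cohort`
reports per-subject values, the fraction of subjects improved, and a
two-sided paired t-test on the MI differences.

## Problem sizes and what the tests show

The test suite and the acceptance script run the pipeline at reduced
scale, chosen once as the package's desk profile:

* module tests use 32^3 single subjects;
* field-recovery properties use twenty 48^3 subjects with smooth fields
  (no hotspots) — recovery inside deliberately non-invertible pileup
  cores is ill-posed for any estimator and is not asserted;
* the end-to-end run trains the reduced U-Net (2 levels, 8 base channels)
  on thirty 16^3 subjects with mixed blip counts for 20 epochs under the
  standard optimizer settings, evaluating on 5 withheld subjects with
  16-bin MI (the small mask bounds the usable bin count).

Passing these shows that every stage implements its stated contract and
that the composed pipeline improves geometric similarity on data drawn
from its own forward model.  It does not show clinical performance: real
brains have texture, partial-volume effects, bias fields and registration
error the simulator does not emulate, and the 16^3 training run is far
below the scale at which the synthesis network becomes anatomically
faithful.

## Known limitations

* The field estimator is a surrogate for topup: voxelwise first-order
  regularization instead of B-splines, no movement parameters, single
  image pair.  The emitted acqparams file is the escape hatch to the
  external tool.
* Pileup cores are corrected only up to the Jacobian clamp; signal
  genuinely collapsed into a fold cannot be redistributed by a pullback.
* The transport initialization assumes line mass is comparable between
  reference and distorted volumes; a gain mismatch between them must be
  removed first (`match_gain`).
* Real-data preprocessing (bias-field correction, template registration,
  skull stripping) is delegated to external tools and not modeled.
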