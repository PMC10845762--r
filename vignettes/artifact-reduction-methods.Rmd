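---
title: "Two-stage suppression of sparse-view and metal artifacts in specimen CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage suppression of sparse-view and metal artifacts in specimen CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinomar)
```

## The problem

Micro-CT of resected breast specimens is used in the operating room to
verify a tumour-free resection margin. Two practical constraints degrade
the images. First, the low-power micro-focus source makes a full
acquisition slow, and the natural remedy — scanning fewer projection
angles — produces streak artifacts from angular under-sampling. Second,
the lesion is localized pre-operatively with a metallic needle marker
that stays in the specimen; its extreme attenuation corrupts every ray
that crosses it and splashes bright/dark streaks across the
reconstruction.

`sinomar` implements a two-stage learned correction wrapped around the
classical metal-artifact-reduction (MAR) workflow:

1. **Sinogram domain.** The sparse scan is reconstructed once by filtered
   backprojection (FBP); metal is segmented there by thresholding and
   forward-projected to locate its track in the sinogram. The sinogram is
   up-sampled to the dense angular grid, the metal track is removed,
   missing entries are initialized by linear interpolation, and a
   *modified U-Net* synthesizes the missing data patch by patch.
2. **Image domain.** The completed sinogram is reconstructed by FBP and a
   *modified ResU-Net* removes the residual streaks. Finally the
   segmented metal is reinserted at its original pixels.

Because paired artifact/clean scans of the same specimen cannot be
acquired, training data are simulated: artifact-free phantoms are forward
projected, a metal wire is embedded, views are decimated (by 4 by
default, 360 to 90), and the corrupted data are paired with their known
ground truth.

## Geometry and the projector

All processing is per slice in 2-D parallel-beam geometry. The scanner's
cone-beam acquisition is not modelled: every algorithmic stage — metal
extraction, angular interpolation, patch networks, metrics — acts
identically on each slice, and the 2-D setting admits closed-form oracles
(the chord-length sinogram of a uniform disk) that pin the projector's
accuracy in tests. Cone-beam weighting, scatter, polychromatic spectra
and beam hardening are out of scope.

Conventions, chosen once and used everywhere: pixel `(1,1)` top-left,
isocenter at the grid center, `y` up; detector coordinate
`s = x cos θ + y sin θ` with `s = 0` at the detector center; angles
counter-clockwise from `+x`, views in increasing-angle order. The default
desk-scale geometry is a 128 px grid, 180 detector bins and 360 views at
1°; the full-resolution 512-bin scale is configurable but not the test
default.

The forward projector integrates along rays Joseph-style (unit steps
along the dominant axis, linear interpolation transversally). Its
contract is behavioural, not implementational: linearity, mass
conservation across views to better than 1%, and per-bin agreement with
the analytic disk sinogram. On the default grid a radius-56 px disk
projects with a maximum per-bin error below 2% of the sinogram peak; the
error concentrates at the tangent rays where the chord profile has a
square-root singularity, and shrinks as the grid is refined. The
projector's exact transpose is used as `A^T` inside iterative
reconstruction so the data-term gradient is a true gradient.

## Reconstruction

**FBP.** Projections are ramp-filtered in the frequency domain
(shepp-logan apodization by default, cutoff 1.0, matching the comparison
setting used for the clinical scanner) after zero-padding to twice the
detector length, then backprojected pixel-driven with linear detector
interpolation (an exact half-bin tie rounds toward the lower index).
Negative values are retained: the metrics operate on raw values.

One subtlety: a full 360° parallel-beam scan measures every ray direction
twice, so backprojection is weighted by `Δθ/2`; a 180° half scan measures
each once and is weighted by `Δθ`. This matters for the view-scaling
study below — over a 360° span, doubling 45 views at 8° to 90 views at 4°
adds only *mirrored* rays (`180° mod 8° = 4°`), reproducing the identical
reconstruction, which we verified numerically. View-doubling experiments
therefore run on the minimal complete 180° span, where each doubling
genuinely refines the angular sampling and the reconstruction error
decreases strictly.

**Iterative baseline.** The comparison reconstructor minimizes a
penalized weighted-least-squares objective: quadratic data fidelity plus
a Huber-type edge-preserving roughness penalty over 4-neighbour
differences, with the published comparison knobs (smoothness weight 150,
edge-preservation threshold 1e-5, 100 iterations) as the preset. The
named knobs fix the family but not the potential or optimizer; we chose
the Huber potential with monotone backtracking gradient descent because
it exposes exactly those knobs and guarantees a non-increasing objective,
which the tests assert. Noise weighting `W` is the identity (the
projection-count weighting of a real scanner is not modelled). This
reconstructor is a baseline, not part of the proposed pipeline.

## Metal handling

Metal is segmented in the image domain with a `≥` threshold. On simulated
data the default threshold — midway between the wire attenuation (50) and
the soft-tissue maximum (≈0.45) — recovers the embedded mask exactly,
because the wire is rasterized binarily (a pixel is metal iff its center
is inside the wire). The metal-only image is forward projected and every
bin above a numerical epsilon belongs to the metal trace; by default the
trace is dilated by one detector bin, because threshold-based extraction
is inherently approximate at track edges and residual metal in the
sinogram degrades the completion stage more than a slightly wider gap
does. Removal only *flags* the trace invalid; values are never edited in
place. Reinsertion is a pixelwise selector, so the final image is
bit-exact equal to the segmented metal on its support.

## Sinogram completion

Missing data come in two shapes: whole views removed by decimation, and
metal-track gaps inside measured views. Linear interpolation fills the
gaps first along the detector direction within each view (two-point
bridging; edge gaps extend the nearest valid bin), then fills missing
views along the angular direction between measured views. Views are
periodic over 360°, so interpolation wraps across the last-to-first seam
— physically correct for a full parallel scan. On sinograms affine in the
view index the angular pass is exact to machine precision, which the
tests assert.

The modified U-Net then refines the initialization. At inference the
sinogram is tiled into overlapping 64-px patches (stride = half patch),
predictions are blended by uniform averaging, and — a deliberate
strengthening — only the originally missing entries are overwritten:
measured bins are restored verbatim, so data fidelity at the retained
samples is guaranteed by construction rather than learned.

## The two networks

Both architectures are encoder–decoders sharing two structural choices:
down-sampling is a 3×3 convolution with stride 2 (never max-pooling), so
the reduction itself is learned and detail-preserving; and the input is
added to the final layer, so each network learns a residual correction
and a freshly initialized network (zeroed final projection) is *exactly*
the identity. They differ in how encoder detail reaches the decoder: the
sinogram U-Net concatenates encoder features channel-wise, while the
image ResU-Net adds them (additive cross-stage connections) and also
carries residual blocks within each stage.

Reference training scale (kept as presets): 64×64 sinogram patches,
180,000/18,000 train/validation, 100 epochs, Adam, learning rate 1e-5,
RMSE loss; 48×48 image patches, 458,640/80,000, 1300 epochs, learning
rate 1e-3. Layer counts, kernel sizes and activations are not fixed by
that description; we use 3×3 kernels, ReLU, no normalization layers, one
convolution per stage, depth 3 and 16 base channels by default — the
contribution is the structural modifications, not capacity.

Patch extraction samples positions with probability proportional to the
local input-target disagreement (mean absolute difference over the
patch), emulating the hand-selection of artifact-rich patches; a uniform
mode and user weights are available. Intensities are normalized to
`[0, 1]` by the training data's min/max, stored with the model and
re-applied at inference.

Training minimizes the batch RMSE `sqrt(mean((pred − target)^2))` with
Adam. The validation loss is evaluated *before* the first epoch and the
returned model carries the best-validation weights, so a trained residual
network is never worse on validation than the identity it started from —
a useful floor for the small training budgets below. All sampling is
seeded; under single-threaded execution training is bit-reproducible.

## The simulated study

Phantoms are two-class ellipse compositions: an adipose-like background
ellipse (attenuation 0.2) filling 70–90% of the field of view and 3–7
fibroglandular-like ellipses (≈0.4) inside it, with low-amplitude seeded
texture (σ = 0.01) so that similarity metrics are not degenerate on flat
regions; attenuations in arbitrary consistent units, roughly in the
proportion of soft-tissue contrast. The wire defaults to a 3 px disk of
attenuation 50 — two orders of magnitude above tissue, as for steel
against soft tissue; the reference wire geometry is not quantified
anywhere, so these are package choices, configurable. Projections are
noise-free by default (optional Gaussian line-integral noise exists but
the low-dose noise model is out of scope). No beam hardening is
simulated.

The desk-scale study used by the tests and the acceptance script: 8
training and 2 held-out cases at 128×128/360 views, ×4 decimation; the
sinogram U-Net (depth 2, 8 base channels) trained on 512+64 patches for
20 epochs at learning rate 1e-3; the image ResU-Net (same capacity) on
384+48 patches for 12 epochs. The learning rate is three orders above the
reference sinogram-stage value because with ~350× fewer patches per epoch
the update count shrinks accordingly; these sizes keep a full study in
minutes on one CPU. At this budget the sinogram network's gain over
linear interpolation is marginal — the initialization is already very
accurate on piecewise-smooth phantoms, and depending on the held-out
draw the held-out RMSE moves by fractions of a percent in either
direction, while the best-validation selection guarantees the model is
never worse than its identity initialization on validation data. The
image network learns more visibly (validation loss drops by several
percent) and the full pipeline scores at or above the
linear-interpolation baseline on held-out SSIM, CNR and PSNR. The
cluster-scale presets are available for larger runs. What passing at
desk scale shows is that the pipeline is wired correctly and that
learning moves in the right direction — not that the clinical-scale
improvements are reproduced:
the simulated phantoms lack beam hardening, scatter, detector blur, real
anatomy and real noise.

## Evaluation

RMSE, PSNR (peak taken as the maximum over both images, not a bit-depth
constant; identical images report `Inf`), SSIM and CNR. SSIM is a
*single-window* statistic computed from the global means, population
variances and covariance, with stabilizers `k1 = 0.001`, `k2 = 0.03`
entering the formula directly; this "literal" reading is the default
because it is what the formula states, and the conventional scaling
`c = (kL)^2` with `L` the reference dynamic range is available as
`mode = "scaled"`. CNR is the fibroglandular-vs-adipose contrast over the
pooled standard deviation, sign-preserving, with a guarded 0/0 → 0 case.
Line profiles are sampled bilinearly. Image-domain metrics evaluate
against the metal-embedded artifact-free image, so metal reinsertion is
scored as part of the result; a metal-free reference is equally available
(`gt_image`).

## Numerical choices and degenerate inputs

* Filter response: zero at DC and above `cutoff × f_Nyquist`; the
  shepp-logan sinc window closes exactly at the cutoff.
* FBP backprojection tie-break at an exact half-bin: lower index.
* Completion requires at least one measured view; a wholly invalid
  sinogram raises an error rather than guessing.
* RMSE-loss gradient at exactly zero loss is defined as zero.
* PWLS halves its step until the objective decreases; forty failed
  halvings raise a divergence error with diagnostics.
* `n_bins` must cover the inscribed circle of the grid (hard error);
  covering the full diagonal is only warned about, because simulated
  specimens live inside the inscribed circle and the reference-scale
  512-bin detector against a 300 px grid has the same property.

## Known limitations

2-D parallel geometry rather than cone-beam; no beam hardening, scatter,
or detector physics; ellipse phantoms are a crude stand-in for anatomy;
the desk-scale training budgets demonstrate direction, not clinical
effect sizes; SSIM's literal stabilizers make its absolute values
dependent on the intensity scale (use `mode = "scaled"` for
scale-invariant comparisons across differently scaled data).
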