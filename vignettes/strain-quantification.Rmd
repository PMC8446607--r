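---
title: "Myocardial strain quantification from cine-MRI: models, losses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Myocardial strain quantification from cine-MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Myocardial strain measures the percent change in length of heart muscle per
unit length over the cardiac cycle. Unlike the ejection fraction, which only
summarizes cavity volume change, strain resolves *where* and *in which
direction* the myocardium deforms, and it detects dysfunction earlier in
several diseases. Short-axis cine-MRI shows the beating heart with excellent
anatomical contrast but carries no intrinsic tissue markers, so deformation
must be inferred by registering the end-diastolic (ED) frame to every other
frame of the cycle.

`cinestrain` implements a complete, automated workflow for this task:

1. **Centering** — a small convolutional network (here called the centering
   network) regresses a Gaussian heatmap whose mode marks the LV myocardial
   centre of mass on the common 256 × 256 × 16 workspace grid (1.25 mm
   in-plane). The input is cropped to 128 × 128 × 16 around the argmax.
2. **Segmentation** — a per-slice 2D network produces four-class tissue
   probabilities (background, right ventricle, LV myocardium, LV cavity).
   Segmentations are *not* used for motion inference; they provide the
   cardiac coordinate system, the regional map, volumetric indices, and an
   anatomical constraint at training time only.
3. **Motion estimation** — a 3D network consumes the concatenated (ED,
   frame t) pair and emits a dense 3-channel displacement field `u_t` in
   voxel units, trained without motion ground truth.
4. **Strain engine** — deterministic post-processing turns `u_t` into the
   Green-Lagrange tensor `E = (∇u + ∇uᵀ + ∇uᵀ∇u)/2`, projects it onto
   per-voxel radial/circumferential/longitudinal directions, averages it
   globally and per AHA segment, interpolates to a 1 ms grid, and extracts
   end-systolic strain (ESS) and peak systolic/early-diastolic strain rates
   (SRs, SRe).

## The motion objective

The motion network is trained unsupervised with a three-term loss,

* an **intensity term**: the mean absolute difference between the ED frame
  and the moving frame warped by `u` (trilinear spatial transformer,
  clamp-to-edge borders),
* an **anatomical term**: a soft multi-class Dice loss between the ED
  segmentation and the warped moving segmentation (one-hot channels warped
  independently so the term stays differentiable),
* a **smoothness term**: a diffusion regularizer `Σ‖∇u·dr‖²`, where each
  directional derivative is scaled by the voxel spacing of its axis, so
  anisotropic slice spacing is penalized consistently,

combined as `λ_i L_i + λ_a L_a + λ_s L_s` with defaults
`λ = (0.01, 0.5, 0.1)`. Identity pairs (ED, ED) are included in training so
the network learns the zero displacement; ED-ES pairs carry the deformation
signal. With the through-plane kernel extent `kz = 1` (the default), every
convolution, pooling and upscaling acts in-plane only; through-plane context
enters exclusively through the trilinear warps of the loss and the 3D
gradient of the smoothness term. This respects the strongly anisotropic and
variable slice spacing of short-axis stacks.

Two loss conventions needed a decision:

* **Dice with four classes.** The multi-class Dice loss averages the per-class
  terms over all four classes, so perfect agreement scores −1. A class absent
  from both masks contributes a term of 1: absence agreed on is not an error,
  and the convention avoids 0/0.
* **Sum vs mean in the smoothness term.** The diffusion regularizer is
  written as a sum over the domain; the implementation defaults to the mean
  (with a `reduce = "sum"` switch) so that `λ_s = 0.1` keeps the same meaning
  across grid sizes. The default weights were chosen with the mean
  convention.

## The phantom: study substrate with closed-form truth

Real cine-MRI with ground-truth motion does not exist, so the package ships
an analytic left-ventricle phantom used both as a training substrate and as
an oracle:

* an annular myocardium (default endo/epi radii 25/35 mm) contracts so that
  the endocardial radius shrinks by the fraction `a·s(t)` (`a = 0.2` by
  default) and the wall preserves its cross-sectional area exactly
  (`r′² = r_endo(t)² + r² − r_endo(0)²`), the 2D form of incompressible
  myocardium;
* each slice additionally rotates by `twist_per_slice · z · s(t)`
  (1.5°/slice by default, ~10° base-to-apex differential — a physiological
  twist), which adds shear but leaves the radial/circumferential diagonals
  of `E` unchanged;
* the activation `s(t)` is a sin² pulse, time-warped so its single peak lands
  at `es_fraction = 0.4` of a 1000 ms cycle;
* the ED image is piecewise-constant tissue contrast plus a smooth *material*
  texture (amplitude 0.15) that advects with the tissue — this is what the
  intensity loss can latch onto — plus per-frame Gaussian noise
  (sd 0.02, non-advected), and frame t is rendered by pulling the ED image
  back through the inverse map, so the standard motion-estimation convention
  `V_0(v) ≈ V_t(v + u_t(v))` holds by construction.

The resulting closed forms, `E_cc = ((r′/r)² − 1)/2` and
`E_rr = ((r/r′)² − 1)/2`, satisfy `(1 + 2E_rr)(1 + 2E_cc) = 1` and give the
canonical check: at `a = 0.2` the endocardium moves 25 → 20 mm at peak, so
endocardial `E_cc = −0.18`.

What the phantom deliberately does *not* model: MR physics (coil profiles,
k-space sampling, banding is available only as a crude optional stripe),
papillary muscles, longitudinal shortening, respiratory motion, and the
patient-derived motion variability of real cohorts. Passing the phantom
recovery tests therefore demonstrates that the estimation machinery and its
losses work as specified — not that clinical accuracy on real scanners is
achieved, which requires real training cohorts at full scale.

## Desk-scale study conditions

All self-contained experiments run at *desk scale*: a 64 × 64 × 8 working
grid at 2.5 mm in-plane / 10 mm slices (half the full working resolution),
10 training phantoms with varied anatomy (endo radius 22–28 mm, wall to
33–38 mm, contraction 15–25%, twist 1–2°/slice, in-plane position jitter),
giving 20 training pairs (ED-ED + ED-ES each), and 5 held-out phantoms. The
motion network trains for 200 epochs with batch size 5; segmentation for 50
epochs and centering for 30 epochs with batch size 80. Adam moments are
(0.9, 0.999) throughout.

The full-scale step size of 1e-4 presumes tens of thousands of optimizer
steps; at 200 epochs × 4 batches there are only 800. The desk-scale default
step size is therefore 2e-3, scaled to the step budget — this is a
configuration default of the reduced protocol, with 1e-4 remaining the
documented full-scale value. Networks at desk scale use base width 6 and
two resolution levels; the full-scale default is base 16 with three levels.
Augmentation (in-plane rotation ±15°, translation ±10 voxels, x/y
mirroring, gamma 0.7–1.4) is implemented and tested but disabled in the
desk protocol, where the corpus variability already comes from the
generator.

The centering network is the exception to the common working grid: it
trains and infers on a half-resolution workspace (64 × 64 × 8 at 5 mm
in-plane, three resolution levels). Localizing the LV is a low-frequency
task, and at the coarser spacing the small network's receptive field covers
the whole heart; at full resolution with only ~10² optimizer steps it
degenerates to predicting the mean location. Detected centres are mapped
back to the input grid through the centre-aligned resampling.

Under these conditions the held-out phantoms show: median in-wall
end-point error ≈ 1–1.4 voxels for the ED→ES field, identity-pair median
displacement well below one voxel, mean global ESS biases of ≈ 1–4 strain
points depending on the corpus draw (harder anatomy draws sit at the upper
end), myocardial Dice ≈ 0.87–0.94, and centering error ≈ 1–1.8 voxels of
the centering grid — the quantities recomputed by `scripts/acceptance.R`
and asserted (at their fixed seeds) by the acceptance tests. Training with
`λ_a = 0` reproduces the qualitative ablation result: the anatomical
constraint materially reduces end-point error.

## Numerical choices

* **Axes and units.** Arrays are indexed (x, y, z), 0-based in voxel
  arithmetic; displacement fields are stored in voxel units of their grid
  and converted to mm (via the spacing) only inside the strain engine and
  landmark evaluation. The identity motion is the all-zero field.
* **Gradients.** Central differences, one-sided at array borders. They are
  exact for linear fields, which makes the rigid-rotation and isotropic
  scaling checks exact rather than approximate.
* **Strain reference.** Strain is computed on the ED grid from the forward
  field and averaged over the ED myocardial mask; `u_0` is defined as zero
  so strain(0) = 0. Whether to average over ED or per-frame warped masks is
  genuinely open; the ED mask was chosen because the field is defined on ED
  coordinates.
* **Oracle comparisons at tissue interfaces.** The analytic map has
  derivative kinks at the endo- and epicardial interfaces, and central
  differences straddling them produce a localized artifact. The package's
  `global_strain()` averages the full mask (matching its contract); at the
  working resolution the full-mask oracle error stays below 0.01. The
  helper `wall_interior()` is provided for boundary-free comparisons.
* **Interpolation.** Strain curves are interpolated linearly to a 1 ms grid
  (configurable upstream of the call); the strain rate uses central
  differences on that grid and is reported in 1/s. Peak detection at 40 ms
  frame spacing attenuates a sinusoidal peak by ~1.5% (secant effect), which
  is visible in tests that use denser sampling.
* **Ties and degenerate inputs.** Heatmap argmax ties break to the lowest
  linear index; ES detection ties break to the earliest frame and a constant
  cavity volume warns and returns ED; an empty class in the Dice loss scores
  as perfect agreement on absence; probabilities are clipped at 1e-7 in the
  cross-entropy.
* **AHA map conventions.** 16 segments (no apical cap — no long-axis data):
  slices containing myocardium are split into basal/mid/apical thirds
  (remainder to basal, then mid; slice 1 is basal), 6 × 60° sectors starting
  at the anterior RV insertion (septal angle + 90°) for basal/mid rings and
  4 × 90° sectors offset 45° apically. The 16- vs 17-segment choice and the
  insertion convention are documented package decisions where the standard
  leaves short-axis-only analyses ambiguous.
* **Determinism.** One master seed fans out to weight initialization, data
  order and augmentation; training twice with the same seed reproduces the
  loss history bit-for-bit in a fixed-threading session, and inference is
  deterministic given fixed weights.

## Repeatability statistics

The evaluation module implements the statistics used for validation and
test-retest studies: Dice and exact boundary Hausdorff distance (mm),
volumetrics (EDV/ESV/EF, LV mass at 1.05 g/mL), in-plane landmark end-point
error and its ES-frame average over subjects and observers, Bland-Altman
bias/precision (mean and n−1 standard deviation of paired differences),
single-rating absolute-agreement two-way ICC — ICC(A,1) with the F-based 95%
interval, cross-checked against an independent statistics package on a fixed
worked table — and relative/absolute relative change with the first
acquisition as reference.

## Known limitations

* Supplement-level architecture details (exact layer counts and widths) are
  not public; the encoder-decoder here is a faithful family (conv +
  batch-norm + PReLU with residual blocks, in-plane pooling for `kz = 1`)
  with configurable width/depth, not a layer-for-layer replica.
* The through-plane aggregation of the intensity/anatomical losses warps on
  the native grid; no intermediate z-upsampling factor is applied.
* Longitudinal strain is out of scope (short-axis data only), as are
  tagging-MRI analysis methods and clinical cohort comparisons.
* Desk-scale results quantify correctness of the machinery on the phantom
  family; clinical performance claims require full-scale training on real
  cohorts.
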