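---
title: "Registration-corrected adversarial CBCT-to-sCT translation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registration-corrected adversarial CBCT-to-sCT translation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cone-beam CT (CBCT) acquired on the treatment couch is the workhorse image
of adaptive radiotherapy, but scatter and reconstruction artifacts make its
Hounsfield units (HU) unreliable for dose calculation. A synthetic CT (sCT)
predicted from the CBCT restores CT-grade intensities on the current
anatomy. The catch for supervised learning is that the planning CT (pCT)
used as the training label was acquired days or weeks earlier: the patient's
anatomy has changed, so the label is *spatially misaligned* with the input.
Training a translator with a plain pixel loss against such labels teaches it
to hedge between geometries and produces blurred, biased outputs.

## The model

`reggan()` fits three networks jointly:

* a **generator** `G` (ResNet-style: 7×7 stem, two stride-2 downsampling
  blocks, `n_residual_blocks` residual blocks, two stride-2 transposed
  convolutions, 7×7 head with tanh) translating a normalized CBCT slice `x`
  into an sCT `G(x)` in `[-1, 1]`;
* a **registration network** `R` (U-Net over the channel-concatenation of
  `G(x)` and the label `ỹ`) emitting a dense displacement field in pixel
  units, with a zero-initialized final convolution so the field starts as
  the identity;
* a **patch discriminator** `D` (four 4×4 convolutions; stride 2, 2, 2, 1)
  scoring local patches real (1) or generated (0).

The key assumption is the label-noise model `ỹ = y ∘ T`: the observed label
is the true, intensity-correct label resampled by an unknown smooth
deformation `T`. Under this assumption the translation objective becomes

* **correction loss** — `mean | ỹ − G(x) ∘ R(G(x), ỹ) |`: the generator
  output is warped by the fitted field before the L1 comparison, so `R`
  absorbs the geometric discrepancy and `G` is supervised on intensity only;
* **smoothness loss** — a penalty on the spatial gradient of the field,
  keeping `R` from "cheating" by synthesizing intensity through
  non-physical deformations;
* **adversarial loss** — least-squares patch terms
  (`d_term = mean((D(ỹ)−1)²)/2 + mean(D(G(x))²)/2`,
  `g_term = mean((D(G(x))−1)²)`), sharpening the output distribution.

Per batch the discriminator is stepped first on its own term, then `G` and
`R` are stepped jointly on the weighted sum. At inference only `G` runs:
`translate()`/`predict()` clip to the HU window, normalize, resample to the
training grid, apply `G`, invert the normalization and resample back.

### Warping operator

`warp()` is bilinear resampling at `p + field(p)` with border clamping, and
is differentiable in both the image and the field. Border clamping (rather
than padding with air) avoids spurious −1000 HU rims entering the losses at
the field's edge. Displacements are in pixels, (row, col) ordered, on
whatever grid the field matches; multiply by `spacing` for mm.

### Smoothness normalization

The smoothness penalty is the sum over the two displacement components and
two grid directions of the *mean squared forward difference*. Under this
normalization a constant field scores 0 and a field whose row component
grows by one pixel per row scores exactly 1, which makes the weight
interpretable across grid sizes.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| HU window | [−1000, 2000] HU | clip range before normalization; keeps dense bone from dominating the loss |
| `image_size` | 256 px | square training grid; toy phantom studies use 64 |
| `learning_rate` | 1e-4 | Adam step for all three networks |
| `adam_betas` | (0.5, 0.999) | GAN-style low β₁ |
| `batch_size` | 1 | gradient-accumulation batch |
| `weight_decay` | 1e-4 | uniform L2 decay in the full fit |
| `epochs` | 80 | reference regime; toy runs use about 5 |
| `loss_weights` | (1, 1, 1) | printed unweighted sum; see below |
| generator `base_channels` / `n_residual_blocks` | 64 / 9 | reference capacity |
| registration `encoder_depth` / `base_channels` | 4 / 16 | U-Net shape |
| discriminator `n_layers` / `kernel_size` / `base_channels` | 4 / 4 / 64 | patch field of view |

Two deliberate deviations from the reference defaults apply to the scaled
study runs shipped in the tests and acceptance script:

* **Loss weights (20, 1, 1).** The unweighted sum is the printed objective,
  but at toy scale the correction term (≈0.03–0.1 in normalized units) is
  an order of magnitude smaller than the adversarial term, and training at
  (1, 1, 1) lets the GAN dominate before the translator has learned the
  intensity map. Up-weighting the correction term to 20 — the conventional
  L1:adversarial ratio for paired translation — makes short runs converge.
* **Registration-only fits** (`train_registration()`) default to a wider
  U-Net (base 32), learning rate 1e-3 and *no* weight decay: decay shrinks
  the zero-initialized field head back toward the identity transform, which
  systematically biases displacement magnitudes low in a fit whose entire
  point is the field. The full adversarial fit keeps the reference 1e-4
  decay since there the decay acts mostly on `G` and `D`.

## The phantom simulator

No public dataset accompanies the clinical study design this package
exercises, so `make_dataset()` synthesizes paired slices with known ground
truth:

* **anatomy** — background air at −1000 HU, an elliptical soft-tissue head
  (40 HU), an enclosing bone ring (700 HU), optional interior air cavities;
  geometry jittered per sample (`shape_jitter`, fraction);
* **acquisition degradation** — per accelerator profile: global HU shift,
  radial cupping bias `amplitude · (r/r_max)²` (the canonical low-frequency
  scatter artifact), Gaussian blur, additive Gaussian noise;
* **anatomy change** — a random smooth deformation (Gaussian-smoothed white
  noise rescaled to a stated maximum displacement) applied *before* the
  intensity degradation, so the spatial error and the intensity error are
  independent, exactly as the `ỹ = y ∘ T` noise model assumes;
* a final clip to [−1000, 2000] HU.

The four built-in profiles (`halcyon`, `trilogy`, `vitalbeam`, `synergy`)
are qualitative: `synergy` is parameterized as by far the most degraded
(HU shift −250, moving the soft-tissue peak from ≈70 toward ≈−220), the
Varian-style profiles moderately and similarly degraded, mirroring the
clinically reported severity ordering. The exact numbers are configuration
defaults, not claims about the scanners. A master seed maps to per-sample
seeds by a fixed affine rule, so any sample is reproducible in isolation.

What the simulator does **not** emulate: anthropomorphic anatomy, physically
modeled scatter or beam hardening, 3-D cone-beam reconstruction, metal
artifacts, and the FOV/resolution mismatches of real scanners. Passing the
toy studies therefore demonstrates that the training scheme works as
specified — the registration network absorbs label misalignment and the
translator corrects accelerator-specific intensity corruption — not that
clinical image quality figures would be reproduced.

## Study sizes used by the tests and acceptance script

Chosen to exercise the full method at desk scale:

* **end-to-end toy study** — 200 pairs at 64×64 cycling all four profiles;
  160 train / 40 held out (10 per profile, matching the per-accelerator
  test-arm size of the motivating clinical design); 5 epochs, learning rate
  5e-4, generator base 24 with 3 residual blocks, registration and
  discriminator base 16, weights (20, 1, 1). Success direction: held-out
  group mean MAE(sCT, pCT) < MAE(CBCT, pCT) for *every* profile.
* **registration recovery** — 10 pairs `(y, y ∘ T)` at 64×64, `T` of 5 px
  amplitude and 8 px smoothness; 2000 iterations of the registration-only
  fit must cut the mean correction loss by at least 80% from its zero-field
  value.
* **metric and DVH oracles** — brute-force loop implementations on random
  16×16 images; exhaustive sorted-voxel order statistics on grids ≤ 10×10.
* **null calibration** — 1000 simulated null datasets (4 groups × 10) for
  the Kruskal–Wallis wrapper; rejection rate expected near α = 0.05.

## Numerical choices

* **Metric conventions.** The published formula set for this family of
  studies prints an MSE whose square sits outside the absolute-difference
  sum, i.e. (MAE)²; that cannot be the MSE that PSNR needs, so `mse()` is
  the standard mean of squared differences. PSNR uses log base 10 (dB) with
  the reference image's maximum as the default peak, overridable by the
  window span (3000 HU) for cross-case comparability. `ssim()` defaults to
  the *global-statistics* form (means, variances, cross-covariance over the
  whole image, constants `(0.01L)²`, `(0.03L)²`), with the usual 11×11
  Gaussian windowed variant available; the cross-covariance reading of the
  numerator term is the standard resolution of the formula's notation.
* **Metrics are computed on clipped HU**, after exact denormalization; the
  restricted-range histogram discards voxels outside [−500, 500] HU before
  normalizing counts, since the air background otherwise dominates.
* **D_p convention.** `dose_at_volume()` returns the largest dose received
  by at least p% of the PTV (the standard radiotherapy reading), via a
  1000-bin cumulative DVH with linear interpolation; interpolated values
  are clamped into the attained dose range, so discretization can never
  push D₉₈ below the voxel minimum. Dmin/Dmax are raw voxel extremes.
* **Discriminator strides.** Four stride-4 4×4 layers would collapse a
  256×256 input to a single score, contradicting a patch map; strides
  2, 2, 2, 1 yield a 31×31 map at 256×256.
* **Label convention** real = 1 / fake = 0, with the least-squares GAN
  objective (stable at batch size 1 and standard with patch
  discriminators).
* **Resampling** is bilinear everywhere (training-grid resizing and
  warping), pixel-center convention, so the two operators are consistent.
* **Degenerate inputs** are rejected with configuration errors (windows
  with `lo ≥ hi`, non-positive smoothing scales, empty masks, empty
  datasets); an all-out-of-range histogram returns an explicit empty flag;
  PSNR of identical images is `Inf`, flagged rather than thrown.
* **Determinism.** All randomness flows from explicit seeds (dataset
  seeds, `train_config(seed)`); repeated runs on one machine reproduce loss
  trajectories bit for bit.

## Known limitations

* 2-D slices only, matching the slice-wise processing of the reference
  regime; no 3-D context.
* The compute engine is a compact CPU implementation (im2col/GEMM
  convolutions with hand-derived gradients); it is exact but not fast, so
  reference-scale settings (256×256, base 64, 80 epochs) are impractical
  on a laptop — the defaults document the regime rather than promise its
  runtime.
* Dose grids are synthetic or user-supplied; there is no treatment-planning
  dose engine, so clinical dose-difference tables cannot be reproduced,
  only the DVH/Dr machinery validated.
* Checkpoint selection uses lowest validation MAE, a pragmatic invention;
  alternatives (adversarial metrics, SSIM) are not explored.
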