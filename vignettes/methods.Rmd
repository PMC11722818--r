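---
title: "Correcting MVCT truncation artifacts with a synthetic-MV prior: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting MVCT truncation artifacts with a synthetic-MV prior: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Megavoltage CT (MVCT) guidance scans in tomotherapy cover a scan field of
view (sFOV) of about 40 cm, while diagnostic kilovoltage CT (KVCT) covers
50-70 cm. A patient cross-section wider than the sFOV truncates the
projection data: every profile ends abruptly at the detector edge, the ramp
filter of filtered back-projection (FBP) turns that step into a bright rim
("blooming") just inside the sFOV boundary, and all anatomy outside the
sFOV is simply missing. Both effects degrade registration against the
planning KVCT and block MVCT-based adaptive replanning.

This package implements a three-stage correction on synthetic data:

1. **Water-cylinder extrapolation (WCE).** Each truncated projection edge
   is extended with the chord profile of a water-equivalent cylinder fitted
   to the boundary value and slope; FBP of the extended sinogram gives the
   pre-corrected image `I_prec`.
2. **KV-to-MV translation (TransNet).** A contrastive-learning GAN maps the
   planning kV slice of the same anatomy into a synthetic MV (sMV) image,
   aligning the intensity scales so the kV anatomy can serve as a prior.
3. **Window-attention inpainting (FOV-Net).** A Swin-transformer U-shaped
   network fuses `I_prec` and the rigidly registered sMV prior into the
   extended-FOV image, removing the residual rim artifact and filling in
   the anatomy beyond the sFOV.

## Water-cylinder extrapolation

For a uniform cylinder of radius $R$ and water attenuation $\mu_w$, the
projection profile is the chord length $p(t) = 2\mu_w\sqrt{R^2-(t-c)^2}$.
Given the projection magnitude $p$ and slope $s$ at a truncation edge, the
cylinder that matches both is

$$x = \frac{s\,p}{4\mu_w^2}, \qquad R = \sqrt{\frac{p^2}{4\mu_w^2} + x^2},$$

with $x$ the signed offset from the edge to the cylinder centre. The filled
channels continue the profile with the fitted chords, clipped at zero, and
the per-view projection mass $\sum_k p_{v,k}\,\Delta t$ - constant across
views for a parallel beam - is restored where the cut removed it
(`mass_consistency()` exposes the diagnostic).

**Estimator choice.** The formula needs $p$ and $s$ *at the edge*; with
discrete noisy samples both must be estimated. `edge_stats()` provides the
plain least-squares line over the `n_fit = 3` innermost measured channels.
The WCE fill itself uses an equivalent but better-conditioned form: since
$s\,p = \tfrac12 (p^2)'$ and $p^2$ is exactly quadratic in $t$ for a
cylinder, a least-squares line on $p^2$ over the same window estimates the
magnitude/slope pair exactly on noise-free cylinder data at any truncation
depth, including views where the cut grazes the rim and the derivative of
$p$ itself diverges. This is why the fitted $(x, R)$ reproduce an
off-centre water disc to fractions of a percent in every affected view
(see `fit_cylinders()` and the acceptance tests).

**Feathering.** For non-cylindrical objects the fill meets the measured
profile with a small mismatch; a cosine ramp over `feather = 4` channels
carries that mismatch into the fill so the profile stays continuous. On a
true water cylinder the mismatch is zero and feathering is a no-op.

The symmetric-mirror baseline (`extrapolate_symmetric()`) reflects the
measured samples about the truncation boundary and tapers linearly to zero
at the detector end.

## Geometry and reconstruction

The projector computes line integrals by ray-driven sampling with bilinear
interpolation at half-pixel steps; the reconstruction is ramp-filtered
back-projection with cosine apodization (the discrete ramp kernel in the
spatial domain, applied by FFT). The default geometry is parallel-beam,
for which the WCE math and the mass diagnostic are exact; an equiangular
fan beam is available behind the same interface (full 360-degree scans,
source-axis distance configurable). Pixel centres sit at half-integer
offsets from the image centre and the isocentre is the image centre, so
projection and reconstruction share one coordinate convention.

Accuracy at the scales used here: projecting and reconstructing a uniform
disc recovers the interior attenuation to well under 1%; a 256 x 256
phantom at 360 views round-trips with masked RMSE below 3% of the peak
attenuation. Zero-filling the truncated channels before FBP reproduces the
characteristic blooming: the annulus just inside the sFOV boundary
reconstructs systematically brighter than the truth.

## The phantom family

Real paired kV/MV patient slices are not distributable, so the package
generates them. A phantom is a set of ellipses (body with a fat rim and
soft-tissue interior, optional lungs, bones, soft-tissue lesions) painted
onto a 96 x 96 canvas at 4 mm spacing (384 mm field; a 256 x 256 / 1.5 mm
configuration of the same physical extent is used for reconstruction
tests). Bodies are drawn wide (semi-axes 150-180 mm) so that moderate
detector truncation cuts into them.

**The kV/MV intensity relation.** The two modalities share identical
geometry and differ only in intensity. Body-tissue MV values are placed on
the regression line $\mathrm{MV} = 0.70\,\mathrm{KV} - 288.56$ (air stays
-1000 in both), with independent per-modality noise (SD 12 HU) added
inside the body. Placing the tissues on the line makes the body-pixel
regression of MV on KV reproduce slope 0.70 and a negative intercept by
construction for *every* phantom, independent of the tissue mixture - a
property a blended or piecewise map cannot provide, since the regression
of a mixture then drifts with the lung/bone fractions. The package adopts
the convention that the reference MV values are regressed on the kV (or
synthetic-MV) values; the identity line (slope 1) is the target for a
perfect translation. A side effect of the linear placement is that MV
soft tissue sits near -260 HU rather than 0; the synthetic MV scale is
internally consistent (water maps to 0 only on the kV side), and all
evaluations are relative to the synthetic MV ground truth.

Body masks come from thresholding (default -300 HU; the MV-domain pipeline
uses -500 HU because fat on the synthetic MV scale sits near -360),
keeping the largest connected component and filling holes, which retains
lungs and removes table-like satellites. Affine augmentation (joint
rotation/translation/scale with -1000 fill) matches the preprocessing the
method expects.

## TransNet: contrastive kV-to-MV translation

The generator is a fully convolutional encoder (7x7 stem, two stride-2
stages), residual bottleneck, and nearest-neighbour-upsampling decoder
with instance normalisation and a tanh output over the HU window
[-1024, 1500] mapped to [-1, 1]. The discriminator is a patch-level
critic. Training couples three losses with unit weights:

* an adversarial loss - least-squares targets by default (stable for
  small desk-scale runs), with the classical form
  $\mathbb{E}[\log D(y)] + \mathbb{E}[\log(1 - D(G(x)))]$ available as
  `gan_flavor = "vanilla"` (non-saturating generator term);
* the **PatchNCE loss**: for queries drawn from the translated image's
  encoder features and positives at the identical spatial position in the
  input's features, an $(N{+}1)$-way cross-entropy
  $\ell = -\log \frac{e^{v\cdot v^+/\tau}}{e^{v\cdot v^+/\tau} +
  \sum_n e^{v\cdot v_n^-/\tau}}$ over unit-normalised projections
  (two-layer MLP heads, $\tau = 0.07$), averaged over five encoder taps
  (the input image and four interior layers) and the sampled positions;
* the same PatchNCE loss applied to target-domain images as a learnable
  identity loss.

During training the negatives for each query are the other sampled
positions of the same image (so `n_negatives = n_positions - 1`), the
standard internal-negatives formulation; the exported
`sample_nce_vectors()` also supports explicit negative counts. Training
is unpaired throughout: kV and MV slices are drawn independently, and
64 x 64 random crops keep the desk-scale step cheap.

## FOV-Net: window-attention inpainting

The pre-corrected image and the registered prior are concatenated as two
channels, split into non-overlapping 4x4 patches and linearly embedded
(512 x 512 x 2 inputs embed to 128 x 128 x 48 tokens in the full-scale
configuration; the desk scale uses 96 x 96 inputs, embed width 24 and
window 4, giving 24 x 24 tokens). Each resolution level runs pairs of
Swin blocks - LayerNorm, window attention, residual, LayerNorm, two-layer
MLP (GELU), residual - alternating plain W-MSA with the shifted variant
(shift $M/2$, cyclic roll, additive mask that blocks attention across the
toroidal seam). Attention within each $M^2$-token window is

$$\mathrm{Attention}(Q,K,V) = \mathrm{SoftMax}(QK^T/\sqrt{d} + B)\,V,$$

with $B$ looked up from a learnable table indexed by the $(2M-1)^2$
relative offsets (the standard table; a published index-range description
of $(2M{+}1)\times(2M{-}1)$ is treated as a typo for this). Patch-merging
(2x2 concatenation + linear, $C \to 2C$) and patch-expansion (linear +
pixel shuffle, $C \to C/2$) move between levels; decoder levels receive
the encoder skip by concatenation followed by a linear fusion.

Two design points matter for training at desk scale:

* **Absolute positional embedding.** A learnable positional table is added
  to the token grid after embedding. The sFOV boundary is a fixed spatial
  structure, and relative-position bias alone gives windows no absolute
  anchor to locate it; without the embedding the network cannot cheaply
  condition its behaviour on "inside vs outside the scan FOV".
* **Input skip and residual head.** The full two-channel input is
  skip-fed to the final linear layer, and the output is predicted as a
  residual on the pre-corrected channel. Zeroing the head therefore turns
  the network into the identity on `I_prec` (a probe the tests use); the
  default initialisation draws the head near - but not at - zero so that
  gradients reach the transformer stages from the first step.
* **FOV-aware head.** The scan FOV is exactly known at inference from the
  scanner geometry, so the head additionally receives the ring indicator
  (1 outside the sFOV disc) and its products with the two input channels.
  The in-FOV/extended-FOV blend is a multiplicative interaction that a
  linear head cannot otherwise express; making it explicit keeps the
  measured interior untouched while the annulus is inpainted. With the
  indicator fed as zeros the head reduces to the plain input skip.

**Training loss.** The reconstruction loss is the L1 norm
$\lVert I_\mathrm{eFOV} - I_\mathrm{gt}\rVert_1$. Consistent with
background-removed training data (the clinical preprocessing this method
assumes), the desk pipeline evaluates it over body pixels only and weights
the extended-FOV annulus (body pixels beyond the sFOV disc, known at
training time from the scan geometry) five-fold. Without the body
restriction most of the gradient is spent cleaning reconstruction noise in
the air background, and without the annulus weighting the inpainting
signal - a few percent of body pixels - is swamped by the irreducible
reconstruction-noise residual inside the sFOV.

## Rigid registration and evaluation

The sMV prior is rigidly registered (rotation + translation) to `I_prec`
by maximising normalized cross-correlation: a coarse multi-start grid
followed by Nelder-Mead refinement, with bilinear resampling and -1000
fill. On phantoms, randomized perturbations up to 10 px / 10 degrees are
recovered to about 0.01 px / 0.03 degrees. After registration the prior
is affinely recalibrated against `I_prec` over in-FOV body pixels: inside
the scan FOV both images live on the MV scale, so an ordinary
least-squares fit estimates - and removes - any residual global intensity
error of the translator using only information available at inference.

MAE, RMSE and SSIM are computed inside the sFOV disc, inside the eFOV
annulus, and over the whole body. SSIM uses an 11 x 11 Gaussian window
(sigma 1.5) and constants $c_1 = (0.01L)^2$, $c_2 = (0.03L)^2$ with
dynamic range $L$ spanning the HU window (2524). The HU regression
(ordinary least squares of reference MV on the translated image inside the
body) summarises intensity fidelity: raw kV regresses on MV with slope
0.70 by construction; a successful translation moves the slope toward 1.

## Desk-scale study conditions and schedules

The published training schedules (400 epochs at batch 1 and learning rate
2e-4 with linear decay for the translator; 100 epochs at batch 8 with
decay over the last 20% for the inpainter) are preserved in the
`"clinical"`/`"full"` presets. The desk-scale presets are sized for a
single CPU: 200 phantoms (160 training / 40 held out), 600 translator
steps and 1400 inpainter steps, learning rates 1e-3 and 5e-3. The higher
desk rates are deliberate: with Adam the cumulative parameter movement is
bounded by (steps x learning rate), and the head weights that blend the
prior into the output are of order one, unreachable in a few hundred steps
at 2e-4. Rates were chosen for the desk budget, not tuned per seed.

What the synthetic study does and does not show: the phantom family
reproduces the *structure* of the clinical problem (paired modalities with
a fixed intensity relation, bodies wider than the sFOV, thresholdable
masks, truncation blooming) but not its difficulty - elliptical anatomy is
far more predictable than patient anatomy, reconstruction noise is mild,
and the translation map is exactly linear. Passing orderings at desk scale
demonstrate that the pipeline's components compose correctly, not that the
clinical error magnitudes would be reproduced.

## Numerical choices and degenerate inputs

* Truncation levels are interpreted as channels removed per side
  (symmetric truncation); the desk default cuts 30 of 144 channels.
* A zero projection magnitude at a truncation edge yields the degenerate
  zero cylinder (no extrapolation); a single usable edge sample falls back
  to the symmetric-apex cylinder.
* Truncated channels are zero-filled before FBP in the uncorrected
  baseline.
* The rigid registration warns (rather than fails) on constant images.
* All randomness flows through R's RNG from explicit seeds; per-stage
  seeds are derived from one master seed, and phantom generation is
  bit-reproducible from `(spec, seed)`.

## Known limitations

* Parallel-beam geometry carries the exactness guarantees; the fan-beam
  path is validated to the few-percent level only.
* The sinogram container serializes as RDS (with an optional JSON geometry
  sidecar) rather than a cross-language format.
* The contrastive translator is trained at a scale where GAN variance
  across seeds is visible; the regression slope of the prior typically
  lands between 0.85 and 1.15, and its pixelwise error (~100 HU in the
  annulus after calibration) remains well above what a fully trained
  clinical-scale translator would achieve.
* Because the L1-trained inpainter outputs a conditional median, its
  annulus is smooth: mean absolute error improves dramatically over the
  water-cylinder fill, but local-structure similarity (SSIM) of the
  network output can stay below the WCE reconstruction, whose fill is
  intensity-wrong yet boundary-sharp. A pixel-faithful prior makes
  "copy the prior" the L1 optimum and restores sharpness; the desk-scale
  GAN prior is not faithful enough for that, so the effect should be read
  as a property of the training scale, not of the architecture.
* Truncation removes only the laterally-cut rays; the annulus is still
  crossed by measured rays at other view angles, so the pre-corrected
  image retains much of the annulus information and a no-prior variant of
  the inpainter is a strong baseline on mean error (it lags on RMSE and
  structural similarity, where the prior's anatomy helps).
* No scatter, beam hardening, or helical geometry; 2D slices only.
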