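---
title: "Methods: simulated 3D photoacoustic breast imaging and learned artifact removal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated 3D photoacoustic breast imaging and learned artifact removal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, conventions and numerical choices behind
`pabreast`. The package simulates 3D photoacoustic tomography (PAT) of the
breast with a hemispherical detector array and trains a 3D residual U-Net to
remove the streak-like artifacts that appear when only a small fraction of
the array's elements is used for acquisition.

## The imaging chain

Pulsed near-infrared light (757 nm) is absorbed by tissue chromophores —
dominantly hemoglobin — causing thermoelastic expansion that launches
ultrasound. The initial acoustic pressure is

$$ p_0(\mathbf r) \;=\; \Gamma\, \mu_a(\mathbf r)\, \phi(\mathbf r), $$

with $\mu_a$ the absorption coefficient, $\phi$ the optical fluence and
$\Gamma$ the Grüneisen parameter, folded into a global constant of 1 here
(only relative image values matter downstream, and every reconstruction is
min-max normalized before scoring). The chain is: digital phantom →
photon-transport Monte Carlo → $p_0$ → acoustic forward model → band-limited
per-element channel data → delay-and-sum (DAS) image → Res-UNet restoration.

## Digital breast phantom

The generator is procedural, not an anatomical model: it reproduces the
seven tissue classes (air, fat, skin, glands, muscle, fiber, vein), the
prone half-ellipsoid geometry and a heterogeneously dense composition, which
is what the downstream physics consumes.

* Half-ellipsoid breast (default semi-axes 36 × 30 × 32 mm) in prone
  orientation on a 3 mm muscle slab at the chest-wall face; the coronal
  (x–y) plane faces the illumination, +z points from chest wall to nipple.
* A closed 1.5 mm skin shell between air and interior tissue.
* Gland/fat partition: a smoothed Gaussian noise field (coarse lattice,
  trilinear interpolation) thresholded at the quantile that realizes the
  target gland volume fraction, default 0.339 (heterogeneously dense). The
  quantile calibration makes the realized fraction essentially exact before
  vessels and fibers carve a few voxels out of both compartments.
* Vasculature: a recursive binary branching tree of cylinders from a root
  at the chest-wall center (root diameter 2.5 mm, per-generation taper
  0.78, random branching angles of 20–55°), rasterized by stamping spheres
  along each centerline at half-voxel steps so the tree is 26-connected by
  construction. Branch endpoints are kept inside the skin margin.
* Fibers: thin random strands (radius 0.3 mm); muscle: a full slab.

All randomness flows through one seed; identical (seed, grid, parameters)
give bitwise-identical volumes. The default grid is 359 × 287 × 153 voxels
at 0.25 mm pitch. Optical properties at 757 nm (absorption, scattering,
Henyey–Greenstein anisotropy per class) are attached by per-voxel lookup;
vein is by far the strongest absorber (4 cm⁻¹ vs 0.13–0.62 cm⁻¹ for the
soft-tissue classes), which is what makes PAT a vascular imaging modality.

## Photon-transport Monte Carlo

A voxel Monte Carlo in the MCML tradition: photon packets enter as a flat
circular beam (default radius 1.2 cm) normal to the illuminated face, take
steps of optical depth $-\ln \xi$, traverse voxel boundaries by DDA ray
marching, deposit the weight fraction $\mu_a/(\mu_a+\mu_s)$ of their weight
at each interaction, scatter into a direction drawn from the
Henyey–Greenstein phase function, and terminate by Russian roulette
(threshold $10^{-4}$, survival probability 0.1) or on leaving the grid.
Conventions worth stating:

* Fluence is derived as deposition divided by $\mu_a$ (zero where
  $\mu_a = 0$), so the identity $A = \mu_a \phi$ holds voxel-wise exactly.
* The energy audit is exact bookkeeping: launched = absorbed + escaped +
  (roulette-killed − roulette-gained) up to float rounding; with the
  default roulette parameters the roulette net is far below the $10^{-3}$
  tolerance asserted in the tests.
* Refractive-index mismatch (Fresnel reflection) is ignored; the water
  coupling gap is simply a non-absorbing, non-scattering region (air label
  properties are $10^{-12}$, effectively transparent).
* In the scattering-free limit the sampled absorption depth is exactly
  exponential, so Beer–Lambert agreement is tested against binomial
  per-slab counting statistics rather than an ad-hoc tolerance.

## Array geometry and acoustic forward model

The detector is a hemispherical bowl of radius 4.8 cm with elements placed
on a Fibonacci spiral lattice restricted to one side of the equatorial
plane — a standard construction for quasi-uniform point sets on the sphere
(nearest-neighbor spacing CV well under 0.15 at n = 5120). The spiral index
is the canonical ordering; "equidistant" under-sampling takes
`round((0:(k-1)) * n/k)` along it, which reproduces plain strides for counts
that divide n (every 20th element for 256 of 5120, every 10th for 512) and
records parent indices so sub-array channel data can be extracted from a
dense simulation by row subsetting.

The medium is homogeneous and lossless (c = 1500 m/s, no attenuation), so
the forward solution is exact: each element's trace is the arrival-time
histogram of source voxels with spherical-spreading weight
$p_0 / (4\pi d)$, linearly split between the two neighboring samples,
followed by the time derivative. The derivative carries the
back-projection sign convention ($-\partial_t$) and is discretized as a
forward difference, which places the positive extremum of the bipolar
transient exactly at $t = d/c$; with a centered difference the DAS
point-spread function would be antisymmetric (zero at the source) and a
point source would not localize. Detection applies a zero-phase Gaussian
band-pass with unit gain at 2.5 MHz and −6 dB (half amplitude) at
$f_0 (1 \pm 0.35)$ (70% fractional bandwidth). Sampling is 20 MHz — at
least 4× the upper band edge — with the record length chosen from the
farthest voxel–element distance. Elements are ideal points: at 2.5 MHz a
one-voxel element has negligible directivity.

## Reconstruction and volume preparation

Signal conditioning is a zero-phase Butterworth-magnitude low-pass (default
4 MHz, order 4, unit DC gain), applied in the frequency domain. DAS then
sums, for every voxel, each element's trace at the voxel-specific time of
flight with linear interpolation — unweighted, unapodized, negatives
retained (the transients are bipolar; no envelope step is used).
Reconstructions are left unnormalized; amplitudes therefore scale with the
element count, and every volume is min-max scaled individually before
metrics are computed.

Preparation for learning mirrors the acquisition protocol: crop to
310 × 310 × 128 voxels about the region of interest (default: the intensity
centroid of the dense volume; the same window is reused for its sparse
partners), then reduce the coronal plane 2× with antialiased Catmull–Rom
bicubic interpolation (kernel support widened by the scale factor, weights
renormalized), giving 155 × 155 × 128. Sparse/dense pairs are normalized by
the affine map that takes the *dense* volume's range to [0, 1]; the sparse
member shares that scale, so the network sees the true amplitude deficit of
under-sampled DAS. At pure inference time, with no dense partner, a volume
is scaled by its own range.

Training patches are random 96³ crops with random flips along the two
coronal in-plane axes (probability 0.5 each), identical window and flips on
both members. Validation/test volumes are tiled into overlapping 96³
patches at equal stride with the last patch flush to the boundary (default
in-plane overlap 37 voxels, the value implied by 155 vs 96), and network
outputs are re-assembled by Gaussian-weighted averaging with a separable
window of σ = patch/4, strictly positive at the patch edges — positivity is
what guarantees the tile-then-stitch identity that patch-wise inference
relies on.

## Res-UNet

The basic module is 3×3×3 convolution → batch normalization → LeakyReLU
(slope 0.01). Each unit is two basic modules plus a residual shortcut: a
3×3×3 convolution of the unit input added to the unit output. The encoder
stacks such units with 2×2×2 max pooling between levels; the decoder uses
2×2×2 transposed convolutions, concatenates the same-scale encoder features
(the classic U-Net copy-and-concatenate; the encoder–decoder skip style is
otherwise unspecified in the sources this package follows), and applies a
unit per level. A final basic module and a 1×1×1 convolution compress to
one channel, and the input is added element-wise (global skip), so the
network learns a residual correction — zeroing the final convolution gives
an exact identity, a property the tests exploit.

Defaults at full scale are 4 levels with 32 base channels doubling per
level; the desk-scale study uses 2 levels with 8 base channels. Weights are
He-normal ($\sigma^2 = 2/\mathrm{fan_in}$), biases zero, batch-norm scale
and shift 1 and 0. Batch statistics are used at training time, running
averages (momentum 0.1) in evaluation, which also makes evaluation-mode
outputs per-sample independent and repeatable. The engine is implemented on
dense GEMM kernels (im2col) in single precision with analytic backward
passes; the gradient of the transposed-input convolution is computed as a
forward convolution with the spatially flipped, channel-transposed kernel.

### Loss

$$ \mathcal L = 0.3\,\mathrm{MAE} + 0.7\,(1 - \text{MS-SSIM}) $$

MS-SSIM uses 3D Gaussian local windows (width 11, σ = 1.5, K₁ = 0.01,
K₂ = 0.03, symmetric boundary handling), contrast–structure terms at every
scale, the luminance term at the coarsest scale, and 2× average pooling
between scales. The standard five scale weights (0.0448, 0.2856, 0.3001,
0.2363, 0.1333) are renormalized to the number of scales the volume permits
— $(w-1)2^{s-1}+1 \le \min(\text{dim})$, i.e. 4 scales for 96³ patches, 2
for 24³–32³ desk-scale patches. Scale means are clamped at $10^{-8}$ before
exponentiation so the value (and the loss) stays defined when a
contrast–structure mean goes negative. The loss gradient is analytic; the
Gaussian filter is used as its own adjoint, exact in the interior and an
approximation within half a window of the boundary — the tests verify the
full gradient against finite differences. The same MS-SSIM engine serves as
the evaluation metric, avoiding metric drift between training and scoring.

### Optimization

Adam (β = 0.9/0.999) with learning rate 0.0025, weight decay 0.001 (added
to gradients), batch size 3, up to 300 epochs at full scale, and early
stopping on the validation loss with patience 20 and minimum improvement
$10^{-4}$. Random cropping expands the training set: two random patches are
drawn per training volume per epoch (`patches_per_volume`); the validation
loss is computed on a fixed seeded set of four patches per validation
volume, which keeps the early-stopping signal stable when the validation
split is small. The best-validation weights are kept; a non-finite training
loss aborts with the last finite weights.

## Evaluation

3D PSNR is $10 \log_{10}(\text{range}^2/\mathrm{MSE})$ with range 1 on the
normalized volumes and a documented cap of 100 dB at zero MSE. The sparsity
sweep reports per-count test-set means for sparse-vs-dense and
network-vs-dense, plus relative improvements
$(\text{dnn} - \text{sparse})/\text{sparse} \times 100$. One network is
trained per sparsity level by default, matching per-count reporting;
training across levels is a caller choice (train on pairs pooled from
several counts).

## The desk-scale study

Full-scale conditions (140 phantoms at 359 × 287 × 153, 5120 elements, 300
GPU epochs) are not a workstation workload, so the package fixes a reduced
study used by its acceptance tests and by `scripts/acceptance.R`:

* 20 phantoms on a 128 × 128 × 64 grid at 0.5 mm pitch (semi-axes
  22 × 20 × 22 mm), 2 × 10⁵ photon packets each;
* a 1024-element dense hemisphere (R = 4.8 cm), training pairs at 128
  elements (12.5% under-sampling), sparse-only sweep at {64, 128, 256};
* reconstruction on a breast-centered 96 × 96 × 64 grid, ROI pipeline
  yielding 48 × 48 × 64 paired volumes;
* a reduced Res-UNet (2 levels, 8 base channels), 24³ training patches, 50
  epochs, split 16/2/2.

These sizes were chosen once, as the smallest configuration in which the
under-sampling artifacts, the network capacity and the test-set evaluation
remain meaningful on a single CPU core in minutes; they are study
conditions, not tuning knobs.

## What the synthetic data does and does not show

The generator emulates the geometry and optics of a dense breast but not
anatomical microstructure (ducts, ligaments), lesion insertion, multiple
density classes, heterogeneous speed of sound, acoustic attenuation,
electronic noise, or the domain gap to clinical data — the forward and
inverse models share the same homogeneous medium, so reconstruction errors
here come from band-limiting, sparse angular sampling and Monte-Carlo
noise only. Passing tests therefore demonstrate correctness of the physics
conventions and the learning machinery, and that the network removes
under-sampling artifacts *within this simulation family*; they do not
certify performance on real tomographs.

## Known limitations

* The MS-SSIM boundary adjoint is approximate (see above); gradients are
  exact elsewhere.
* Pure-tone amplitudes quoted for the zero-phase filters assume records
  long enough that spectral leakage is negligible.
* The Monte Carlo ignores polarization, fluorescence and refraction;
  photons are launched normally to the face (collimated beam).
* `evaluate_sweep` reports means over the test split; with the desk-scale
  split (2 test phantoms) those means carry visible sampling noise, which
  is why the sweep monotonicity check allows a small tolerance.
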