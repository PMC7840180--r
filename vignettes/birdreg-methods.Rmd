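---
title: "Bi-channel mutual-information registration of whole-brain stacks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bi-channel mutual-information registration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Whole-brain volumetric microscopy (serial two-photon tomography, or
light-sheet imaging of cleared tissue) produces anisotropic stacks —
typically 1 × 1 × 10 µm³ voxels over hundreds of gigabytes — that must be
brought into register with a standardized atlas (an average template plus
an integer annotation volume, e.g. a common-coordinate-framework
distribution at 20 µm isotropic resolution) before any region-wise
quantification is possible. Two obstacles make this hard:

1. **Shape**: brains are physically sectioned, cleared (with shrinkage),
   or compressed, so the anterior–posterior (AP) axis is stretched
   *non-uniformly* — a single global resampling ratio cannot rectify the
   stack.
2. **Appearance**: the sample and the template come from different
   modalities. Intensity relationships are nonlinear and
   non-monotone in places, and much of the anatomically informative
   structure (ventricles, fibre tracts, region outlines) is *dim* in the
   raw channel.

`birdreg` implements a registration pipeline that addresses both: a
landmark-driven dynamic z-resampling that rectifies the AP axis
sub-stack by sub-stack, and a *bi-channel* registration in which the raw
image is complemented by an assistant feature channel — a grayscale
reversal map (geometry/outline) and a phase-congruency map
(edge/texture) — all driving a single weighted mutual-information cost.

# Preprocessing: dynamic z-resampling

The user marks K+1 corresponding coronal planes between the reference
atlas (plate indices $a_i$, at 100 µm intervals) and the raw stack
(slice indices $b_i$). Because the average template stack is sampled at
20 µm, plate $a_i$ sits at template layer

$$c_i = 5a_i - 2 .$$

Sub-stack $k$ (between planes $k$ and $k+1$) is then resampled along z
with its own step

$$l_k = \frac{b_{k+1}-b_k}{c_{k+1}-c_k} \quad \text{raw slices per output slice},$$

by linear interpolation at raw positions $b_k + j\,l_k$. The output
depth of sub-stack $k$ is exactly $c_{k+1}-c_k$ regardless of how the
raw depth was distributed, so the concatenated stack has template
z-geometry by construction. The reciprocal output/input ratio
$(c_{k+1}-c_k)/(b_{k+1}-b_k)$ is reported in the `resample_recipe` as a
diagnostic; for 10 µm raw data it hovers around 0.35–0.55 across the
brain instead of sitting at the uniform 0.5 that a fixed ratio would
assume. The resampling itself consumes the input-per-output step $l_k$;
both conventions are exposed because they are easy to confuse.

Laterally the stack is reduced by block-mean averaging (factor 20 for
1 µm data), which is also the anti-aliasing choice: at a 20× reduction a
plain decimation would alias high-frequency texture into the 20 µm grid.
Slices before the first and after the last landmark plane are discarded
— the landmark planes are chosen to bound the usable brain.
Interpolation for the z-step is linear; labels never pass through this
path (restoration back to native resolution is strictly
nearest-neighbour, see below).

# The assistant feature channel

Background is removed first: Huang's fuzzy threshold minimises the
fuzzy entropy $\sum_g h(g)\,S(\mu_t(g))$ with membership
$\mu_t(g) = 1/(1+|g-m_t(g)|/C)$, where $m_t(g)$ is the mean of the side
of the threshold $g$ falls on, $C$ the intensity range and $S$ the
Shannon pair entropy. The scan over candidate thresholds is exhaustive
and deterministic. Voxels below the threshold are zeroed and the
foreground mask is kept.

**Grayscale reversal** inverts intensities against the mask-wide
maximum (`max − I` inside the mask, 0 outside), turning dim outline
structure into high-intensity features with strong axial mutual
information.

**Phase congruency** (PC) marks points where the local Fourier
components are maximally in phase — a contrast-invariant detector of
edges, lines and texture. Per 2D coronal slice, a log-Gabor quadrature
bank (defaults: 4 scales, 6 orientations, minimum wavelength 3 voxels,
multiplier 2.1, bandwidth parameter 0.55) yields per-scale amplitudes
$A_n$ and phases $\phi_n$; the local energy is

$$E(x)=\sum_n A_n\left[\cos(\phi_n-\bar\phi) - |\sin(\phi_n-\bar\phi)|\right],$$

and the PC measure is

$$PC(x)=\frac{W(x)\,\lfloor |E(x)|-T\rfloor}{\sum_n A_n(x)+\varepsilon},$$

with $\lfloor\cdot\rfloor$ read as the positive part (energy below the
noise floor is discarded), $T$ estimated per orientation as `noise_k`
(default 2) times the median amplitude of the smallest-scale filter,
$W$ a sigmoid weighting of the filter-response spread, and
$\varepsilon = 0.01$ stabilising the denominator. Orientations are
summed and the volume rescaled to [0, 1]. Three implementation choices
matter in practice:

* intensities are normalised to unit range before filtering, so
  $\varepsilon$ acts on a consistent amplitude scale — this is what
  makes the map invariant to multiplicative intensity scaling (to well
  under 1% RMS);
* PC is computed per 2D slice, not in 3D: the anatomy that drives the
  registration lives in the coronal planes, and the slice axis is
  selectable;
* PC responses outside the foreground mask are suppressed. The
  log-Gabor filters ring several wavelengths into the zeroed
  background; those responses are artefacts of the background removal,
  not structure, and would otherwise dilute the channel.

# The bi-channel registration model

Registration estimates a transform $T_\mu$ mapping fixed-image
(sample) physical coordinates to moving-image (template) coordinates —
the pull-back direction, so the template and its annotation are
resampled *onto* the sample grid. The transform is a three-stage chain

$$T_\mu(x) = A\,(R\,(x)) + D(x),$$

with $R$ rigid (3 rotations + 3 translations), $A$ affine (12
parameters), and $D$ a cubic B-spline free-form displacement field
parameterised by a control-point lattice over the fixed domain
(spacing 30 fixed-image voxels at the finest level, scaled by the
pyramid factor at coarser levels, one-cell margin beyond the domain).
The deformable stage composes *additively* with the global stages: the
displacement is evaluated at the fixed-space point and added to the
globally aligned position. This keeps the analytic gradient of the
metric with respect to the lattice simple, and at the displacement
magnitudes this pipeline targets (a few voxels at 20 µm) the difference
from functional composition is negligible.

## The cost

Each of the N channels (raw, reversal, PC; N = 3 in the standard
configuration) contributes a negative mutual information

$$c_i(T_\mu) = -\sum_{f,m} p(f,m;T_\mu)\log_2\frac{p(f,m;T_\mu)}{p_F(f)\,p_M(m;T_\mu)},$$

estimated from a joint histogram over spatial samples of the fixed
image paired with transform-interpolated moving intensities (32 bins
per image). The combined cost is the weight-normalised mean
$\sum_i\omega_i c_i / \sum_i\omega_i$; the weights default to equal
(1, 1, 1) and are configurable — no published weighting exists, and on
the synthetic phantoms equal weights are never worse than raw-alone.

Two estimator variants are used deliberately:

* **hard binning** (Parzen order 0) for the rigid and affine stages and
  for all verification: it is exactly the discrete joint-histogram MI,
  is maximised at perfect alignment by construction, and is robust
  under finite differences;
* **cubic B-spline Parzen window** on the moving image for the
  B-spline stage, where the analytic gradient needs a differentiable
  kernel.

Spatial samples are drawn once per stage/level from a seeded RNG (8192
samples above 32³ voxels, every voxel below) and *jittered off the
voxel grid*. The jitter matters: with grid-aligned sampling the
smoothed estimator has an artefactual spike at configurations where
fixed and moving grids coincide exactly, and an optimiser will happily
walk off a perfect alignment to escape it. Sampling at off-grid
positions removes the degeneracy. The bin count also adapts to the
sample count (`max(8, min(n_bins, sqrt(n/4)))`): at the coarsest
pyramid level a few hundred samples cannot populate a 32 × 32 joint
histogram, and the MI of a mostly-empty histogram is noise that the
optimiser would otherwise overfit into large spurious rotations.

## Optimisation

Each stage is minimised by gradient descent over a five-level Gaussian
pyramid (smoothing $\sigma$ = factor/2 voxels with matched decimation;
a level is skipped if any image axis would fall below 8 voxels).
Gradients are central finite differences for the 6/12 global parameters
and analytic for the B-spline lattice (the standard Parzen-MI
derivative, with the *exact* spatial gradient of the trilinear
interpolant rather than a pre-smoothed gradient image, so
finite-difference checks agree to the 10⁻³ level away from domain
boundaries). Steps are normalised to the largest parameter change and
accepted only if they lower the cost by at least `min_improve`
(2 × 10⁻⁵ bits): an accepted step grows the rate by 1.5× (capped at 4×
the initial rate), a rejected step halves it. Consequences:

* the per-level cost trace is monotone non-increasing by construction,
  and the divergence guard (error if a level ends above its starting
  cost) is unreachable in normal operation;
* the `min_improve` threshold stops the optimiser from chasing
  sampling noise around a converged optimum — registering a volume to
  itself leaves 99% of displacements below a few hundredths of a
  voxel;
* rotations and affine matrix entries are rescaled by the domain
  radius so one internal unit ≈ 1 µm of boundary displacement for
  every parameter, making a single step length meaningful across
  parameter types.

Between B-spline levels the coarser field is carried over by sampling
it at the new control-point positions (values, not re-fitted
coefficients); the resulting slight smoothing is absorbed by the
subsequent optimisation.

# Annotation transfer, inversion and restoration

Labels are moved with nearest-neighbour interpolation only — linear
interpolation would fabricate label ids. The inverse direction
(rendering sample structures in template space) uses numeric inversion
of the fitted chain: a fixed-point iteration preconditioned by the
inverse of the global linear part, to 0.1 voxel by default, erroring if
more than 1% of points fail to converge. Restoration to the native
grid inverts the lateral block down-sampling and the per-sub-stack
reslicing by nearest-neighbour up-sampling using the recorded
`b`/`l_k` recipe.

Region surfaces for the 3D digital map are extracted by isosurfacing at
0.5 on a Gaussian-smoothed (σ = 1.2 voxels) binary mask of each label.
The extractor uses the tetrahedral decomposition of the voxel lattice
(Kuhn triangulation, six tetrahedra per cube sharing the main
diagonal): per-tetrahedron cases are unambiguous, shared-face diagonals
agree between neighbouring cells, and the resulting meshes are
watertight by construction — the classic cube-table variant can leak
through ambiguous saddle configurations. The pre-smoothing is what
makes mesh areas track the continuous region shape (a digitised sphere
of radius 10 voxels meshes to within 5% of $4\pi r^2$) rather than the
blocky voxel surface, at the cost of rounding genuinely sharp corners
by about a voxel.

# Evaluation metrics

* **POI distances**: Euclidean distance
  $\rho=\sqrt{(x_2-x_1)^2+(y_2-y_1)^2+(z_2-z_1)^2}$ between
  name-matched fiducials, with the median (MED) as the headline value.
* **Dice**: $2|A\cap B|/(|A|+|B|)$ per region; the both-empty case is
  an error, not a score. Medians over even counts are the mean of the
  middle pair.
* **STAPLE**: binary expectation–maximisation fusion of repeated
  manual segmentations (prior = mean rater foreground fraction,
  initial sensitivities/specificities 0.99, tolerance 10⁻⁶, at most
  100 iterations). Unanimous raters reproduce their mask within two
  iterations; an inverted rater is outvoted and exposed by an
  estimated sensitivity below 0.5. When the posterior stays near the
  prior the fit is flagged low-confidence. Fusion is per-region
  binary; multi-label STAPLE is out of scope.

# The synthetic phantom

Real whole-brain datasets run to hundreds of gigabytes, so every stage
is exercised on synthetic phantoms with known ground truth instead.
`make_atlas_phantom()` builds a lobed-ellipsoid "brain" of nested
labelled shells (default 4 regions) with per-region base intensities,
band-passed noise texture and softened edges, plus fiducials spread
over region boundaries. The lobe modulation mixes odd and even angular
orders deliberately: a modulation with a pure rotational symmetry
(e.g. `sin(2θ)` alone, which is invariant under a 180° flip) would make
the rigid stage ill-posed in a way no real brain is. `make_sample_from_atlas()` then applies, in
order: a random smooth cubic B-spline displacement field (coefficient
lattice ≈ a quarter of the volume across, amplitude scaled so the
maximum displacement is `deform_max` voxels — default 6 — and the
Jacobian determinant stays strictly positive, regenerating at reduced
amplitude otherwise); optional per-sub-stack z stretching with the
matching landmark table (the boundaries are placed so
$c_i = 5a_i - 2$ holds with equal sub-stack depths); a monotone
intensity remap (default $v^{0.7}$ on normalised intensities,
emulating the cross-modality transfer curve); and additive Gaussian
noise at `noise_sd` (default 0.1) of the dynamic range. The true chain
is returned in the same direction a fitted registration estimates
(sample frame → template frame), and the sample-frame fiducials are
obtained by tight numeric inversion, so target-registration errors and
Dice against the deformed labels are exact scores.

What the phantom does *not* emulate: optical point-spread anisotropy,
stitching seams, vignetting, non-monotone intensity relationships, and
anatomy whose texture statistics differ between modalities. Passing
the phantom suite therefore demonstrates the correctness of the
machinery and the advantage of the assistant channel under noise and
monotone modality change; it does not by itself establish accuracy
numbers on real brains.

# Problem sizes and defaults

Unit tests run on 16³–32³ phantoms; the end-to-end evaluation
(`scripts/acceptance.R` and the heavier test blocks) uses a 64³
phantom for translation recovery and a 128³ phantom for the full
deform–stretch–remap–register–annotate pipeline, the sizes the package
documents for desk-scale verification. On one CPU core the 128³
end-to-end run (feature extraction, three-stage five-level
registration, annotation warp, scoring) takes a few minutes.

# Known limitations

* The optimiser is a plain adaptive-step gradient descent; it has no
  stochastic averaging, so very coarse levels can stop at shallow
  local optima that finer levels must correct.
* The B-spline stage does not constrain the Jacobian; diffeomorphic
  behaviour is encouraged only by the multi-resolution schedule and
  step limits, not guaranteed.
* MI estimation assumes enough samples per histogram bin; a
  warning fires below `n_bins²/10` samples.
* Axis-role metadata is carried but not semantically enforced against
  the atlas: the loader lets the caller re-tag axes because on-disk
  axis order of atlas distributions varies.
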