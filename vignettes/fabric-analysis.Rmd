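---
title: "Quantifying cancellous bone fabric from CT stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cancellous bone fabric from CT stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cancellous` quantifies the directional architecture (*fabric*) of
cancellous (trabecular) bone in whole limb bones, from segmentation of the
raw CT stack through per-region fabric tensors to anatomically referenced
mean fabric directions, together with the statistical procedures used to
relate such measurements to body size and the closed-form torsional-buckling
relations used to interpret diaphyseal cross-bracing. This vignette explains
the models and the choices behind them; the README shows a worked example.

## The fabric tensor

Cancellous bone is a network of struts (trabeculae) whose preferential
alignment adapts to habitual loading. The directional arrangement within a
volume of interest (VOI) is summarised by a symmetric positive-definite
second-rank *fabric tensor* H with eigenvalues `e1 >= e2 >= e3 > 0` and
orthonormal eigenvectors `u1, u2, u3` — the primary, secondary and tertiary
fabric directions. The degree of anisotropy is `DA = e1/e3`; `DA = 1` is
isotropy, and for perfectly isotropic material the principal directions are
undefined (any basis diagonalises H).

Two directional measures are implemented:

* **Star volume distribution (SVD, the default).** `n_points` points are
  sampled uniformly within the bone phase of the VOI (4,000 by default, with
  replacement if fewer bone voxels exist, so the sample size is fixed
  regardless of VOI occupancy). From each point a bidirectional ray is cast
  along each test direction and the uninterrupted bone intercept length
  through the point is recorded, censored at the VOI sphere boundary (the
  censored fraction is reported per direction). The directional value used
  for tensor fitting is the cube root of the mean cubed intercept — the star
  length scale — which makes SVD and MIL commensurable.
* **Mean intercept length (MIL).** For each direction a parallel grid of
  test lines is laid through the VOI sphere and
  `MIL = total line length / number of bone–background crossings`.
  Directions whose grid meets no interface are censored to the VOI diameter
  and flagged. The phase sequence along each line is cleaned with a
  median-of-3 filter before crossings are counted: single-sample spikes are
  staircase artefacts of oblique rays crossing voxel surfaces, not real
  interfaces, and counting them biases MIL low in oblique directions.

Directions come from a Fibonacci lattice of `n = 2049` antipodally unique
unit vectors on a hemisphere — 2,049 is not an icosahedral-subdivision
count, so a quasi-uniform lattice is the natural construction — rotated
rigidly by a seeded random rotation so that no test direction is
systematically aligned with the voxel grid.

The tensor is obtained by least squares on the quadric
`n' M n = 1 / v(n)^2` (the standard MIL ellipsoid convention), and
`H = M^(-1/2)`, trace-normalised to 3 so that isotropy corresponds to the
identity. Directions in which the structure is long-ranged have large
`v(n)`, hence small `n' M n`, hence a large eigenvalue of H: `u1` points
along the dominant trabecular tract. A non-positive-definite fit (possible
only for degenerate inputs) is an error, not a silent repair. Eigenvalue
ties are resolved deterministically and every eigenvector is flipped so its
largest-magnitude component is positive — fabric directions are axes, so the
sign carries no meaning, and this makes repeated runs bit-identical.

## VOI sampling

Each fabric tensor describes one spherical VOI (spheres avoid corner
effects). VOIs tile the cancellous region as cubic close-packed spheres —
layered hexagonal sheets with ABC stacking along z, nearest-neighbour centre
distance exactly `2r` — so adjacent VOIs touch without overlap and no part
of the bone is analysed twice. The lattice can be rotated and translated;
placement was found not to alter results in the original protocol, and the
packing here defaults to [111] stacking along the bone's long axis.

A VOI is retained when at least 95% of its voxels lie in the cancellous
mask. The underlying protocol pruned peripheral VOIs manually, admitting "at
most minimal" cortical bone or medullary cavity; 95% is this package's
declared, reproducible surrogate for that judgement, not a replication
claim. Exclusion masks (cracks, deformation) remove any VOI whose overlap
with the mask exceeds a caller-chosen fraction.

The continuum rule requires the VOI diameter to span at least five mean
trabecular spacings for a fabric tensor to represent bulk behaviour;
`continuum_ok()` applies it with the spacing from `trabecular_spacing()`,
the mean local thickness of the background phase (largest-inscribed-sphere
definition, computed from the exact Euclidean distance transform with a
half-voxel surface offset, since the EDT measures to voxel centres rather
than the phase boundary).

## Segmentation protocols

Four protocols cover the scan regimes:

1. **Clean micro-CT.** Bernsen local thresholding: a voxel is bone iff the
   local contrast (max − min over a ball window, radius ~5 px) reaches the
   contrast threshold (20–50) *and* the voxel exceeds the local mid-grey.
   Low-contrast windows are assigned to background; with the threshold set
   high this keeps uniform dense non-bone material (dried marrow) out of
   the bone phase. Floating voxels are then removed by keeping the largest
   26-connected component — cancellous bone is a single connected network.
2. **Anisotropic medical CT.** The stack is first upsampled to triple the
   in-plane resolution and simultaneously made isotropic: with
   `f = slice thickness / pixel resolution`, the axial axis is resampled by
   `3f`. Resampling uses separable cubic convolution (the "bicubic" of
   common image tools); it adds no information but raises the local contrast
   available to the thresholding step, which partial-volume voxels otherwise
   defeat. Binary masks are resampled nearest-neighbour so they stay binary.
3. **Peripheral-QCT.** In-plane-only resampling to isotropic voxels at the
   slice thickness, a low-radius 3D median denoise, then protocol 1.
4. **Noisy scans of dense specimens.** Median background subtraction: a
   low-radius 3D median (radius 2–10 px) suppresses salt-and-pepper noise;
   a large-radius 2D median (10–40 px, large relative to the trabecular
   thickness), chained over all three slice orientations as a fast stand-in
   for a 3D median, estimates the low-frequency background (beam hardening,
   bulk-density drift). Their difference, clipped at zero, is smoothed with
   a low-radius 3D mean filter and thresholded globally. On data whose
   background subtracts to near zero a threshold of 1–2 grey values
   suffices; for the synthetic phantoms here the threshold scales with the
   phantom's bone grey value (45 for bone at 100).

All filter windows are discrete balls (discs for the 2D medians) with edge
replication, which keeps every filter constant-preserving at borders;
consequently protocol 4 is exactly invariant to adding a constant to the
input. Protocol parameters are per-specimen choices in practice (the
original workflow tuned them by iterative visual comparison); the defaults
here are tuned the same way against phantoms with known ground truth,
scoring by Dice overlap.

## Anatomical referencing

For femora, fabric is referenced in a bone-fixed frame: z is the principal
axis of inertia (+z proximal, sign fixed by a user-supplied proximal hint —
the original procedure resolved it visually); y is the normalised cross
product of z with the medial-to-lateral condyle-centre vector (+y anterior);
x completes the right-handed frame (+x lateral). Condyle centres come from
least-squares spheres (algebraic fit, then Gauss–Newton refinement) fitted
to user-delimited surface patches. The direction of the condyle vector is
not fixed by convention elsewhere, so this package declares medial→lateral,
which makes `z x c` anterior for a right femur. Left bones are mirrored
about their sagittal plane (the plane spanned by z and the anterior axis)
before frame construction; `express_in_frame()` applies the same mirror to
fabric axes, and a mirrored left twin then yields angles identical to its
right counterpart to numerical tolerance.

Mean fabric directions are vectorial means of per-VOI primary axes. Fabric
axes are sign-free, so each axis is first flipped into the hemisphere of the
running resultant and then, in a second pass, re-aligned to the first-pass
mean — the second pass removes the order dependence of the running
alignment. The mean is reported with the resultant length `R-bar` and as two
inclination angles: anterior inclination is the signed angle between +z and
the projection of the axis onto the sagittal (y–z) plane; medial inclination
is the analogue in the coronal plane, positive towards −x. Stereoplots use
the equal-angle (Wulff) projection, radius `tan(theta/2)` from the chosen
pole (northern or southern hemisphere), azimuth preserved.

## Statistics

Size relationships use **major axis regression** (the first principal axis
of the bivariate covariance), appropriate when both variables carry error.
Because residuals of such data are typically non-normal and heteroscedastic,
the slope is tested by **permutation** (100,000 replicates by default,
`p = (1 + #extreme) / (n_perm + 1)`). The permutation statistic is the
association |r| rather than the slope magnitude itself: the variances are
invariant under permutation of y, so |r| orders replicates exactly, whereas
|MA slope| is not monotone in association — it diverges towards the vertical
axis as the permuted correlation vanishes whenever `var(y) != var(x)`, which
would invert the test. This is the convention of the `lmodel2` lineage of
model II regression software.

Heteroscedasticity is checked with the **Breusch–Pagan** test (classical
ESS/2 form by default, matching PAST's default; the Koenker studentised
`n R^2` form is available via `studentize = TRUE`). Normality checking is a
visual QQ diagnostic (`residual_qq()`), with no automated decision.

Scorer reliability for the three categorical features of diaphyseal
cancellous bone (extent 0–3; orientation 0–8 in 10° bins; association 0–2)
uses **ICC(2,k)** — two-way random effects, average measures across k = 5
scorers — computed from the two-way mean squares; bones not scored
numerically by all scorers are dropped, and fewer than two complete rows is
an error (this genuinely occurs: a feature where almost every specimen has a
majority of "n/a" scores admits no ICC). Per-bone aggregation takes the mean
of numeric scores unless "n/a" scores outnumber them, in which case the bone
is "n/a"; a scorer who assigned feature 1 a zero did not score features 2–3,
and `aggregate_scores(..., feature1 =)` applies that gating.

## Torsional buckling

The buckling module evaluates the thin-walled-tube relations
`D = E t^3 / (12 (1 - nu^2))`, `tau_crit = k pi^2 D / (l^2 t)`,
`tau = T / (2 t A)` (`= 2T / (pi d^2 t)` for circular sections) and
`T_crit = K pi^3 d^2 t^3 / (2 l^2)` with `K = k E / (12 (1 - nu^2))`. It is
a calculator, not a validated predictor: no empirical `k` is supplied, and
validity assumes `t << d`. Units are SI; the identity chaining the first
three relations into the fourth holds to machine precision and is tested
over random parameter sweeps, as are the `d^2 t^3 / l^2` scaling laws. The
mechanical reading — buckling propensity grows with `l^2/d^2`, so small,
slender bones are the more buckling-prone, favouring internal cross-bracing
— motivates the diaphyseal scoring above.

## Synthetic phantoms: what they do and do not show

All tests run on generated phantoms with known truth:

* **Rod lattices** (parallel cylinders on a jittered square lattice) emulate
  strongly aligned trabecular tracts; truth: `u1` = rod axis. Defaults (rod
  radius 0.2 mm, pitch 1 mm, voxel 0.05 mm) give BV/TV ≈ 0.13 and rods 8
  voxels across — typical of avian proximal femora scanned by micro-CT.
* **Plate stacks** emulate plate-like trabeculae; truth: `u3` = plate
  normal, Tb.Sp = gap.
* **Connected scaffolds** (rods plus thinner transverse struts sharing the
  unjittered lattice) are the standard phantom for segmentation-recovery
  experiments: unlike the plain rod lattice, whose rods are mutually
  disconnected, they form the single connected network that
  largest-component cleaning presumes, as real cancellous bone does.
* **Boolean sphere unions** are the isotropy control (equal eigenvalues).
* **Pseudo-CT corruption** adds a smooth background field (sum of
  single-period sinusoids scaled to a stated peak-to-peak amplitude),
  salt-and-pepper impulses and optional Gaussian blur — the qualitative
  noise regime of low-voltage scans of dense fossils. The corruption
  parameters are free knobs: the original scans' noise spectra were never
  characterised quantitatively, so nothing here is calibrated to a specimen.
* **Bone phantoms** (shaft, two condylar spheres, rod-filled head) exercise
  the full anatomical chain; truth: long axis, condyle centres, fill axis.
* **Score tables and allometry samples** have specified variance components
  and optional heteroscedasticity for calibrating the statistics.

Passing tests therefore demonstrate correctness of the algorithms under
known geometry, controlled noise, and exactly satisfied assumptions
(connectedness, continuum scale). They do not demonstrate fidelity on real
scans, where noise is structured, trabeculae are curved and plate-rod mixed,
and segmentation parameters must be chosen per specimen.

## Numerical choices and problem sizes

* Grids are (slice, row, column) arrays mapping to world (z, y, x); voxel
  centres at `origin + index * spacing`; world direction vectors are (x, y, z).
* Ray marching steps half a voxel (SVD) or one voxel (MIL, whose statistic
  pools totals over the whole line grid and needs less density; the default
  line grid is 3 voxels). Intercepts are censored at the VOI sphere, not the
  image boundary.
* Every stochastic routine takes an explicit integer seed and uses a
  private RNG stream; the caller's `.Random.seed` is never touched. Same
  seed, same bits.
* Test problem sizes — 128³ fabric-recovery phantoms, 96³ segmentation and
  isotropy phantoms, 1,000-replicate type-I calibrations at 2,000
  permutations, a 0.25 mm whole-bone phantom — were chosen as the smallest
  sizes at which the geometric tolerances (5° axis recovery, Dice 0.90,
  DA ≤ 1.15, 20° ± 3° end-to-end) are comfortably meaningful.
* Rounding of synthetic categorical scores is half-up, for cross-platform
  reproducibility.

## Known limitations

* Numerical identity with any particular legacy implementation of the star
  volume distribution is not claimed — direction schemes and edge handling
  differ between implementations — only agreement with ground-truth
  phantoms.
* Local thickness by ridge sphere-drawing is exact up to voxelisation but
  inherits the open-boundary inflation of any inscribed-sphere definition:
  background regions touching the volume boundary admit oversized spheres,
  so spacing should be measured in interior regions.
* `principal_axis()` refuses near-degenerate inertia tensors (moment gap
  below 1%) instead of guessing; supply the axis manually for such shapes.
* The anatomical frame is defined for femora only.
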