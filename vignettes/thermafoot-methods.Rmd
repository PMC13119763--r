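---
title: "Quantitative thermography with a low-cost LWIR camera: models and methods"
author: "thermafoot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative thermography with a low-cost LWIR camera: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermafoot)
```

## The measurement problem

Uncooled microbolometer cameras in the 8-14 um long-wavelength infrared
(LWIR) band are cheap enough for routine bedside thermography of the
diabetic foot, where a bilateral temperature difference of about 2 degC is
a clinically meaningful signal. Getting quantitative temperatures out of
such a camera requires undoing, in order: the spatially varying
multiplicative sensitivity of the optics and detector (vignetting), the
non-linear Planck calibration of the sensor combined with atmospheric and
reflected-radiance terms, lens distortion, and the parallax between the
thermal sensor and the higher-resolution visible camera mounted a few
millimetres away. This package implements that chain, together with the
hybrid marker detection and constrained matching that register the visible
image onto the thermal frame, and a synthetic-scene simulator that
provides exact ground truth for every stage.

## Vignetting: a multiplicative gain in the radiometric domain

The measured radiometric signal is modelled as
$R(x,y,t) = G(x,y,t)\,R^\star(x,y,t)$ with a smooth, strictly positive
gain field $G$. Because the effect is multiplicative in radiance, the
correction happens in the radiometric domain, before the non-linear
temperature inversion: dividing temperatures instead would leave
level-dependent residuals over scenes spanning several degrees.

A gain model is estimated from flat-field epochs (the camera pressed
against cardboard): per epoch the pixelwise **median** over the $N_k$
frames (robust to hot pixels and transient reflections), an optional
symmetric quantile clamp at `[0.02, 0.98]`, Gaussian smoothing with
$\sigma$ in the 3-6 px range (default 4; small enough to preserve the
spatial structure of the gain, large enough to suppress residual noise),
normalization by the median (configurable to the mean) so the gain has
unit level, and a floor at $\varepsilon = 10^{-6}$.

Across epochs the pixelwise median gives a **master gain**; the decision
between the master and temporal interpolation is automatic: if the
maximum inter-epoch RMS of $\log(\hat G_i/\hat G_j)$ is at most 0.01
(a package choice; the log domain is the natural metric for
multiplicative fields), the vignetting is declared stable and the master
is used, otherwise the gain is interpolated **geometrically**,
$\hat G(t) = \hat G_j^{1-w}\hat G_{j+1}^{w}$, which is linear
interpolation of the log-gains and preserves positivity. No
extrapolation outside the calibration epochs is allowed.

Two details are worth flagging:

* *Boundary handling.* Gaussian smoothing uses replicate padding;
  circular convolution would darken the borders and masquerade as
  vignetting. Grayscale morphology (used later for detection) is also
  replicate-padded for the same reason.
* *The quantile clamp and simulated flats.* The clamp exists to suppress
  rare artefacts. On simulated flats there are no artefacts, and the
  synthetic gain (a planar tilt plus a radial quartic, amplitude 10%)
  places genuine smooth structure in the top and bottom 2% of the
  intensity distribution; clamping there clips real signal and inflates
  the gain error by roughly a factor five. The end-to-end accuracy
  experiment therefore builds its gains with `clamp = FALSE`, while the
  clinical default keeps the clamp on. This is a deliberate,
  documented asymmetry between the simulation and the bedside
  configuration.

## Radiometric inversion

The corrected signal is converted to temperature through the standard
radiometric chain for this camera family. With Planck calibration
constants $P_B, P_{R1}, P_{R2}, P_O, P_F$:

$$T = \frac{P_B}{\log\!\left(\frac{P_{R1}}{P_{R2}(R_\mathrm{object}+P_O)}+P_F\right)} - 273.15,$$

$$R_\mathrm{object} = \frac{\hat R^\star}{\epsilon\,\tau\,W_t}
  - R_\mathrm{atm} - R_\mathrm{opt} - R_\mathrm{refl},$$

where $\epsilon$ is the object emissivity (0.98 for skin in LWIR),
$W_t$ the window transmission, and the three path radiances are Planck
radiances of the air, window and reflected background with prefactors
$(1-\tau)/(\epsilon\tau)$, $(1-W_t)/(\epsilon\tau W_t)$ and
$(1-\epsilon)/\epsilon$. The atmospheric transmission is the
two-exponential model
$\tau = X\exp[-\sqrt d\,(\alpha_1+\beta_1\sqrt{W_p})] +
(1-X)\exp[-\sqrt d\,(\alpha_2+\beta_2\sqrt{W_p})]$
with the water-vapour pressure given by a cubic-exponential polynomial in
the air temperature (in Celsius) scaled by relative humidity.

Unit handling is centralized: the vapour-pressure polynomial takes
Celsius, the path radiances Kelvin, and "log" is the natural logarithm
(the convention of the underlying calibration literature). The composition
of square roots in the transmission model is typeset ambiguously in parts
of the literature; the package implements the square-root form of the
original reference and exposes `atmFormula = "linear"` for the literal
product form, so neither reading is silently discarded.

The package also provides the exact algebraic **forward model**
(`planckForward`) so simulated scenes are rendered through the same
physics the inversion undoes; the round trip is exact to better than
$10^{-9}$ degC across $[-20, 60]$ degC. Pixels whose radiance would imply
a non-positive absolute temperature raise an error naming the offending
pixels; they are never silently clipped.

Detector noise is parameterized by the noise-equivalent temperature
difference (NETD, 70 mK for this camera class) and converted to count
units through the local slope of the forward model, so the simulated
noise level is physically meaningful at any scene temperature.

## Marker detection

**Visible.** The 10 mm marker holes appear as white disks on matte black
strips. After luma conversion and subtraction of a large-scale Gaussian
background (default scale $4r$), the disk/ring contrast score
$S = \mu_\mathrm{disk} - \mu_\mathrm{ring}$ (disk radius $r \approx 5$ px,
ring width 5 px) is computed by convolution; candidates are local maxima
above 5 robust noise levels (MAD) with non-maximum suppression of radius
$r$. Each candidate is validated geometrically: Otsu segmentation of a
$(4r)^2$ neighbourhood, component area within $[0.4, 2.5]\,\pi r^2$,
circularity $4\pi A/P^2 \ge 0.7$, and minor/major axis ratio $\ge 0.75$.
The centre is the component centroid and the radius comes from the
equivalent-disk area. The circularity and axis-ratio thresholds are
engineering defaults (the underlying criteria are qualitative), exposed in
`visDetectConfig()`.

Perimeters use the Vossepoel-Smeulders corner-corrected chain-code
estimator (the regionprops-style convention), under which digitized disks
score circularity near or above 1 while elongated shapes fall well below
the thresholds; moderately elongated blobs that squeak past circularity
are caught by the axis-ratio test.

**Thermal.** In the LWIR frame a heated marker is a diffuse "thermal
hill" 10-15 px across, not a disk. The background is estimated by a
grayscale **opening** (erosion then dilation) with a disc structuring
element of radius about twice the expected marker radius (default 12 px);
the relief $T - T_\mathrm{bg}$ is non-negative by the anti-extensivity of
opening and contains only small-scale warm structure. The relief is
thresholded at $\Delta T_\mathrm{min} = 2$ degC, cleaned by area opening
(20 px), closing (disc radius 2) and hole filling, and 8-connected
components are kept when their area lies in
$[\alpha_\mathrm{min}\pi r_\mathrm{min}^2,
  \alpha_\mathrm{max}\pi r_\mathrm{max}^2]$ with
$\alpha_\mathrm{min} = 0.4$, $\alpha_\mathrm{max} = 2.5$,
$r \in [5, 7.5]$ px (about 31-442 px^2 -- the slack admits the irregular
boundaries of diffuse hills), circularity at least $\tau_\mathrm{circ} =
0.20$, and peak relief at least $\Delta T_\mathrm{min}$. Centres are
**relief-weighted barycentres**, sub-pixel estimates dominated by pixels
near the hill summit and robust to diffuse boundaries and moderate
anisotropy.

The narrative description of this procedure sometimes states the retained
equivalent diameters as literally 10-15 px; the formal area bounds above
(with their $\alpha$ slack) are what the package enforces -- the two
descriptions coincide up to that slack, and enforcing the literal range
would contradict the stated bounds.

## Matching and registration

Matching IR and VIS marker sets must survive missing points, strong
layout symmetries, and a ~3x resolution difference. Each point gets a
**signature**: sorted distances to its $k = 4$ nearest same-modality
neighbours, normalized by their mean (scale-invariant by construction).
Each IR point shortlists the $m = 5$ most signature-similar VIS points.
RANSAC then samples IR triplets paired with shortlisted VIS triplets
(up to 2000 seeded iterations, exiting early once every point is
matched) and rejects hypotheses that:

* pair triplets of opposite **orientation** (sign of the oriented
  triangle area), or
* have a non-positive determinant -- reflections are physically
  impossible for rigidly mounted, nearly parallel cameras, or
* violate **rank monotonicity** of matched x and y coordinates.

Surviving hypotheses are scored by inlier count under a one-to-one
distance-capped assignment (greedy during search; the exact Hungarian
solver at finalization), ties broken by total residual. The distance caps
(permissive 5 px, strict 2 px) are expressed in LWIR pixels and scaled
into the VIS frame by $\sqrt{\det A}$ of the hypothesis, so they mean the
same physical distance in both frames. Finalization re-fits on all
inliers and re-assigns under the strict cap until the pair set reaches a
fixed point; a hypothesis must also retain at least 80% of
$\min(M, N)$ pairs (`minInlierFrac`), which blocks partial matches onto
self-similar sub-patterns -- the failure mode of mirrored scenes whose
marker strips are nearly congruent to their own reflection.

Monotonicity is reported as Spearman rank correlations per axis. For the
pass/fail decision the package uses a tie-tolerant Kendall-type
concordance: only point pairs separated by more than the strict distance
cap (in both modalities) vote, because rank order between points closer
than the localization noise is physically meaningless; plain Spearman
would register noise-level swaps between near-tied coordinates of a
vertical marker strip as order violations. A full reversal still scores
-1 and fails.

If the shortlisted search finds nothing (spurious detections can distort
the k-NN signatures enough to push true partners off every shortlist),
the matcher falls back to exhaustive enumeration of IR triplets (in
seeded random order) against all ordered VIS triplets -- the orientation
and determinant filters make this cheap, and coverage becomes
deterministic rather than probabilistic.

The final anamorphosis maps VIS coordinates to LWIR coordinates (keeping
the clinical thermal raster untouched) in one of three families: affine
(default -- the geometry of a plane viewed by two nearly parallel
pinholes is affine), projective, or degree-2 polynomial. Warping is
inverse-mapped bilinear resampling with an explicit validity mask; the
metric scale follows from the known 10 mm marker diameter as
`trueDiameter / median(detected diameters)`.

## The synthetic scene and what it does (not) show

`makeBimodalScene()` renders the full bimodal study geometry: an LWIR
pinhole (160x120, 54 deg field of view) and a VIS pinhole (640x480,
71.5 deg) at 0.5 m, baseline (4, 12) mm; eight 10 mm markers in two
vertical strips flanking the feet, jittered (generously in x -- this
breaks the strips' mirror symmetry, so a left-right flip cannot be
re-explained by an orientation-preserving affine; modestly in y, keeping
neighbouring hills from merging); foot-shaped warm plateaus (~31.5 degC,
supergaussian so the interior is wide and flat relative to the opening's
structuring element while the tails vanish at the marker strips) over a
~23 degC ambient field with a gentle tilt; marker hills of amplitude
3-6 degC and sigma ~14 mm; counts rendered through the forward Planck
model, the vignetting gain, and NETD-scaled noise. At these settings a
10 mm hole spans ~9 VIS px and its thermal imprint 10-15 LWIR px -- the
regime all the detector defaults assume. All generators restore the RNG
state and are bit-reproducible under their seed.

What passing on these fixtures does **not** show: real feet have sharp,
irregular thermal boundaries, moisture and callus emissivity variations,
and patient motion; real markers heat unevenly; real flats contain hot
pixels (which is exactly what the quantile clamp is for). The simulator
validates the algorithmic chain under its stated assumptions, not the
clinical acquisition itself.

## Numerical choices and degenerate inputs

* Even-count medians use the mean of the two central order statistics.
* Gain fields are floored at $10^{-6}$; a zero region in a flat is
  floored, not an error (only negative flats are rejected), so
  downstream division is always finite.
* The circularity denominator carries $\varepsilon' = 10^{-9}$.
* All-zero barycentre weights fall back to the unweighted centroid with
  a warning.
* Collinear triplets (zero oriented area) are skipped as degenerate
  hypotheses; collinear point sets make the affine fit fail with a
  "degenerate" error.
* Out-of-domain pixels in undistortion and warping are NA plus a
  validity mask, never silently filled.
* The record and container formats serialize doubles at 17 significant
  digits so parameters survive the round trip bit-exactly.
* Problem sizes in the validation experiments: the radiometric accuracy
  experiment uses 3 flat-field epochs of 16 frames at 160x120 and one
  28-35 degC scene; the registration experiment uses 50 seeded
  repetitions of the 8-marker scene with 0.3 px detection noise. These
  match the simulator's default study conditions.

## Known limitations

* Intrinsic calibration is *applied*, not estimated: the package consumes
  intrinsics JSON from any standard planar calibration (the thermal
  checkerboard for the LWIR camera is hardware, out of scope).
* The scene-plane affine truth ignores lens distortion (the simulator's
  cameras are ideal pinholes); with distorted inputs the chain expects
  undistorted coordinates, which is how the pipeline wires it.
* Matching assumes nearly parallel camera axes (the orientation,
  determinant and monotonicity constraints all encode it); a strongly
  rotated camera pair would require relaxing those constraints.
* Registration accuracy degrades for markers away from the sole plane:
  the plane-model error grows monotonically with out-of-plane offset
  (`parallaxOffsetM`), which is why the protocol keeps markers near the
  plane through the soles.
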