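---
title: "Geometry calibration and 2D reduction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry calibration and 2D reduction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffractr)
```

# The problem

A flat 2D area detector records powder diffraction rings or small-angle
scattering patterns. Turning raw frames into quantitative 1D data requires
knowing the *diffraction geometry*: six independent parameters — the
sample-to-detector distance $D$ (mm, along the direct beam), the beam-centre
pixel coordinates $(c_f, c_s)$, two orthogonal detector tilts
$(\tau_p, \tau_y)$ (deg), and the wavelength $\lambda$ (Å) or equivalently
the energy, with $E\,[\mathrm{keV}] \cdot \lambda\,[\text{Å}] = 12.3984$.
Given the geometry, every pixel maps to scattering angle $2\theta$, azimuth
$\chi$, momentum transfer $q = 4\pi \sin\theta/\lambda$ and resolution
$d = 2\pi/q$, and a Debye–Scherrer cone of half-angle $2\theta$ intersects
the detector plane as a conic — a circle when untilted, an ellipse when
tilted.

`diffractr` provides (i) calibration of these six parameters from images of
a certified standard (CeO₂ SRM 674b, Si SRM 640c, or a user line list), by
automatic single-image, multi-distance and manual routes; (ii) a
provenance-preserving processing-chain engine that reduces N-dimensional
scan stacks to corrected diffractograms, azimuth × radial "cake" grids,
peak-position/FWHM trajectories and azimuthal orientation maps, written as
NeXus/HDF5 files; and (iii) seeded synthetic generators for every data
shape the package consumes, which double as the test oracles.

# Conventions (declared, not inferred)

These choices are used everywhere, including the synthetic generators:

- **Pixels** are 0-based; the point $(0,0)$ is the *centre* of the corner
  pixel; "fast" is the second array axis (columns of the count matrix).
- **Pose model**: the detector plane is rotated first by `tilt_pitch` about
  the lab horizontal axis (the untilted fast axis), then by `tilt_yaw`
  about the lab vertical axis, then positioned so the direct beam pierces
  it at the beam-centre pixel at distance $D$.
- **Azimuth**: $\chi = 0$ along +fast, counter-clockwise viewed from the
  sample, range $(-180°, 180°]$.

The upstream description of this kind of calibration fixes only "two
orthogonal tilt angles"; the rotation order and azimuth origin above are
package-level decisions and are pinned by the test suite.

# Ring finding

The automatic route assumes near-circular rings with the beam centre on
the detector. Its stages, each chosen for robustness on realistic images:

1. **Beam-centre estimate.** The autoconvolution of the
   background-subtracted image peaks at twice the symmetry centre; this is
   robust to rings clipped by the detector edge, where a plain intensity
   centroid is badly biased. The FFT's mod-$N$ ambiguity leaves at most
   four candidates; the sharpest radial profile decides. (Deliberately
   *no* sharpness-maximizing polish: on a tilted detector the sharpness
   optimum is the mean-ellipse-centre compromise, systematically off the
   beam centre.)
2. **Tilt de-biasing.** On a tilted detector each ring ellipse's centre
   drifts away from the beam centre roughly as $D	an^2 2	heta$, so both
   the full-image symmetry estimate and a radial profile about any single
   point degrade with angle (rings split into twin peaks). Two
   refinements fix this: the symmetry estimate is redone restricted to
   the inner rings, where the drift is negligible, and the centre of an
   ellipse fitted to the innermost ring — within a few pixels of the true
   beam centre at any tilt — re-anchors the radial profile (twice).
3. **Peak detection** on the azimuthal-mean radial profile, with a noise
   floor scaled by per-bin pixel support (Poisson statistics of a bin
   mean) plus a robust MAD prominence threshold.
4. **Assignment to calibrant lines.** Each candidate anchors one of the
   innermost detected radii on a calibrant line (fixing $D$, and
   $\lambda$ via a radius ratio when free); the four innermost radii —
   the ones least distorted by tilt drift — are matched to the nearest
   predicted rings, and the best assignment wins by a quality-weighted
   score: crisp matches count fully, marginal ones barely, and predicted
   lines inside the covered span with no detected counterpart are
   penalized (clustered at the match resolution first, so unresolvable
   doublets are not punished). This defeats the spuriously dense
   assignments a high-index line comb can offer. The winning $(D,
   \lambda)$ then assigns the full detected list with a drift-tolerant
   window.

**Sub-pixel ring points** come from 256 line profiles (the "several
hundred" of standard practice) of $\pm$`half_width` pixels about the
predicted conic, each crossing the ring along the *local ellipse normal*
(a ray from the conic centre crosses obliquely on eccentric rings,
widening and biasing the profile), sampled by bilinear interpolation at
unit-pixel steps and fitted with a Gaussian plus linear baseline
(analytic Jacobian). When a geometry estimate is available — the later
refinement passes — the profile is fitted as a Gaussian in $q$ rather
than in the spatial coordinate, matching the physical ring model and
removing the $q(s)$-curvature bias that grows with scattering angle. A
profile is accepted when the fitted amplitude exceeds 3× the rms fit
residual, the centre lies in the middle 80% of the window, and the
landing pixel is unmasked; the point weight is the inverse variance of
the fitted centre. The window shrinks to 45% of the distance to the
nearest neighbouring ring, so a window never straddles two rings.

**Ellipse fitting** uses the numerically stable direct least-squares
method with the ellipse-specific constraint ($4AC - B^2 = 1$,
Halir–Flusser formulation) after centring/scaling normalization. It is
exact for noiseless conic points and its bias under isotropic point noise
is below 0.05 px at $\sigma = 0.5$ px on 256 points (verified against a
radial geometric-distance minimizer).

# Geometry refinement

All routes end in the same damped (Levenberg–Marquardt-style) least
squares on the free subset of the six parameters, minimizing

$$\sum_i w_i\,\bigl(q(\text{point}_i;\,\text{params}) - 2\pi/d_{\text{ring}(i)}\bigr)^2 .$$

The residual is defined in $q$, not ring-radius pixels: it weights all
rings uniformly and is exact for the Gaussian-in-$q$ synthetic generator.
Pixel-position weights are converted to $q$ weights through the local
gradient $|\nabla q|$ at each point. Internals: relative tolerance
$10^{-10}$, iteration cap 200, angles in radians, parameter scaling so the
normal matrix is well-conditioned. Uncertainties are the square roots of
the diagonal of the inverse normal matrix scaled by the reduced
chi-square. A condition number above $10^{10}$ raises an error naming the
inseparable parameters (e.g. the distance–wavelength degeneracy of a
single untilted ring, or the Bragg ambiguity of low-angle rings with a
free wavelength). One robust pass drops points more than 5 robust sigma
out — profiles that locked onto a neighbouring ring are gross outliers
with confident weights — and a final residual-versus-ring-spacing gate
turns any remaining self-consistent mislock into an explicit error rather
than a silently wrong geometry.

Two design points that proved load-bearing during development:

- **Ellipse-regression seeding.** To first order in the tilts the ellipse
  centre drifts from the beam centre by
  $D \tan^2(2\theta)\,(\sin\tau_y,\ \cos\tau_y \sin\tau_p)$; regressing
  per-ring ellipse centres (mm) on $\tan^2 2\theta$ therefore yields the
  beam centre (intercept) and the tilt direction cosines (slope / $D$).
  Starting the least squares from this seed, rather than from zero tilt,
  avoids a family of wrong tilt-direction local minima that appear above
  ~3° tilt.
- **Two extraction passes.** Points are re-extracted along the refined
  conics and re-refined once; on tilted detectors this removes the
  residual bias of circle-seeded windows.

**Multi-distance route.** From frames at precisely known increments
$\delta_i$ of an unknown base distance $D_0$: rings are paired across
frames by the dense cluster of pairwise radius ratios (the same ring's
radius scales as $(D_0+\delta_i)/(D_0+\delta_j)$, so true pairs cluster
tightly while spurious peaks fall out); per ring the fitted semi-major
axis is regressed on $\delta$, giving slope $\tan 2\theta$ and
$D_0 = \text{intercept}/\text{slope}$ — independent of both $D_0$ and
$\lambda$. The *absolute* regressed angles are then assigned to calibrant
lines: each anchor fixes $\lambda = 2d\sin\theta$, and the assignment with
the most matches and the most consistent implied wavelength wins. (Radius
*ratios* are useless for this at high energy — $\tan 2\theta$ ratios
degenerate to $d$ ratios as $\theta \to 0$, which is exactly the ambiguity
the multi-distance method exists to break.) The algebraic solution is
always polished by the joint least squares (shared centre/tilts/$\lambda$,
per-frame distances $D_0+\delta_i$) before uncertainties are quoted.

# Reduction

Per-frame operations, composable as chain steps:

- **Threshold mask**: pixels outside `[low, high]` join the mask; counts
  untouched.
- **Detector error model**: $\sigma = g\sqrt{\max(c/g, 1)}$ — Poisson with
  a one-photon floor at gain $g$ — propagated down the chain.
- **Solid angle**: multiply by $\Omega_0/\Omega_{\text{pix}}$ with
  $\Omega_{\text{pix}} = A\cos(\text{incidence})/L^2$, normalized to 1 at
  the beam centre; $1/\cos^3 2\theta$ for an untilted detector.
- **Polarization**: divide by the Kahn factor
  $P = \tfrac12\bigl(1 + \cos^2 2\theta - \xi \cos 2\chi \sin^2 2\theta\bigr)$,
  $\xi \in [-1, 1]$; cells where $P$ vanishes are masked, not divided. The
  upstream description names the correction without printing the formula;
  the Kahn convention is this package's declared choice.
- **Divide**: by a scalar, a metadata value (monitor), or a reference
  frame with quadrature error propagation.
- **Azimuthal integration / cake remap**: equal-width bins in the
  requested radial unit ($q$, $2\theta$ or $d$, each computed directly
  from per-pixel maps — a profile is never re-binned from another unit).
  The bin statistic is the weighted mean $\sum w c / \sum w$ (flat fields
  stay flat) with error $\sqrt{\sum w^2\sigma^2}/\sum w$; per-bin weights
  are retained so sums are recoverable; empty bins are flagged, never
  zero-filled. Pixel splitting `"none"` assigns each pixel to the bin of
  its centre — bitwise identical to a per-pixel histogram loop.
  `"bbox"` distributes each pixel's footprint — the interval spanned by
  its four corner coordinates — proportionally over overlapped bins (full
  polygon clipping is out of scope); total weight is conserved to
  $10^{-9}$ relative. Azimuth bins live on $(-180°, 180°]$; a requested
  range crossing the seam is handled by rotating the azimuth origin before
  binning, and bbox footprints straddling the rotated seam are split in
  two. Collapsing a cake over azimuth with its stored weights reproduces
  the direct integration.
- **Dynamic background**: an iteratively clipped smooth lower envelope —
  values above envelope + `clip_factor` × local error are replaced by the
  envelope (moving average with trend-preserving edge padding), repeated
  `iterations` times; the converged clip mask, dilated by half a window,
  is then bridged by interpolating the smoothed unclipped signal, which
  removes the residual tent any clipped moving average leaves under broad
  peaks. The `window` must exceed the widest peak (default $\max(15, n/10)$
  bins); the algorithm is a named task upstream with no published
  formula, so this estimator is pinned by the synthetic-truth tests, not
  by a reference.

# Downstream analysis

**Peak fitting**: weighted least squares of a Gaussian (FWHM
$= 2\sqrt{2\ln 2}\,\sigma$, exact) or pseudo-Voigt (shared-width mix,
clamped mixing fraction) plus linear baseline; uncertainties from the
covariance weighted by the profile errors; a flat window is flagged as a
failure rather than fabricating a peak. `track_peak()` fits every frame
independently but warm-starts from the previous success, stabilizing
gradual drifts; failures are recorded per frame without aborting the
series, so output length always equals the scan length.

**Orientation**: from an azimuthal profile over a $q$ band, the isotropic
level $I_{\text{iso}}$ is a low percentile of the valid bins (default the
5th — a percentile floor rather than the minimum, for noise robustness;
the analytic checks use the 0th). Then

$$\text{degree} = \frac{\sum (I - I_{\text{iso}})_+}{\sum I} \in [0, 1],
\qquad
\text{direction} = \tfrac12 \arg \sum (I - I_{\text{iso}})_+\, e^{2i\chi}
\in (-90°, 90°],$$

the $2\chi$ circular mean giving the $\pi$-periodic fibre direction. For
$I = 1 + \cos^2(\chi - \chi_0)$ the degree is exactly
$(1/2)/(3/2) = 1/3$ and the direction $\chi_0$. The degree is invariant
to positive rescaling; the direction is equivariant to rotation modulo
180°; an isotropic profile reports degree 0 with the direction flagged
invalid. `orientation_map()` applies this per scan cell and propagates
the stage axes verbatim, so a 3 × 4 grid scan yields 3 × 4 degree and
direction maps.

# The chain engine and provenance

Each processing step couples an operation with a declared parameter model
(type, default, bounds, choices); the schema drives validation and CLI
help, and `register_step()` accepts user plug-ins. A chain validates
data-kind compatibility along the sequence; a step marked *pass-through*
has its output saved while its *input* is forwarded downstream (the
cake-then-integrate idiom). Execution walks every innermost frame of an
N-d scan independently (serially or via forked workers with bitwise
identical results and preserved order) and reassembles outputs so the
scan rank is preserved: rank-$r$ input and a 1D-producing chain give a
rank-$(r-1)$ stack; scalar outputs give one scan-shaped map per scalar.
Failed frames become flagged `NA` gaps, never silent drops.

Outputs are NeXus/HDF5: `/entry/result` (NXdata with `signal`, axis
attributes and `errors`), `/entry/intermediate/<n>-<step>` for saved
intermediates, and `/entry/process` (NXprocess) holding the program
name/version, the input reference, the verbatim JSON chain serialization
and one sequenced NXnote per step with its parameter record. The chain is
a versioned JSON document — diff-able provenance, hand-editable configs —
and `extract_chain()` on any output file re-runs to bitwise identical
results. The exact field names are this package's own versioned layout;
no byte compatibility with any other program's files is claimed.

# What the synthetic generators emulate — and what they do not

`render_calibration_image()` draws each calibrant ring as a Gaussian in
$q$ (not in radius), so the calibration oracle is exact in $q$ space;
background is constant or polynomial in $q$; Poisson noise is applied
last under a stated seed; static-mask pixels carry the detector
saturation sentinel so threshold masking exercises the hot/overexposed
path. `render_distance_series()` shares everything but the distance.
`render_peak_shift_series()` and `render_oriented_grid_scan()` attach
their ground truth (trajectories, direction/degree fields) to the output.
All generators are bit-reproducible given a seed.

Not emulated: detector point-spread, flat-field structure, dark current,
texture/spotty rings, amorphous halos, sample absorption. A green test
therefore establishes correctness of the geometry, the estimators and
the propagation machinery under ideal counting statistics — not
robustness to every instrumental artefact of real beamline data.

Because the generator has no point spread, the ring width is chosen so
rings are resolved by the pixel grid (sigma of roughly one pixel or more
at the scene's dispersion; `ring_width_q = 0.02` at the 25.5 keV scenes,
`0.04` at 60 keV). A sub-pixel ring is something no real detector
records, and sampling one through bilinear interpolation aliases the
profile and biases sub-pixel centres at the 1e-4 relative level — far
inside every accuracy tolerance here, but visible against the 1e-5
statistical uncertainties of a high-count fit.

# Numerical choices and degenerate inputs

- Bragg-unreachable reflections ($\lambda \ge 2d$) error at prediction
  and are silently excluded from ring lists.
- `conic` prediction is closed-form (cone–plane intersection expanded to
  a quadratic in pixel coordinates); the sampling oracle is retained in
  the tests. Tilt → 0 degenerates continuously to the circle
  $r = D\tan 2\theta$.
- The direct beam maps to $q = 0$, $d = \infty$; `d`-unit maps exclude
  non-finite pixels from binning.
- Ellipse fits error on collinear or non-elliptical configurations; ring
  point sets below 6 points error with per-ring acceptance counts.
- Random-geometry acceptance runs at 1024², Poisson peak SNR 30,
  tilts to ±8°, centre anywhere in the central half of the detector:
  the stated world of the recovery criterion, not a tuned showcase.

# Known limitations

- Flat single-panel detectors only; no distortion (spline) correction,
  no per-panel poses, no refraction/absorption path corrections.
- The automatic route requires the beam centre on the detector and
  near-circular rings; beyond that it errors and points to the manual
  route (a residual-versus-ring-spacing gate makes silent mislock
  impossible, at the cost of refusing some marginal images).
- `bbox` splitting approximates the pixel footprint by its bounding
  interval; strongly anisotropic pixels near the beam centre smear over
  azimuth accordingly.
- Absolute-intensity calibration and flat-field correction are out of
  scope.
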