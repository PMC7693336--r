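---
title: "Models and methods behind besselflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind besselflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

besselflow analyses volumetric two-photon fluorescence recordings of brain
vasculature made with an axially extended Bessel focus. This vignette is
the package's own account of the models it implements, the parameters that
matter, what the synthetic phantom does and does not emulate, and the
numerical choices made where the design was genuinely open.

## 1. The Bessel focus and the optics calculator

An annular mask in a plane conjugate to the objective pupil restricts
illumination to a thin cone-angle shell between `theta_in` and
`theta_out`, where `sin(theta) = NA / n`. In the scalar model the on-axis
one-photon intensity of such an annulus is

    I(z) = sinc^2( k z (cos(theta_in) - cos(theta_out)) / 2 ),
    k = 2 pi n / lambda,  sinc(u) = sin(u) / u,

so the axial full width at half maximum is
`FWHM = 4 * 1.39156 / (k * (cos(theta_in) - cos(theta_out)))`: the thinner
the annulus, the longer the focus. `annulus_axial_profile()` evaluates
this closed form; the test suite cross-checks it against numerical
integration of the scalar Debye annular-pupil integral (agreement better
than 1% over NA 0.2–0.6, ratio 0.7–0.98). For the mask geometry used
throughout (outer NA 0.4, inner/outer radius ratio 2.3/2.5, 920 nm,
n = 1.33) the model gives 84.45 um, matching the 85 um design value of
such systems. Two-photon excitation is the square of the one-photon
intensity and is always narrower.

We interpret the quoted ~85 um design figure as the *one-photon intensity*
FWHM: the scalar-annulus intensity model reproduces it, whereas the
two-photon (squared) profile would be markedly narrower, and measured
in-vivo signal extents are narrower still.

`design_annulus()` inverts the closed form by a monotone root search
(FWHM is strictly increasing in the radius ratio). `axial_fwhm()` and
`measure_bead_fwhm()` find half-max crossings by linear interpolation on
the sampling grid; the default profile grid step is FWHM/400, well below
the FWHM/200 needed for interpolation error to be negligible.

## 2. The synthetic vascular scene

The phantom (`scene_config()`, `build_network()`, `manual_network()`,
renderers) is a stated world, not a fit to any data set:

* **Geometry.** Horizontal pial tubes near the top surface, vertical
  penetrating tubes spanning the depth, and tortuous capillaries built as
  persistent 3D random walks. Capillary radii stay below 3 um (diameters
  < 6 um, the conventional capillary cutoff).
* **Dynamics.** Each segment has radius
  `r_i(t) = r0_i (1 + A sin(2 pi f t + phi_i) + s_i g a(t))` with
  vasomotion frequency `f = 0.1 Hz` and default amplitude `A = 0.1`;
  `a(t)` is a unit-variance, low-pass-filtered arousal trace and
  `s_i = +-1` labels the two dilation populations. Phases are
  population-coherent (0 versus pi, small jitter), so opposite-sign
  vessels are anticorrelated in both the vasomotion band and the arousal
  band — the structure the correlation maps are designed to reveal. The
  pupil follows arousal through a first-order low-pass with a default
  2 s time constant: the pupil is a slow follower of the same latent
  state that drives the vessels.
* **RBC shadows.** Unlabeled red blood cells exclude dye. They are
  modelled as ellipsoids 6 um long with radial half-extent
  `min(2.4 um, lumen radius)`: they plug capillaries but occupy only the
  core of larger vessels. Full-lumen plugs were rejected: in wide vessels
  they removed essentially all local dye and drowned the dilation signal,
  which is not what sparse flowing cells do. RBCs advect at the segment
  speed on a virtual circular track at least 2 s of travel long
  (`max(L, 2 s * v)`). Wrapping at the segment length itself makes the
  whole shadow pattern exactly periodic with period `L/v`, which aliases
  any slope estimator (a 3 mm/s phantom read out as ~0.1 mm/s); with the
  long track the in-vessel cell count fluctuates Poisson-like, which is
  also more realistic. RBC linear density defaults to one cell per 20 um
  of track (`rbc_spacing`), exposed in the configuration because the
  literature value depends on vessel class and hematocrit.
* **Rendering.** A frame is the axial integral of dye concentration
  weighted by the two-photon axial profile (squared annulus profile for
  Bessel, narrow Gaussian for single-plane imaging), evaluated on a voxel
  grid with a linear partial-volume factor at lumen edges, blurred
  laterally with a 0.65-um-FWHM Gaussian, scaled to photons
  (`noise_photons` = photon count of a 10-um dye column at peak weight,
  default 50) plus a uniform background, then Poisson noise.
  `noise_photons = 0` requests a noiseless render in dye-column units.
  A noiseless frame conserves total dye to < 1% as shadows advect.
* **Not emulated.** Scattering and depth attenuation, Bessel side-ring
  background, aberration shadows beneath large vessels, axial motion,
  non-rigid motion. A green test therefore establishes correctness of the
  *analysis chain* under the stated physics, not robustness to every
  in-vivo nuisance.

Axis convention: arrays are `[row, col, frame]` / `[row, col, slice]`
(column-major R layout, a frame is a contiguous matrix); row increases
downward; physical positions are micrometres from the volume corner;
pixel centres sit at `(i - 0.5) * pixel_size`.

## 3. Preprocessing

Registration maximises windowed circular cross-correlation in the Fourier
domain, integer shifts only, ties toward the smaller shift. Because the
initial reference (mean of the first 30 frames) is blurred by the motion
itself, the reference is re-derived from the registered frames and the
procedure iterated (up to 4 passes); shifts are then exact on integer-
shift phantoms with sharp texture. Moving averages are centred with
truncated edges; temporal binning drops a trailing partial bin; local
background subtraction removes the per-frame background-ROI mean and adds
back its session average, so absolute intensity is preserved exactly.

## 4. Size and brightness measurement

The brightness-based dilation readout relies on the axially extended
focus: the projected signal of a lumen grows with the chord length, i.e.
with diameter, while a 3.1-um Gaussian plane saturates once the vessel is
thicker than the focus. Thresholds are "mean + 3 sd" of a vessel-free
background region (sample sd). For diameter time series the threshold
pools the background pixels over all frames of the moving-averaged movie,
because the spatial sd of a temporal-mean image collapses with duration
and would not reflect the per-frame noise the counts face. Probe lines
are sampled bilinearly at 1-pixel steps; ties at the threshold count as
vessel, but exactly-zero samples never do (this keeps the degenerate
zero-background threshold meaningful). The 10-pixel-thick probe count is
normalised by thickness and scaled by pixel size, so the trace is a
length in micrometres.

## 5. Correlation maps

ROI traces are block means (default 16 x 16 pixels), ΔF/F-normalised
about their median, and correlated with a reference at every integer lag
within +-10 frames. The lag maximising |r| wins, ties to the smaller
|lag|, and the *signed* coefficient is reported: the published maps show
negative values, so "absolute maximum" is read as the lag-selection rule,
not as reporting |r|. References on a different timebase are linearly
resampled. Constant ROIs are flagged and set to 0 rather than NA so maps
stay displayable.

## 6. Pupillometry

Frames are thresholded at the valley between the two dominant intensity
modes (fallback: 5th percentile), the largest connected dark component is
kept, and an oval is fitted from second moments: for an ideal filled
ellipse the axis-aligned variance of x-coordinates is `(width/4)^2`, so
`width = 4 sd(x)`. Width, not height, is the diameter readout (squinting
and blinking corrupt height first). Invalid frames (no component above
the minimum area) are linearly interpolated. The moment fit is
deterministic and insensitive to a specular reflection covering < 10% of
the pupil.

## 7. Kymograph velocimetry with 3D correction

Kymographs sample the registered movie along a hand-traced polyline at
1-pixel arc steps, one row per frame. Because the trace lives in the 2D
projection, out-of-plane stretches advance less per column than per
micrometre of vessel: a segment diving at 45 degrees under-reads speed by
1/sqrt(2). The structural stack is thresholded, speckle-cleaned,
skeletonized by sequential deletion of simple voxels (Bertrand's
foreground-26 / background-6 connectivity characterisation) with a curve
preservation rule — voxels with two or fewer remaining neighbours are
never deleted. The weaker "keep only degree-1 endpoints" rule lets
diagonal voxel ladders zipper-collapse from their ends, which is why the
stronger rule is used; the frozen staircase is smoothed downstream.
Short terminal spurs and short cycles are pruned. The trace is matched to
the skeleton by Dijkstra routing between the skeleton voxels nearest the
trace endpoints (robust to thick-junction path fragmentation); route
coordinates are smoothed (window 9) before cumulative 3D length is
measured, because staircase jitter otherwise inflates arc length; trace
samples are projected onto the smoothed route to build the monotone map
`u(s)`, and each kymograph row is resampled onto a uniform 3D arc-length
grid through `u^{-1}`.

Speeds come from 50-frame (0.5 s at 99 Hz) blocks: columns are
standardised (the static lumen profile and column-wise noise scale would
otherwise dominate), Sobel gradient magnitude is taken, and the Radon
projection variance is maximised over streak angles — coarse 1-degree
grid, then iterative range-halving to 0.05 degrees. Speed is
`(dx/dt) tan(theta)`, signed; mirror-flipping a block negates it.
A block whose angle-smoothed variance spectrum has no peak above twice
the median is "flat": if its raw columns still carry static structure the
speed is 0 (stationary shadows), otherwise NA (no streaks). The factor 2
replaces a provisional 1.2: on this objective pure noise reaches
peak/median ratios of 1.4–1.8 because Sobel's local correlations leave
few effective degrees of freedom per angle, while visible streaks sit at
2.9 or higher at the nominal photon scale. Segment speed is the median
over finite blocks; a segment is rejected when more than one third of its
finite blocks exceed 5 mm/s or reverse (strict inequality: exactly one
third is kept), or when more than two thirds of all blocks are flat.

## 8. Numerical choices and limitations

* Rendering resolution: `z_render_step` defaults to 1 um; derived tests
  that compare chord integrals at small diameters use 0.25 um. The
  partial-volume transition width is `max(pixel_size, z_render_step)`.
* All randomness flows through the scene seed (network layout, RBC
  phases, arousal, Poisson noise, motion walks); identical seeds give
  bit-identical outputs, and every pipeline run logs its seed and
  configuration echo.
* TIFF I/O implements the minimal baseline subset this package needs
  (uncompressed greyscale, 8/16-bit unsigned or 32-bit float, multi-page,
  JSON calibration in ImageDescription); compressed, tiled or RGB files
  are rejected with explicit errors.
* The velocimetry ceiling is set by sampling: at frame interval `dt` a
  shadow must stay identifiable between rows, and streaks steeper than
  the angular grid's useful range (|theta| -> 90 degrees) lose precision;
  with 3.25-um pixels at 99 Hz the pipeline recovers 3 mm/s within a few
  percent, and speeds beyond ~5 mm/s fall under the rejection rule. No
  claim is made that this bound equals any published closed-form limit.
* Skeleton-based 3D lengths erode by a few micrometres at segment ends
  (thinning plus smoothing); traces should stay clear of vessel tips.
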