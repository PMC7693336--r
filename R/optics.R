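# Axial excitation profile of an annular-aperture (Bessel) focus.
#
# An annular mask in the pupil restricts illumination to focusing cone
# angles between theta_in and theta_out (sin(theta) = NA/n). The on-axis
# one-photon intensity of such a thin annulus is, in the scalar model,
#
#   I(z) = sinc^2( k z (cos(theta_in) - cos(theta_out)) / 2 ),
#
# with k = 2*pi*n/lambda and sinc(u) = sin(u)/u, giving an axial FWHM of
# 2 * 2*1.39156 / (k * dcos) — the narrower the annulus, the longer the
# focus. Two-photon excitation is proportional to the square of this
# intensity.

# first positive root of sinc^2(u) = 1/2
SINC2_HALF_ROOT <- 1.391557377204432

#' Describe an annular illumination aperture
#'
#' @param na_outer outer numerical aperture of the annulus (dimensionless).
#' @param ratio inner/outer radius ratio of the annular mask, in (0, 1).
#' @param wavelength excitation wavelength in micrometres.
#' @param refractive_index refractive index of the immersion/sample medium.
#' @return an object of class `annulus_spec`.
#' @export
#' @examples
#' annulus_spec(0.4, 2.3 / 2.5, 0.92, 1.33)
annulus_spec <- function(na_outer, ratio, wavelength, refractive_index = 1.33) {
  if (!is.finite(na_outer) || na_outer <= 0 || na_outer >= refractive_index)
    stopf("invalid annulus: need 0 < na_outer < refractive_index")
  if (!is.finite(ratio) || ratio <= 0 || ratio >= 1)
    stopf("invalid annulus: ratio must be in (0, 1)")
  if (!is.finite(wavelength) || wavelength <= 0)
    stopf("invalid annulus: wavelength must be positive (um)")
  structure(list(na_outer = na_outer, ratio = ratio, wavelength = wavelength,
                 refractive_index = refractive_index),
            class = "annulus_spec")
}

# cos(theta_in) - cos(theta_out) for the annulus cone angles
annulus_dcos <- function(spec) {
  s_out <- spec$na_outer / spec$refractive_index
  s_in <- spec$ratio * spec$na_outer / spec$refractive_index
  sqrt(1 - s_in^2) - sqrt(1 - s_out^2)
}

wavenumber <- function(spec) 2 * pi * spec$refractive_index / spec$wavelength

# closed-form axial FWHM (um) of the one-photon sinc^2 profile
annulus_fwhm_closed_form <- function(spec)
  4 * SINC2_HALF_ROOT / (wavenumber(spec) * annulus_dcos(spec))

#' On-axis axial intensity profile of an annular aperture
#'
#' Evaluates the scalar-model on-axis intensity of the Bessel focus on a
#' symmetric z grid, normalised to peak 1. The two-photon excitation
#' profile is the square of the one-photon intensity.
#'
#' @param spec an [annulus_spec].
#' @param z micrometre grid (monotone increasing). Defaults to a symmetric
#'   grid spanning 2.5x the closed-form FWHM at a step of FWHM/400.
#' @param kind `"one_photon"` (illumination intensity) or `"two_photon"`
#'   (excitation, intensity squared).
#' @return an `axial_profile`: list with `z`, `intensity` (peak 1), `kind`.
#' @export
#' @examples
#' p <- annulus_axial_profile(annulus_spec(0.4, 0.92, 0.92))
#' axial_fwhm(p)  # ~85 um
annulus_axial_profile <- function(spec, z = NULL,
                                  kind = c("one_photon", "two_photon")) {
  stopifnot(inherits(spec, "annulus_spec"))
  kind <- match.arg(kind)
  fw <- annulus_fwhm_closed_form(spec)
  if (is.null(z)) {
    half <- 2.5 * fw
    z <- seq(-half, half, by = fw / 400)
  }
  stopifnot(is.numeric(z), length(z) >= 3, all(diff(z) > 0))
  u <- wavenumber(spec) * z * annulus_dcos(spec) / 2
  s <- ifelse(u == 0, 1, sin(u) / u)
  intensity <- s^2
  if (kind == "two_photon") intensity <- intensity^2
  intensity <- intensity / max(intensity)
  structure(list(z = z, intensity = intensity, kind = kind),
            class = "axial_profile")
}

#' Full width at half maximum of an axial profile
#'
#' Half-max crossings found by linear interpolation on the z grid around
#' the global maximum.
#'
#' @param profile an `axial_profile` (or any list with `z`, `intensity`).
#' @return FWHM in micrometres.
#' @export
axial_fwhm <- function(profile) {
  stopifnot(!is.null(profile$z), !is.null(profile$intensity))
  profile_fwhm(profile$z, profile$intensity)
}

#' Find the annulus radius ratio giving a target axial FWHM
#'
#' The FWHM increases monotonically with the inner/outer ratio (a thinner
#' annulus makes a longer focus), so the design reduces to a
#' one-dimensional root search.
#'
#' @param target_fwhm desired axial FWHM in micrometres.
#' @param na_outer outer numerical aperture.
#' @param wavelength excitation wavelength, micrometres.
#' @param refractive_index medium index.
#' @return the radius ratio in (0, 1).
#' @export
#' @examples
#' design_annulus(85, na_outer = 0.4, wavelength = 0.92)  # ~0.92 = 2.3/2.5
design_annulus <- function(target_fwhm, na_outer, wavelength,
                           refractive_index = 1.33) {
  lo <- 1e-4; hi <- 1 - 1e-7
  f <- function(r) annulus_fwhm_closed_form(
    annulus_spec(na_outer, r, wavelength, refractive_index)) - target_fwhm
  if (f(lo) > 0)
    stopf("target FWHM %.3g um below the minimum achievable (%.3g um) at NA %.3g",
          target_fwhm, f(lo) + target_fwhm, na_outer)
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Measure a bead PSF FWHM from a stack
#'
#' Extracts the 1-D intensity profile through the global intensity maximum
#' of the stack along the requested axis and returns its FWHM by linear
#' interpolation at half maximum.
#'
#' @param stack a [bf_stack] containing one dominant bright punctum.
#' @param axis `"lateral"` (along image columns through the peak) or
#'   `"axial"` (across slices through the peak).
#' @return FWHM in micrometres.
#' @export
measure_bead_fwhm <- function(stack, axis = c("lateral", "axial")) {
  stopifnot(inherits(stack, "bf_stack"))
  axis <- match.arg(axis)
  d <- stack$data
  if (max(d) <= min(d)) stopf("measurement error: stack has no punctum")
  idx <- arrayInd(which.max(d), dim(d))
  if (axis == "lateral") {
    prof <- d[idx[1], , idx[3]]
    grid <- (seq_along(prof) - 1) * stack$pixel_size
  } else {
    prof <- d[idx[1], idx[2], ]
    grid <- (seq_along(prof) - 1) * stack$z_step
  }
  profile_fwhm(grid, prof, floor = min(prof))
}
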