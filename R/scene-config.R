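# Parametric description of a synthetic vascular scene.

#' Configure a synthetic vascular scene
#'
#' The phantom emulates the imaged preparation: dye-filled vessels in a
#' cortical volume — horizontal pial vessels near the surface, vertical
#' penetrating vessels, tortuous capillaries (radius < 3 um) — with
#' unlabeled red blood cells advecting along each segment (dark shadows),
#' sinusoidal vasomotion near 0.1 Hz organised into two anticorrelated
#' populations, a slow arousal trace that drives both vessel radius (via
#' `arousal_coupling`, signed per vessel) and a slower pupil diameter,
#' Poisson shot noise, and optional rigid lateral drift.
#'
#' @param volume_size c(x, y, z) extents in micrometres.
#' @param pixel_size lateral pixel size, micrometres.
#' @param frame_rate volumetric frame rate, Hz.
#' @param duration recording length, seconds.
#' @param n_pial,n_penetrating,n_capillaries segment counts per class.
#' @param radius_ranges named list of `c(min, max)` radius intervals in
#'   micrometres for `pial`, `penetrating`, `capillary` (capillaries < 3 um).
#' @param rbc_speeds either `c(min, max)` mm/s to sample per segment, or a
#'   vector with one speed per segment (pial, penetrating, capillary order).
#' @param rbc_spacing mean arc-length gap between RBCs, micrometres.
#' @param rbc_length RBC length along the vessel axis, micrometres.
#' @param rbc_radius radial half-extent of an RBC, micrometres; RBCs are
#'   dye-excluding ellipsoids that fill capillary lumina (radius below
#'   `rbc_radius`) but occupy only the core of larger vessels.
#' @param vasomotion_freq vasomotion frequency, Hz.
#' @param vasomotion_amp fractional radius oscillation amplitude.
#' @param population_signs optional vector of +1/-1 per segment; default
#'   alternates between the two dilation populations.
#' @param arousal_coupling fractional radius gain per unit arousal (the
#'   arousal trace is standardised to unit variance).
#' @param pupil_tau pupil low-pass time constant, seconds (the pupil is a
#'   slow follower of arousal).
#' @param noise_photons photon count of a 10-um dye column at peak axial
#'   weight; 0 disables Poisson noise (noiseless rendering).
#' @param background_photons mean background photon rate per pixel-frame.
#' @param motion_amplitude rigid lateral drift bound, micrometres.
#' @param z_render_step axial integration step used by the renderers, um.
#' @param seed integer; fully determines all generated randomness.
#' @return a validated `scene_config` list.
#' @export
scene_config <- function(volume_size = c(100, 100, 60),
                         pixel_size = 1,
                         frame_rate = 15,
                         duration = 20,
                         n_pial = 2, n_penetrating = 2, n_capillaries = 3,
                         radius_ranges = list(pial = c(3, 8),
                                              penetrating = c(2.5, 5),
                                              capillary = c(1, 2.5)),
                         rbc_speeds = c(0.3, 3),
                         rbc_spacing = 20,
                         rbc_length = 6,
                         rbc_radius = 2.4,
                         vasomotion_freq = 0.1,
                         vasomotion_amp = 0.1,
                         population_signs = NULL,
                         arousal_coupling = 0.1,
                         pupil_tau = 2,
                         noise_photons = 50,
                         background_photons = 2,
                         motion_amplitude = 0,
                         z_render_step = 1,
                         seed = 1L) {
  cfg <- list(volume_size = volume_size, pixel_size = pixel_size,
              frame_rate = frame_rate, duration = duration,
              n_pial = n_pial, n_penetrating = n_penetrating,
              n_capillaries = n_capillaries, radius_ranges = radius_ranges,
              rbc_speeds = rbc_speeds, rbc_spacing = rbc_spacing,
              rbc_length = rbc_length, rbc_radius = rbc_radius,
              vasomotion_freq = vasomotion_freq,
              vasomotion_amp = vasomotion_amp,
              population_signs = population_signs,
              arousal_coupling = arousal_coupling,
              pupil_tau = pupil_tau,
              noise_photons = noise_photons,
              background_photons = background_photons,
              motion_amplitude = motion_amplitude,
              z_render_step = z_render_step,
              seed = as.integer(seed))
  pos <- c("pixel_size", "frame_rate", "duration", "rbc_spacing",
           "rbc_length", "rbc_radius", "vasomotion_freq", "pupil_tau",
           "z_render_step")
  for (nm in pos) if (!is.numeric(cfg[[nm]]) || any(cfg[[nm]] <= 0))
    stopf("scene_config: %s must be positive", nm)
  if (length(volume_size) != 3 || any(volume_size <= 0))
    stopf("scene_config: volume_size must be three positive extents (um)")
  for (nm in c("vasomotion_amp", "arousal_coupling", "noise_photons",
               "background_photons", "motion_amplitude"))
    if (!is.numeric(cfg[[nm]]) || any(cfg[[nm]] < 0))
      stopf("scene_config: %s must be non-negative", nm)
  for (nm in names(radius_ranges)) {
    r <- radius_ranges[[nm]]
    if (length(r) != 2 || any(r <= 0) || r[1] > r[2])
      stopf("scene_config: radius range '%s' must be a positive interval", nm)
  }
  if (max(radius_ranges$capillary) >= 3)
    stopf("scene_config: capillary radii must stay below 3 um (diameter < 6 um)")
  class(cfg) <- "scene_config"
  cfg
}

scene_n_frames <- function(config)
  max(1L, round(config$duration * config$frame_rate))

scene_times <- function(config)
  (seq_len(scene_n_frames(config)) - 1L) / config$frame_rate
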