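# Vessel network and ground-truth generation for the synthetic scene.

#' Build a ground-truthed vessel network from a scene configuration
#'
#' Lays out the three vessel classes (horizontal pial tubes near the top
#' surface, vertical penetrating tubes, tortuous random-walk capillaries),
#' assigns each a baseline radius, RBC flow speed and dilation-population
#' sign, and generates the dynamic ground truth: an arousal trace `a(t)`
#' (unit variance, low-pass filtered noise), per-segment radius time series
#'
#'   `r_i(t) = r0_i * (1 + A sin(2 pi f t + phi_i) + sign_i * g * a(t))`,
#'
#' and a pupil diameter trace that follows arousal through a first-order
#' low-pass with time constant `pupil_tau` (the pupil responds on the scale
#' of seconds, slower than vessels). Vasomotion phases are coherent within
#' a population and offset by pi between the two populations, so vessels
#' with opposite signs have anticorrelated radius dynamics.
#'
#' Everything is deterministic given `config$seed`.
#'
#' @param config a [scene_config].
#' @return list with `network` (class `vessel_network`: per-segment
#'   centerline, radius series, speed, sign) and `truth` (class
#'   `ground_truth`: time grid, arousal, pupil, radius matrix, RBC offsets,
#'   speeds, mean diameters).
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  vol <- config$volume_size
  n_total <- config$n_pial + config$n_penetrating + config$n_capillaries
  if (n_total < 1) stopf("scene has no vessels")
  with_seed(config$seed, {
    segs <- list()
    add <- function(type, centerline, r_range) {
      r0 <- stats::runif(1, r_range[1], r_range[2])
      if (2.2 * r0 > min(vol[1], vol[2]))
        stopf("volume too small for a vessel of radius %.1f um", r0)
      segs[[length(segs) + 1L]] <<- list(
        id = length(segs) + 1L, type = type, centerline = centerline, r0 = r0)
    }
    margin <- max(config$radius_ranges$pial) + 2
    if ((config$n_pial + config$n_penetrating > 0) &&
          (2 * margin >= vol[1] || 2 * margin >= vol[2]))
      stopf("volume too small for the requested vessels (margin %.0f um)",
            margin)
    for (i in seq_len(config$n_pial)) {
      # horizontal tube near the top surface, random in-plane direction
      y0 <- stats::runif(1, margin, vol[2] - margin)
      z0 <- stats::runif(1, margin, min(vol[3] / 3 + margin, vol[3] - margin))
      ang <- stats::runif(1, -pi / 12, pi / 12)
      p0 <- c(0, y0 - tan(ang) * vol[1] / 2, z0)
      p1 <- c(vol[1], y0 + tan(ang) * vol[1] / 2, z0)
      p0[2] <- min(max(p0[2], 2), vol[2] - 2)
      p1[2] <- min(max(p1[2], 2), vol[2] - 2)
      add("pial", rbind(p0, p1), config$radius_ranges$pial)
    }
    for (i in seq_len(config$n_penetrating)) {
      x0 <- stats::runif(1, margin, vol[1] - margin)
      y0 <- stats::runif(1, margin, vol[2] - margin)
      add("penetrating", rbind(c(x0, y0, 0), c(x0, y0, vol[3])),
          config$radius_ranges$penetrating)
    }
    for (i in seq_len(config$n_capillaries)) {
      # persistent 3D random walk, clamped inside the volume
      step <- 8; n_steps <- max(4L, round(0.8 * min(vol[1], vol[2]) / step))
      p <- c(stats::runif(1, 10, vol[1] - 10), stats::runif(1, 10, vol[2] - 10),
             stats::runif(1, 10, vol[3] - 10))
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      pts <- matrix(NA_real_, n_steps + 1L, 3); pts[1, ] <- p
      for (k in seq_len(n_steps)) {
        dir <- dir + 0.45 * stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        p <- p + step * dir
        p <- pmin(pmax(p, 4), vol - 4)
        pts[k + 1L, ] <- p
      }
      keep <- c(TRUE, sqrt(rowSums(diff(pts)^2)) > 1e-6)
      add("capillary", pts[keep, , drop = FALSE], config$radius_ranges$capillary)
    }

    signs <- config$population_signs
    if (is.null(signs)) signs <- rep_len(c(1, -1), n_total)
    if (length(signs) != n_total)
      stopf("population_signs must have one entry per vessel (%d)", n_total)

    speeds <- config$rbc_speeds
    if (length(speeds) == 2 && n_total != 2)
      speeds <- stats::runif(n_total, speeds[1], speeds[2])
    speeds <- rep_len(speeds, n_total)

    t <- scene_times(config)
    nt <- length(t)
    # arousal: unit-variance low-pass filtered white noise (~0.05 Hz band)
    a <- smooth_noise(nt, sigma_frames = max(2, 3 * config$frame_rate))
    pupil_rel <- lowpass_first_order(a, tau = config$pupil_tau,
                                     dt = 1 / config$frame_rate)
    if (nt > 1 && stats::sd(pupil_rel) > 0)
      pupil_rel <- pupil_rel / stats::sd(pupil_rel)

    A <- config$vasomotion_amp
    g <- config$arousal_coupling
    f <- config$vasomotion_freq
    radius_t <- matrix(NA_real_, n_total, nt)
    for (i in seq_len(n_total)) {
      phi <- (if (signs[i] > 0) 0 else pi) + 0.3 * stats::rnorm(1)
      segs[[i]]$phase <- phi
      segs[[i]]$sign <- signs[i]
      segs[[i]]$speed <- speeds[i]
      mod <- 1 + A * sin(2 * pi * f * t + phi) + signs[i] * g * a
      radius_t[i, ] <- pmax(segs[[i]]$r0 * mod, 0.2 * segs[[i]]$r0)
      segs[[i]]$radius_t <- radius_t[i, ]
      L <- polyline_length(segs[[i]]$centerline)
      # RBCs advect on a circular track at least 2 s of travel long so the
      # wrap-around recirculation never repeats within an analysis block
      track <- max(L, 2000 * speeds[i])
      n_rbc <- max(1L, floor(track / config$rbc_spacing))
      segs[[i]]$rbc_s0 <- sort(stats::runif(n_rbc, 0, track))
      segs[[i]]$rbc_track <- track
      segs[[i]]$length_3d <- L
    }

    network <- structure(list(segments = segs, volume_size = vol),
                         class = "vessel_network")
    truth <- structure(list(
      t = t, arousal = a, pupil_rel = pupil_rel,
      radius_t = radius_t,
      speeds = speeds, signs = signs,
      rbc_s0 = lapply(segs, `[[`, "rbc_s0"),
      lengths_3d = vapply(segs, `[[`, numeric(1), "length_3d"),
      mean_diameters = 2 * rowMeans(radius_t)), class = "ground_truth")
    list(network = network, truth = truth)
  })
}

polyline_length <- function(pts) sum(sqrt(rowSums(diff(pts)^2)))

#' Build a vessel network from explicit segment descriptions
#'
#' Deterministic counterpart of [build_network()] for controlled phantoms:
#' the caller supplies centerlines, baseline radii, speeds and population
#' signs; radius dynamics, arousal and pupil traces follow the same model
#' as [build_network()] (phases population-coherent: 0 for sign +1, pi for
#' sign -1).
#'
#' @param centerlines list of n x 3 micrometre polylines.
#' @param radii baseline radii r0, micrometres (recycled).
#' @param speeds RBC speeds, mm/s (recycled; use 0 for static shadows).
#' @param signs dilation population signs +-1 (recycled).
#' @param config a [scene_config] (volume, timing, noise, seed).
#' @param types segment class labels (recycled).
#' @return list with `network` and `truth`, as [build_network()].
#' @export
manual_network <- function(centerlines, radii, speeds = 1, signs = 1,
                           config = scene_config(), types = "manual") {
  stopifnot(inherits(config, "scene_config"), is.list(centerlines))
  n <- length(centerlines)
  radii <- rep_len(radii, n); speeds <- rep_len(speeds, n)
  signs <- rep_len(signs, n); types <- rep_len(types, n)
  with_seed(config$seed, {
    t <- scene_times(config)
    nt <- length(t)
    a <- smooth_noise(nt, sigma_frames = max(2, 3 * config$frame_rate))
    pupil_rel <- lowpass_first_order(a, tau = config$pupil_tau,
                                     dt = 1 / config$frame_rate)
    if (nt > 1 && stats::sd(pupil_rel) > 0)
      pupil_rel <- pupil_rel / stats::sd(pupil_rel)
    A <- config$vasomotion_amp; g <- config$arousal_coupling
    f <- config$vasomotion_freq
    radius_t <- matrix(NA_real_, n, nt)
    segs <- vector("list", n)
    for (i in seq_len(n)) {
      pts <- centerlines[[i]]
      stopifnot(is.matrix(pts), ncol(pts) == 3, nrow(pts) >= 2)
      phi <- if (signs[i] > 0) 0 else pi
      mod <- 1 + A * sin(2 * pi * f * t + phi) + signs[i] * g * a
      radius_t[i, ] <- pmax(radii[i] * mod, 0.2 * radii[i])
      L <- polyline_length(pts)
      track <- max(L, 2000 * speeds[i])
      n_rbc <- max(1L, floor(track / config$rbc_spacing))
      segs[[i]] <- list(
        id = i, type = types[i], centerline = pts, r0 = radii[i],
        phase = phi, sign = signs[i], speed = speeds[i],
        radius_t = radius_t[i, ],
        rbc_s0 = sort(stats::runif(n_rbc, 0, track)),
        rbc_track = track,
        length_3d = L)
    }
    network <- structure(list(segments = segs,
                              volume_size = config$volume_size),
                         class = "vessel_network")
    truth <- structure(list(
      t = t, arousal = a, pupil_rel = pupil_rel, radius_t = radius_t,
      speeds = speeds, signs = signs,
      rbc_s0 = lapply(segs, `[[`, "rbc_s0"),
      lengths_3d = vapply(segs, `[[`, numeric(1), "length_3d"),
      mean_diameters = 2 * rowMeans(radius_t)), class = "ground_truth")
    list(network = network, truth = truth)
  })
}

# zero-mean, unit-variance Gaussian-smoothed white noise
smooth_noise <- function(n, sigma_frames) {
  if (n < 2) return(numeric(n))
  h <- ceiling(3 * sigma_frames)
  x <- stats::rnorm(n + 2 * h)
  k <- stats::dnorm(seq(-h, h), sd = sigma_frames)
  k <- k / sum(k)
  y <- stats::filter(x, k, sides = 2)[(h + 1):(h + n)]
  y <- y - mean(y)
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

# first-order low-pass (exponential smoothing), steady-state gain 1
lowpass_first_order <- function(x, tau, dt) {
  alpha <- dt / (tau + dt)
  y <- numeric(length(x))
  y[1] <- x[1]
  for (i in seq_along(x)[-1]) y[i] <- y[i - 1] + alpha * (x[i] - y[i - 1])
  y
}

#' @export
print.vessel_network <- function(x, ...) {
  types <- vapply(x$segments, `[[`, character(1), "type")
  cat(sprintf("<vessel_network> %d segments (%s) in %g x %g x %g um\n",
              length(x$segments),
              paste(sprintf("%d %s", table(types), names(table(types))),
                    collapse = ", "),
              x$volume_size[1], x$volume_size[2], x$volume_size[3]))
  invisible(x)
}

#' Write per-segment ground truth as CSV
#' @param network a `vessel_network`.
#' @param truth the matching `ground_truth`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(network, truth, path) {
  df <- data.frame(
    id = vapply(network$segments, `[[`, integer(1), "id"),
    type = vapply(network$segments, `[[`, character(1), "type"),
    length_3d = truth$lengths_3d,
    speed = truth$speeds,
    sign = truth$signs,
    mean_diameter = truth$mean_diameters)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
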