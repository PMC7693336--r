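# Streak-slope velocimetry: Sobel filtering and iterative Radon
# transforms on 0.5-s kymograph blocks, median speed and rejection rules.

# Variance of the Radon projection at streak angle theta (radians from the
# time axis). Pixels are projected onto the axis perpendicular to the
# streak direction and binned at unit spacing; the objective is the
# count-weighted dispersion of the bin means per bin, maximal when the
# projection direction matches the streaks. Normalising by the number of
# bins (not pixels) keeps the spectrum flat for featureless noise, whose
# bin count varies with angle.
radon_projection_variance <- function(vals, rowc, colc, theta) {
  r <- round(-sin(theta) * rowc + cos(theta) * colc)
  sums <- rowsum(vals, r)
  cnts <- rowsum(rep(1, length(vals)), r)
  mu <- sums / cnts
  wm <- sum(sums) / sum(cnts)
  sum(cnts * (mu - wm)^2) / max(length(cnts) - 1, 1)
}

#' Blood-flow speed of one kymograph block by iterative Radon transform
#'
#' The block is Sobel-filtered (gradient magnitude), mean-subtracted and
#' Radon-projected over a coarse 1-degree grid of candidate streak angles
#' measured from the time axis; the angle maximising projection variance
#' is refined by iterative halving of the angular range (at least 3
#' rounds, to 0.05 degrees). The slope converts to a signed speed
#' `v = (dx / dt) * tan(theta)` — positive when streaks advance toward
#' increasing distance with time, negative for reversed flow.
#'
#' Blocks with no directional structure (angle-smoothed variance peak
#' below `flat_factor` times the median variance across angles) return
#' `NA`. The default factor 2 sits between the ratios produced by pure
#' noise (up to ~1.8) and by visible streaks (>= ~2.9 at nominal SNR).
#'
#' @param block numeric matrix (>= 50 rows = time, >= 8 columns =
#'   distance), or a `kymograph`.
#' @param dx micrometres per column (taken from the kymograph if given).
#' @param dt seconds per row.
#' @param flat_factor flat-block detection threshold (default 2).
#' @return speed in mm/s, or `NA` for a flat block.
#' @export
radon_block_speed <- function(block, dx = NULL, dt = NULL, flat_factor = 2) {
  if (inherits(block, "kymograph")) {
    dx <- block$dx; dt <- block$dt; block <- block$data
  }
  stopifnot(is.matrix(block), !is.null(dx), !is.null(dt))
  if (nrow(block) < 50) stopf("block must have at least 50 rows (0.5 s)")
  if (ncol(block) < 8) stopf("block must have at least 8 columns")
  # standardise each column (remove the static intensity profile and its
  # noise scale) so moving RBC shadows, not standing lumen structure or
  # column-wise variance differences, drive the estimate
  blk <- sweep(block, 2, colMeans(block))
  csd <- apply(blk, 2, stats::sd)
  blk <- sweep(blk, 2, pmax(csd, 1e-12 + 0.05 * max(csd)), "/")
  g <- sobel_magnitude(blk)
  g <- g - mean(g)
  rowc <- matrix(seq_len(nrow(g)) - (nrow(g) + 1) / 2, nrow(g), ncol(g))
  colc <- matrix(seq_len(ncol(g)) - (ncol(g) + 1) / 2, nrow(g), ncol(g),
                 byrow = TRUE)
  vals <- as.vector(g); rowv <- as.vector(rowc); colv <- as.vector(colc)
  coarse <- seq(-89.5, 89.5, by = 1) * pi / 180
  v_coarse <- vapply(coarse, function(th)
    radon_projection_variance(vals, rowv, colv, th), numeric(1))
  # flat detection on the angle-smoothed spectrum: a real streak family
  # produces a broad variance peak; white noise only narrow flukes
  v_smooth <- moving_average(v_coarse, 9L)
  if (max(v_smooth) < flat_factor * stats::median(v_smooth) ||
        max(v_smooth) <= 1e-12 * mean(block^2)) {
    # nothing moves; distinguish a static pattern (stationary shadows,
    # speed 0) from a truly featureless block (no streaks at all)
    col_struct <- stats::var(colMeans(block))
    noise_est <- mean(apply(block, 2, stats::var)) / nrow(block)
    return(if (col_struct > 5 * noise_est) 0 else NA_real_)
  }
  theta <- coarse[which.max(v_coarse)]
  delta <- 1 * pi / 180
  repeat {
    grid <- theta + seq(-1, 1, length.out = 9) * delta
    vg <- vapply(grid, function(th)
      radon_projection_variance(vals, rowv, colv, th), numeric(1))
    theta <- grid[which.max(vg)]
    delta <- delta / 2
    if (delta <= 0.05 * pi / 180 / 2) break
  }
  # streaks lie along the angle of maximal variance; speed from the slope
  (dx / dt) * tan(theta) / 1000  # um/s -> mm/s
}

#' Block-speed rejection rules for a vessel segment
#'
#' A segment is rejected when more than one third of its finite block
#' speeds are very high (> `high` mm/s) or reversed (< 0 mm/s) — strict
#' inequality, so exactly one third is kept — or when more than two thirds
#' of all blocks are flat (little to no RBC streaks).
#'
#' @param block_speeds numeric vector of per-block speeds, `NA` = flat.
#' @param high high-speed cutoff in mm/s (default 5).
#' @return list with `rejected` (logical) and `reason` (`""`,
#'   `"outlier_or_reversed_speeds"` or `"no_rbc_streaks"`).
#' @export
reject_segment <- function(block_speeds, high = 5) {
  n_all <- length(block_speeds)
  finite <- block_speeds[is.finite(block_speeds)]
  if (n_all == 0 || length(finite) == 0 ||
        sum(!is.finite(block_speeds)) / n_all > 2 / 3)
    return(list(rejected = TRUE, reason = "no_rbc_streaks"))
  n_bad <- sum(finite > high | finite < 0)
  if (n_bad / length(finite) > 1 / 3)
    return(list(rejected = TRUE, reason = "outlier_or_reversed_speeds"))
  list(rejected = FALSE, reason = "")
}

#' Blood-flow speed time course of a kymograph
#'
#' Splits the kymograph into non-overlapping `block_frames`-row blocks
#' (trailing partial block dropped), estimates each block's speed with
#' [radon_block_speed()], takes the median over finite blocks and applies
#' [reject_segment()].
#'
#' @param kymo a `kymograph`.
#' @param block_frames rows per block (default 50, i.e. 0.5 s at 99 Hz).
#' @param high rejection cutoff passed to [reject_segment()].
#' @return a `flow_result`: list with `block_speeds`, `block_times` (s,
#'   block centres), `median_speed` (mm/s), `rejected`, `reason`.
#' @export
flow_trace <- function(kymo, block_frames = 50L, high = 5) {
  stopifnot(inherits(kymo, "kymograph"))
  nb <- nrow(kymo$data) %/% block_frames
  if (nb < 1) stopf("kymograph shorter than one block")
  speeds <- vapply(seq_len(nb), function(b) {
    rows <- ((b - 1L) * block_frames + 1L):(b * block_frames)
    radon_block_speed(kymo$data[rows, , drop = FALSE], kymo$dx, kymo$dt)
  }, numeric(1))
  rej <- reject_segment(speeds, high = high)
  structure(list(
    block_speeds = speeds,
    block_times = (seq_len(nb) - 0.5) * block_frames * kymo$dt,
    median_speed = if (any(is.finite(speeds)))
      stats::median(speeds[is.finite(speeds)]) else NA_real_,
    rejected = rej$rejected, reason = rej$reason), class = "flow_result")
}

#' Vessel segment diameter from a hand-drawn cross-section line
#'
#' FWHM of the bilinearly interpolated intensity profile along the line,
#' with the half level taken between the local background floor (profile
#' minimum) and the peak.
#'
#' @param image average-intensity projection (matrix).
#' @param p0,p1 line endpoints `c(x, y)` in pixels, crossing one vessel.
#' @param pixel_size micrometres per pixel.
#' @return diameter in micrometres.
#' @export
segment_diameter <- function(image, p0, p1, pixel_size = 1) {
  prof <- drop(probe_samples(image, segment_probe(p0, p1, 1)))
  if (max(prof) <= min(prof)) stopf("no peak above background on the line")
  profile_fwhm((seq_along(prof) - 1) * pixel_size, prof, floor = min(prof))
}
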