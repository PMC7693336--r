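# Vessel size and brightness measurement from Bessel projections and
# Gaussian stacks, and their time dynamics.

#' Define a perpendicular measurement probe for a vessel segment
#'
#' @param p0,p1 line endpoints `c(x, y)` in pixel coordinates, drawn
#'   perpendicular to the vessel.
#' @param thickness probe thickness in pixels (1 for static size and
#'   brightness, 10 for diameter time series).
#' @param bg_region rectangle `c(x0, y0, x1, y1)` of vessel-free pixels for
#'   threshold estimation (optional for operations that take it separately).
#' @param id probe identifier.
#' @return a `segment_probe` object.
#' @export
segment_probe <- function(p0, p1, thickness = 1, bg_region = NULL, id = NA) {
  stopifnot(length(p0) == 2, length(p1) == 2)
  if (all(p0 == p1)) stopf("probe endpoints coincide")
  if (thickness < 1) stopf("probe thickness must be >= 1")
  structure(list(p0 = as.numeric(p0), p1 = as.numeric(p1),
                 thickness = as.numeric(thickness), bg_region = bg_region,
                 id = id), class = "segment_probe")
}

# Sample an image along the probe: rows = offsets across the thickness
# (unit normal steps), cols = positions along the line (unit arc steps).
probe_samples <- function(image, probe) {
  ny <- nrow(image); nx <- ncol(image)
  chk <- rbind(probe$p0, probe$p1)
  if (any(chk[, 1] < 1 | chk[, 1] > nx | chk[, 2] < 1 | chk[, 2] > ny))
    stopf("probe line extends outside the image")
  rs <- resample_polyline(rbind(probe$p0, probe$p1), step = 1)
  u <- (probe$p1 - probe$p0) / sqrt(sum((probe$p1 - probe$p0)^2))
  nrm <- c(-u[2], u[1])
  offs <- seq_len(probe$thickness) - (probe$thickness + 1) / 2
  vapply(seq_along(rs$x), function(i) {
    bilinear_sample(image, rs$y[i] + offs * nrm[2], rs$x[i] + offs * nrm[1])
  }, numeric(length(offs))) |>
    matrix(nrow = length(offs))
}

#' Common intensity threshold from a vessel-free background region
#'
#' Mean plus three (sample) standard deviations of the pixels in the
#' region.
#'
#' @param image numeric matrix.
#' @param bg_region rectangle `c(x0, y0, x1, y1)` or logical mask.
#' @return intensity threshold.
#' @export
common_threshold <- function(image, bg_region) {
  mask <- as_mask(bg_region, nrow(image), ncol(image))
  if (!any(mask)) stopf("background region is empty")
  v <- image[mask]
  mean(v) + 3 * stats::sd(v)
}

#' Brightness and size of a vessel along a 1-pixel probe (Bessel image)
#'
#' Brightness is the brightest (bilinearly interpolated) sample along the
#' line; size is the number of line samples at or above the common
#' threshold.
#'
#' @param image Bessel projection image.
#' @param probe a [segment_probe] with thickness 1.
#' @param threshold intensity threshold, typically from
#'   [common_threshold()]; defaults to the probe's own `bg_region`.
#' @return list with `brightness` and `size_px`.
#' @export
bessel_segment_measure <- function(image, probe, threshold = NULL) {
  stopifnot(inherits(probe, "segment_probe"))
  if (probe$thickness != 1) stopf("static size probes must have thickness 1")
  if (is.null(threshold)) {
    if (is.null(probe$bg_region)) stopf("no threshold and no bg_region")
    threshold <- common_threshold(image, probe$bg_region)
  }
  prof <- drop(probe_samples(image, probe))
  # ties at the threshold count as vessel, but zero signal never does
  # (so a zero threshold from a noiseless background stays meaningful)
  list(brightness = max(prof), size_px = sum(prof >= threshold & prof > 0))
}

#' Brightness and size of a vessel from an axial reslice (Gaussian stack)
#'
#' The stack is resliced along the probe line across all z, giving a 2-D
#' axial cross-section. Brightness is its maximum; size is the largest
#' FWHM over cross-section rows, in micrometres.
#'
#' @param stack a [bf_stack].
#' @param probe a [segment_probe] crossing the vessel.
#' @return list with `brightness` and `size_um` (0 with a warning when no
#'   peak rises above half of the section maximum).
#' @export
gaussian_cross_section_measure <- function(stack, probe) {
  stopifnot(inherits(stack, "bf_stack"))
  nz <- dim(stack$data)[3]
  sect <- t(vapply(seq_len(nz), function(k)
    drop(probe_samples(stack$data[, , k],
                       segment_probe(probe$p0, probe$p1, 1))),
    numeric(length(resample_polyline(rbind(probe$p0, probe$p1), 1)$s))))
  bright <- max(sect)
  if (bright <= 0) {
    warnf("no vessel signal in the reslice")
    return(list(brightness = 0, size_um = 0))
  }
  grid <- (seq_len(ncol(sect)) - 1) * stack$pixel_size
  widths <- apply(sect, 1, function(p) {
    if (max(p) < bright / 2) return(NA_real_)
    tryCatch(profile_fwhm(grid, p, floor = min(p)), error = function(e) NA_real_)
  })
  if (all(is.na(widths))) {
    warnf("vessel does not intersect the reslice")
    return(list(brightness = bright, size_um = 0))
  }
  list(brightness = bright, size_um = max(widths, na.rm = TRUE))
}

#' Vessel diameter time series from a thick probe
#'
#' Per frame, the number of probe samples above the threshold divided by
#' the probe thickness, times the pixel size. The movie should already be
#' moving-averaged (see [moving_average()]).
#'
#' @param movie a [bf_movie].
#' @param probe a [segment_probe], typically thickness 10.
#' @param bg_region background rectangle/mask; the threshold is the mean
#'   plus three standard deviations of these pixels pooled over all frames
#'   of the (moving-averaged) movie.
#' @return numeric vector of diameters (um), one per frame.
#' @export
diameter_timeseries <- function(movie, probe, bg_region) {
  stopifnot(inherits(movie, "bf_movie"), inherits(probe, "segment_probe"))
  d <- dim(movie$data)
  mask <- as_mask(bg_region, d[1], d[2])
  if (!any(mask)) stopf("background region is empty")
  bg <- matrix(movie$data, d[1] * d[2], d[3])[as.vector(mask), ]
  thr <- mean(bg) + 3 * stats::sd(bg)
  nt <- d[3]
  d <- vapply(seq_len(nt), function(t) {
    sm <- probe_samples(movie$data[, , t], probe)
    sum(sm >= thr & sm > 0) / probe$thickness * movie$pixel_size
  }, numeric(1))
  if (all(d == 0)) warnf("threshold above lumen intensity: all-zero diameters")
  d
}

#' Fractional fluorescence change about the median baseline
#'
#' `(x - F) / F` with `F = median(x)`.
#'
#' @param trace numeric vector with positive median.
#' @return ΔF/F trace (median 0 by construction).
#' @export
dff <- function(trace) {
  f <- stats::median(trace)
  if (!is.finite(f) || f <= 0) stopf("trace median must be positive for dF/F")
  (trace - f) / f
}

#' Squared Pearson correlation of a size-brightness relation
#'
#' @param size,brightness paired measurements (>= 3 pairs).
#' @return R^2 of the least-squares linear fit.
#' @export
size_brightness_correlation <- function(size, brightness) {
  stopifnot(length(size) == length(brightness), length(size) >= 3)
  if (stats::sd(size) == 0 || stats::sd(brightness) == 0)
    stopf("zero variance: correlation undefined")
  rsq(size, brightness)
}

#' Temporal variation map (std/mean) with dim-pixel mask
#'
#' Per-pixel standard deviation over time divided by the temporal mean;
#' the dimmest 80% of pixels of the mean image (non-vasculature tissue)
#' are set to zero.
#'
#' @param movie a [bf_movie] with >= 2 frames.
#' @param dim_fraction fraction of dimmest pixels masked out (default 0.8).
#' @return matrix of coefficients of variation, masked pixels 0.
#' @export
temporal_variation_map <- function(movie, dim_fraction = 0.8) {
  stopifnot(inherits(movie, "bf_movie"))
  d <- dim(movie$data)
  if (d[3] < 2) stopf("need at least 2 frames")
  m <- matrix(movie$data, d[1] * d[2], d[3])
  mu <- rowMeans(m)
  sd_t <- sqrt(rowSums((m - mu)^2) / (d[3] - 1))
  cv <- ifelse(mu > 0, sd_t / mu, 0)
  cut <- stats::quantile(mu, dim_fraction, names = FALSE, type = 7)
  cv[mu <= cut] <- 0
  matrix(cv, d[1], d[2])
}
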