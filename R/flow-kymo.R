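# Kymograph extraction along traced vessel segments and 2D -> 3D
# arc-length remapping.

#' Create a kymograph container
#' @param data matrix, rows = time, cols = distance along the vessel.
#' @param dx micrometres per column.
#' @param dt seconds per row.
#' @return a `kymograph`.
#' @export
kymograph <- function(data, dx, dt) {
  stopifnot(is.matrix(data), dx > 0, dt > 0)
  structure(list(data = data, dx = dx, dt = dt), class = "kymograph")
}

#' Extract a kymograph along a hand-traced vessel segment
#'
#' Samples the (registered) movie along the polyline at 1-pixel arc-length
#' steps with bilinear interpolation; one kymograph row per frame.
#'
#' @param movie a [bf_movie].
#' @param trace n x 2 matrix of `(x, y)` pixel coordinates (>= 2 points).
#' @return a `kymograph` with `dx = pixel_size` and `dt = frame_interval`.
#' @export
extract_kymograph <- function(movie, trace) {
  stopifnot(inherits(movie, "bf_movie"), is.matrix(trace), ncol(trace) == 2)
  d <- dim(movie$data)
  if (any(trace[, 1] < 1 | trace[, 1] > d[2] |
            trace[, 2] < 1 | trace[, 2] > d[1]))
    stopf("trace extends outside the image")
  rs <- resample_polyline(trace, step = 1)
  ns <- length(rs$x)
  # bilinear weights are the same for every frame: index into flat frames
  y <- pmin(pmax(rs$y, 1), d[1]); x <- pmin(pmax(rs$x, 1), d[2])
  y0 <- pmin(floor(y), d[1] - 1L); x0 <- pmin(floor(x), d[2] - 1L)
  fy <- y - y0; fx <- x - x0
  i00 <- (x0 - 1) * d[1] + y0
  m <- matrix(movie$data, d[1] * d[2], d[3])
  K <- t(m[i00, , drop = FALSE]) * rep((1 - fy) * (1 - fx), each = d[3]) +
    t(m[i00 + 1, , drop = FALSE]) * rep(fy * (1 - fx), each = d[3]) +
    t(m[i00 + d[1], , drop = FALSE]) * rep((1 - fy) * fx, each = d[3]) +
    t(m[i00 + d[1] + 1, , drop = FALSE]) * rep(fy * fx, each = d[3])
  dim(K) <- c(d[3], ns)
  kymograph(K, dx = movie$pixel_size, dt = movie$frame_interval)
}

#' Build a 2D -> 3D arc-length map
#'
#' @param s projected 2-D arc-length grid, micrometres (starting at 0).
#' @param u matched 3-D arc length at each `s`, monotone nondecreasing,
#'   `u[1] = 0`.
#' @return an `arc_length_map` with `s`, `u`, `total_3d_length`.
#' @export
arc_length_map <- function(s, u) {
  stopifnot(length(s) == length(u), length(s) >= 2)
  if (any(diff(u) < -1e-9)) stopf("3D arc length map must be monotone")
  u <- cummax(u - u[1])
  structure(list(s = s, u = u, total_3d_length = u[length(u)]),
            class = "arc_length_map")
}

#' Remap a kymograph's distance axis from 2-D projected to 3-D length
#'
#' Each row is resampled onto a uniform 3-D arc-length grid (step `dx`)
#' through the inverse of the arc-length map, by linear interpolation.
#' Out-of-plane vessel stretches are thereby expanded so streak slopes
#' read true 3-D speed.
#'
#' @param kymo a `kymograph` whose columns span the map's `s` grid.
#' @param map an `arc_length_map`.
#' @return a `kymograph` with `round(total_3d_length / dx) + 1` columns.
#' @export
remap_kymograph_3d <- function(kymo, map) {
  stopifnot(inherits(kymo, "kymograph"), inherits(map, "arc_length_map"))
  n2 <- ncol(kymo$data)
  s_cols <- (seq_len(n2) - 1) * kymo$dx
  if (max(map$s) < max(s_cols) - kymo$dx)
    stopf("arc-length map does not cover the kymograph width")
  u <- map$u + seq_along(map$u) * 1e-9  # ensure strictly increasing
  n3 <- round(map$total_3d_length / kymo$dx) + 1L
  u_grid <- (seq_len(n3) - 1) * kymo$dx
  s_of_u <- stats::approx(u, map$s, xout = pmin(u_grid, max(u)), rule = 2)$y
  cpos <- pmin(pmax(s_of_u / kymo$dx + 1, 1), n2)
  j0 <- pmin(floor(cpos), n2 - 1L); w <- cpos - j0
  K <- kymo$data[, j0, drop = FALSE] * rep(1 - w, each = nrow(kymo$data)) +
    kymo$data[, j0 + 1L, drop = FALSE] * rep(w, each = nrow(kymo$data))
  kymograph(K, dx = kymo$dx, dt = kymo$dt)
}
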