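# Physical image containers: movies (time series) and z-stacks.
#
# Arrays are stored [row, col, frame] (movies) and [row, col, slice]
# (stacks) so that a single frame `m$data[, , t]` is contiguous in memory.
# Row index increases downward; physical positions are in micrometres with
# the origin at the volume corner.

#' Create a calibrated movie (T-frame image series)
#'
#' @param data numeric array `[rows, cols, frames]` of non-negative
#'   intensities.
#' @param pixel_size lateral pixel size in micrometres.
#' @param frame_interval time between frames in seconds.
#' @return an object of class `bf_movie`.
#' @export
bf_movie <- function(data, pixel_size, frame_interval) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stopf("pixel_size must be a positive scalar (um)")
  if (!is.numeric(frame_interval) || length(frame_interval) != 1 || frame_interval <= 0)
    stopf("frame_interval must be a positive scalar (s)")
  structure(list(data = data, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "bf_movie")
}

#' Create a calibrated z-stack
#'
#' @param data numeric array `[rows, cols, slices]`.
#' @param pixel_size lateral pixel size in micrometres.
#' @param z_step axial step between slices in micrometres.
#' @return an object of class `bf_stack`.
#' @export
bf_stack <- function(data, pixel_size, z_step) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stopf("pixel_size must be a positive scalar (um)")
  if (!is.numeric(z_step) || length(z_step) != 1 || z_step <= 0)
    stopf("z_step must be a positive scalar (um)")
  structure(list(data = data, pixel_size = pixel_size, z_step = z_step),
            class = "bf_stack")
}

#' @export
print.bf_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bf_movie> %d x %d px, %d frames, %.3g um/px, %.4g s/frame\n",
              d[1], d[2], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' @export
print.bf_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bf_stack> %d x %d px, %d slices, %.3g um/px, %.3g um z-step\n",
              d[1], d[2], d[3], x$pixel_size, x$z_step))
  invisible(x)
}

n_frames <- function(m) dim(m$data)[3]

#' Mean-intensity projection of a movie
#'
#' @param movie a [bf_movie].
#' @return a 2-D matrix, the per-pixel temporal mean.
#' @export
average_projection <- function(movie) {
  stopifnot(inherits(movie, "bf_movie"))
  rowMeans(movie$data, dims = 2)
}
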