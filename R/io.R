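# Calibrated TIFF movie/stack I/O. Calibration (um/px, s/frame or um
# z-step) is stored as JSON in the ImageDescription tag; reading without
# calibration in either the file or the call is an error — no silent
# defaults.

movie_description <- function(m)
  jsonlite::toJSON(list(kind = "movie", pixel_size_um = m$pixel_size,
                        frame_interval_s = m$frame_interval),
                   auto_unbox = TRUE, digits = NA)

stack_description <- function(s)
  jsonlite::toJSON(list(kind = "stack", pixel_size_um = s$pixel_size,
                        z_step_um = s$z_step), auto_unbox = TRUE,
                   digits = NA)

parse_description <- function(txt) {
  if (!nzchar(txt)) return(NULL)
  out <- tryCatch(jsonlite::fromJSON(txt), error = function(e) NULL)
  if (is.list(out)) out else NULL
}

#' Write a movie to a multi-page TIFF with embedded calibration
#' @param movie a [bf_movie].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "bf_movie"))
  write_tiff(path, movie$data, movie_description(movie))
}

#' Write a z-stack to a multi-page TIFF with embedded calibration
#' @param stack a [bf_stack].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "bf_stack"))
  write_tiff(path, stack$data, stack_description(stack))
}

#' Read a movie from TIFF
#'
#' Calibration is taken from the embedded metadata; explicit arguments
#' override the file tags (with a warning when both are present and differ).
#'
#' @param path TIFF path.
#' @param pixel_size optional override, micrometres per pixel.
#' @param frame_interval optional override, seconds per frame.
#' @return a [bf_movie].
#' @export
read_movie <- function(path, pixel_size = NULL, frame_interval = NULL) {
  tf <- read_tiff(path)
  meta <- parse_description(tf$description)
  px <- resolve_calibration(pixel_size, meta$pixel_size_um, "pixel_size", path)
  dt <- resolve_calibration(frame_interval, meta$frame_interval_s,
                            "frame_interval", path)
  bf_movie(tf$data, px, dt)
}

#' Read a z-stack from TIFF
#' @inheritParams read_movie
#' @param z_step optional override, micrometres per slice.
#' @return a [bf_stack].
#' @export
read_stack <- function(path, pixel_size = NULL, z_step = NULL) {
  tf <- read_tiff(path)
  meta <- parse_description(tf$description)
  px <- resolve_calibration(pixel_size, meta$pixel_size_um, "pixel_size", path)
  dz <- resolve_calibration(z_step, meta$z_step_um, "z_step", path)
  bf_stack(tf$data, px, dz)
}

resolve_calibration <- function(override, tag, what, path) {
  if (!is.null(override)) {
    if (!is.null(tag) && is.finite(tag) && abs(tag - override) > 1e-9)
      warnf("%s override (%g) differs from file tag (%g) in %s; using override",
            what, override, tag, path)
    return(override)
  }
  if (is.null(tag) || !is.finite(tag))
    stopf("no %s calibration in %s and none supplied", what, path)
  tag
}

#' Read vessel probe definitions from CSV
#'
#' Columns: `id, x0, y0, x1, y1, thickness, bg_x0, bg_y0, bg_x1, bg_y1`
#' (pixel coordinates; the bg rectangle is used for threshold estimation).
#' @param path CSV path.
#' @return list of [segment_probe] objects.
#' @export
read_probes <- function(path) {
  df <- utils::read.csv(path)
  need <- c("id", "x0", "y0", "x1", "y1", "thickness",
            "bg_x0", "bg_y0", "bg_x1", "bg_y1")
  if (!all(need %in% names(df)))
    stopf("probe CSV must have columns: %s", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    segment_probe(p0 = c(df$x0[i], df$y0[i]), p1 = c(df$x1[i], df$y1[i]),
                  thickness = df$thickness[i],
                  bg_region = c(df$bg_x0[i], df$bg_y0[i],
                                df$bg_x1[i], df$bg_y1[i]),
                  id = df$id[i]))
}

#' Read hand-traced vessel polylines from CSV
#'
#' Long format, columns `id, x, y`; points are ordered within each id.
#' @param path CSV path.
#' @return named list of n x 2 `(x, y)` matrices.
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("id", "x", "y") %in% names(df)))
    stopf("trace CSV must have columns: id, x, y")
  split_idx <- split(seq_len(nrow(df)), df$id)
  lapply(split_idx, function(i) cbind(x = df$x[i], y = df$y[i]))
}
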