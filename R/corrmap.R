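# ROI-grid construction and signed lagged cross-correlation maps against a
# reference ROI trace or a pupil trace.

#' Bin a movie into an ROI grid of mean-intensity traces
#'
#' Non-overlapping `roi_px` x `roi_px` blocks averaged per frame; trailing
#' rows/columns that do not fill a block are cropped.
#'
#' @param movie a [bf_movie].
#' @param roi_px ROI edge length in pixels (default 16, giving 64 x 64
#'   ROIs on a 1024 x 1024 frame).
#' @return a `roi_grid`: list with `traces` (array rows x cols x T),
#'   `roi_px`, `pixel_size`, `frame_interval`.
#' @export
bin_rois <- function(movie, roi_px = 16L) {
  stopifnot(inherits(movie, "bf_movie"))
  d <- dim(movie$data)
  nr <- d[1] %/% roi_px; nc <- d[2] %/% roi_px
  if (nr < 1 || nc < 1) stopf("roi_px larger than the image")
  dat <- movie$data[seq_len(nr * roi_px), seq_len(nc * roi_px), , drop = FALSE]
  dim(dat) <- c(roi_px, nr, roi_px, nc, d[3])
  traces <- apply(dat, c(2, 4, 5), mean)
  structure(list(traces = traces, roi_px = roi_px,
                 pixel_size = movie$pixel_size,
                 frame_interval = movie$frame_interval),
            class = "roi_grid")
}

#' Lagged cross-correlation, signed value at the best lag
#'
#' Pearson correlation of the overlapping samples at every integer lag in
#' `[-max_lag, max_lag]`; returns the signed coefficient at the lag with
#' the largest absolute value (ties broken toward the smaller |lag|).
#'
#' @param x,y numeric series of equal length (> 2 * max_lag), nonconstant.
#' @param max_lag sliding window half-width in frames (default 10).
#' @return list with `cc` (signed coefficient) and `lag` (frames; positive
#'   means `y` lags `x`).
#' @export
lagged_max_correlation <- function(x, y, max_lag = 10L) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n <= 2 * max_lag) stopf("series shorter than the lag window")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("constant series: correlation undefined")
  lags <- order(abs(seq(-max_lag, max_lag)))  # 0, -1, 1, -2, 2, ...
  lags <- seq(-max_lag, max_lag)[lags]
  best_cc <- NA_real_; best_lag <- NA_integer_
  for (lag in lags) {
    if (lag >= 0) { xi <- x[seq_len(n - lag)]; yi <- y[seq_len(n - lag) + lag] }
    else { xi <- x[seq_len(n + lag) - lag]; yi <- y[seq_len(n + lag)] }
    if (stats::sd(xi) == 0 || stats::sd(yi) == 0) next
    cc <- stats::cor(xi, yi)
    if (is.na(best_cc) || abs(cc) > abs(best_cc) + 1e-12) {
      best_cc <- cc; best_lag <- lag
    }
  }
  if (is.na(best_cc)) stopf("correlation undefined at every lag")
  list(cc = best_cc, lag = best_lag)
}

#' Lagged correlation map of an ROI grid against a reference trace
#'
#' Each ROI trace is ΔF/F-normalised (median baseline) and correlated with
#' the reference using [lagged_max_correlation()]. A reference sampled on
#' a different timebase is linearly resampled onto the grid timebase.
#'
#' @param grid a `roi_grid` from [bin_rois()].
#' @param reference numeric reference series (e.g. one ROI's trace or a
#'   pupil diameter trace).
#' @param max_lag lag window half-width in frames.
#' @param reference_times optional time stamps of `reference` (seconds)
#'   when its sampling differs from the grid's.
#' @return a `correlation_map`: list with `cc` and `lag` matrices and the
#'   `flagged` logical matrix marking constant ROIs (cc set to 0).
#' @export
correlation_map <- function(grid, reference, max_lag = 10L,
                            reference_times = NULL) {
  stopifnot(inherits(grid, "roi_grid"))
  d <- dim(grid$traces)
  nt <- d[3]
  if (!is.null(reference_times)) {
    t_grid <- (seq_len(nt) - 1) * grid$frame_interval
    reference <- stats::approx(reference_times, reference, xout = t_grid,
                               rule = 2)$y
  }
  if (length(reference) != nt)
    stopf("reference length %d does not match %d frames",
          length(reference), nt)
  ref <- reference
  cc <- matrix(0, d[1], d[2]); lag <- matrix(NA_integer_, d[1], d[2])
  flagged <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    tr <- grid$traces[i, j, ]
    if (stats::sd(tr) == 0 || stats::median(tr) <= 0) {
      flagged[i, j] <- TRUE
      next
    }
    r <- lagged_max_correlation(dff(tr), ref, max_lag)
    cc[i, j] <- r$cc; lag[i, j] <- r$lag
  }
  structure(list(cc = cc, lag = lag, flagged = flagged, max_lag = max_lag),
            class = "correlation_map")
}

#' Write a correlation map as CSV (row, col, cc, lag)
#' @param map a `correlation_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_correlation_csv <- function(map, path) {
  d <- dim(map$cc)
  df <- data.frame(row = rep(seq_len(d[1]), d[2]),
                   col = rep(seq_len(d[2]), each = d[1]),
                   cc = as.vector(map$cc), lag = as.vector(map$lag))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
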