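# Preprocessing: rigid registration, temporal smoothing/binning, local
# background subtraction and display normalisation.

#' Rigid lateral registration of a movie
#'
#' Each frame is translated by an integer pixel shift maximising its
#' circular cross-correlation (computed in the Fourier domain, with a Hann
#' window against border wrap-around) with a reference image — initially
#' the mean of the first 30 frames, then iteratively refined from the
#' registered frames until the shifts stabilise. Ties are broken toward
#' the smaller shift magnitude; exposed pixels are filled with the frame
#' median.
#'
#' @param movie a [bf_movie] with at least 2 frames.
#' @param n_reference number of leading frames averaged into the initial
#'   reference.
#' @param max_iter maximum reference-refinement iterations.
#' @return list with `movie` (registered) and `shifts` (T x 2 matrix of
#'   applied `(dy, dx)` corrections).
#' @export
register_rigid <- function(movie, n_reference = 30L, max_iter = 4L) {
  stopifnot(inherits(movie, "bf_movie"))
  d <- dim(movie$data)
  if (d[3] < 2) stopf("registration needs at least 2 frames")
  ref <- rowMeans(movie$data[, , seq_len(min(n_reference, d[3])), drop = FALSE],
                  dims = 2)
  if (stats::sd(ref) == 0 || all(apply(movie$data, 3, stats::sd) == 0)) {
    warnf("all-constant frames: registration returns zero shifts")
    return(list(movie = movie,
                shifts = matrix(0L, d[3], 2,
                                dimnames = list(NULL, c("dy", "dx")))))
  }
  ny <- d[1]; nx <- d[2]
  win <- outer(0.5 - 0.5 * cos(2 * pi * (seq_len(ny) - 1) / (ny - 1)),
               0.5 - 0.5 * cos(2 * pi * (seq_len(nx) - 1) / (nx - 1)))
  fwin <- function(img) stats::fft((img - mean(img)) * win)
  signed <- function(i, n) ifelse(i - 1 <= n / 2, i - 1, i - 1 - n)
  ffts <- lapply(seq_len(d[3]), function(t) fwin(movie$data[, , t]))
  shifts <- matrix(0L, d[3], 2, dimnames = list(NULL, c("dy", "dx")))
  for (iter in seq_len(max_iter)) {
    fref <- fwin(ref)
    new_shifts <- shifts
    for (t in seq_len(d[3])) {
      cc <- Re(stats::fft(fref * Conj(ffts[[t]]), inverse = TRUE))
      best <- max(cc)
      cand <- which(cc > best - 1e-9 * abs(best), arr.ind = TRUE)
      dys <- signed(cand[, 1], ny); dxs <- signed(cand[, 2], nx)
      pick <- which.min(abs(dys) + abs(dxs))
      new_shifts[t, ] <- c(dys[pick], dxs[pick])
    }
    converged <- all(new_shifts == shifts) && iter > 1
    shifts <- new_shifts
    reg <- vapply(seq_len(d[3]), function(t)
      shift_image(movie$data[, , t], shifts[t, 1], shifts[t, 2]),
      matrix(0, ny, nx))
    if (converged) break
    ref <- rowMeans(reg[, , seq_len(min(n_reference, d[3])), drop = FALSE],
                    dims = 2)
  }
  list(movie = bf_movie(reg, movie$pixel_size, movie$frame_interval),
       shifts = shifts)
}

#' Centered moving average with truncated edges
#'
#' @param series numeric vector, or a [bf_movie] (averaged along time).
#' @param window odd window length in samples/frames.
#' @return object of the same type, same length.
#' @export
moving_average <- function(series, window) {
  if (window < 1 || window %% 2 == 0) stopf("window must be odd and >= 1")
  if (inherits(series, "bf_movie")) {
    d <- dim(series$data)
    if (window > d[3]) stopf("window longer than the movie")
    m <- matrix(series$data, d[1] * d[2], d[3])
    sm <- t(moving_average_mat(t(m), window))
    return(bf_movie(array(sm, d), series$pixel_size, series$frame_interval))
  }
  if (window > length(series)) stopf("window longer than the series")
  drop(moving_average_mat(matrix(series, ncol = 1), window))
}

# column-wise centered moving mean with truncated windows at the edges
moving_average_mat <- function(m, window) {
  n <- nrow(m)
  h <- (window - 1L) / 2L
  cs <- rbind(0, apply(m, 2, cumsum))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L); hi <- pmin(i + h, n)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
}

#' Temporal binning of a movie
#'
#' Non-overlapping mean bins of `bin_seconds`; a trailing partial bin is
#' dropped and the frame interval is updated.
#'
#' @param movie a [bf_movie].
#' @param bin_seconds bin length in seconds (>= frame interval).
#' @return a binned [bf_movie].
#' @export
temporal_bin <- function(movie, bin_seconds) {
  stopifnot(inherits(movie, "bf_movie"))
  k <- max(1L, round(bin_seconds / movie$frame_interval))
  d <- dim(movie$data)
  nb <- d[3] %/% k
  if (nb < 1) stopf("bin longer than the movie")
  m <- matrix(movie$data[, , seq_len(nb * k), drop = FALSE], d[1] * d[2])
  dim(m) <- c(d[1] * d[2], k, nb)
  binned <- apply(m, 3, rowMeans)
  bf_movie(array(binned, c(d[1], d[2], nb)), movie$pixel_size,
           movie$frame_interval * k)
}

#' Frame-by-frame local background subtraction
#'
#' Removes shared background fluctuations near a capillary: per frame the
#' mean of the background ROI is subtracted, then the session-averaged
#' background value is added back, so absolute intensities are preserved.
#'
#' @param movie a [bf_movie].
#' @param bg_roi logical mask (rows x cols) or rectangle `c(x0, y0, x1, y1)`
#'   selecting vessel-free background pixels.
#' @return corrected [bf_movie].
#' @export
subtract_local_background <- function(movie, bg_roi) {
  stopifnot(inherits(movie, "bf_movie"))
  d <- dim(movie$data)
  mask <- as_mask(bg_roi, d[1], d[2])
  if (!any(mask)) stopf("background ROI is empty")
  m <- matrix(movie$data, d[1] * d[2], d[3])
  bg_t <- colMeans(m[as.vector(mask), , drop = FALSE])
  corr <- sweep(m, 2, bg_t - mean(bg_t))
  bf_movie(array(corr, d), movie$pixel_size, movie$frame_interval)
}

# rectangle c(x0, y0, x1, y1) in pixel coords, or a logical mask
as_mask <- function(roi, ny, nx) {
  if (is.logical(roi)) {
    stopifnot(all(dim(roi) == c(ny, nx)))
    return(roi)
  }
  stopifnot(is.numeric(roi), length(roi) == 4)
  xs <- sort(round(roi[c(1, 3)])); ys <- sort(round(roi[c(2, 4)]))
  if (xs[1] < 1 || xs[2] > nx || ys[1] < 1 || ys[2] > ny)
    stopf("ROI rectangle outside the image")
  m <- matrix(FALSE, ny, nx)
  m[ys[1]:ys[2], xs[1]:xs[2]] <- TRUE
  m
}

#' Square-root display normalisation
#'
#' Maps an image to `[0, 1]` by taking the square root (negatives clipped
#' to zero) and rescaling from minimum to maximum; used for display of
#' volume projections so dim capillaries stay visible next to bright
#' vessels.
#'
#' @param image numeric matrix or array.
#' @return normalised object of the same shape, values in `[0, 1]`.
#' @export
sqrt_display_normalize <- function(image) {
  s <- sqrt(pmax(image, 0))
  rng <- range(s)
  if (rng[2] == rng[1]) {
    warnf("constant image: normalisation returns zeros")
    return(array(0, dim(image) %||% length(image)))
  }
  (s - rng[1]) / (rng[2] - rng[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
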