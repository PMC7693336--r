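# Pupillometry: dark-region oval fitting on infrared eye videos.

#' Segment the pupil in a single frame as an oval
#'
#' Binarises the frame below an automatic threshold (the valley between
#' the two main intensity modes; falls back to the 5th percentile when no
#' valley is found), keeps the largest connected dark component, and fits
#' an oval from its second moments. Width and height are the axis-aligned
#' extents of the fitted oval: for an ideal filled ellipse the axis-aligned
#' variance of the pixel x-coordinates is (width/4)^2, so width = 4 * sd(x).
#'
#' @param frame numeric intensity matrix (bright iris, dark pupil).
#' @param min_area minimum component area in pixels for a valid fit.
#' @return list with `valid`, `center` c(x, y), `width`, `height` (pixels)
#'   and `angle` (radians, principal-axis orientation).
#' @export
segment_pupil <- function(frame, min_area = 20L) {
  thr <- histogram_valley_threshold(frame)
  mask <- frame < thr
  if (!any(mask))
    return(list(valid = FALSE, center = c(NA, NA), width = NA_real_,
                height = NA_real_, angle = NA_real_))
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  if (sizes[big] < min_area)
    return(list(valid = FALSE, center = c(NA, NA), width = NA_real_,
                height = NA_real_, angle = NA_real_))
  idx <- which(lab == big, arr.ind = TRUE)
  ys <- idx[, 1]; xs <- idx[, 2]
  cx <- mean(xs); cy <- mean(ys)
  sxx <- stats::var(xs); syy <- stats::var(ys); sxy <- stats::cov(xs, ys)
  angle <- 0.5 * atan2(2 * sxy, sxx - syy)
  list(valid = TRUE, center = c(cx, cy),
       width = 4 * sqrt(sxx), height = 4 * sqrt(syy), angle = angle)
}

# threshold at the histogram valley between the two dominant modes,
# falling back to the 5th percentile of the intensities
histogram_valley_threshold <- function(frame, n_bins = 64L) {
  if (diff(range(frame)) == 0) return(frame[1])  # constant frame
  h <- graphics::hist(frame, breaks = n_bins, plot = FALSE)
  if (length(h$counts) < 5) return(stats::quantile(frame, 0.05, names = FALSE))
  cnt <- as.numeric(stats::filter(h$counts, rep(1 / 3, 3), sides = 2))
  cnt[is.na(cnt)] <- h$counts[is.na(cnt)]
  n <- length(cnt)
  peaks <- which(cnt > c(-Inf, cnt[-n]) & cnt >= c(cnt[-1], -Inf) & cnt > 0)
  if (length(peaks) >= 2) {
    main <- peaks[order(cnt[peaks], decreasing = TRUE)][1:2]
    lo <- min(main); hi <- max(main)
    if (hi - lo >= 2) {
      valley <- lo + which.min(cnt[(lo + 1):(hi - 1)])
      return(h$mids[valley])
    }
  }
  stats::quantile(frame, 0.05, names = FALSE)
}

# 4-connected component labelling by flood fill (iterative stack)
label_components <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  cur <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      y <- (p - 1L) %% ny + 1L; x <- (p - 1L) %/% ny + 1L
      nb <- c(if (y > 1) p - 1L, if (y < ny) p + 1L,
              if (x > 1) p - ny, if (x < nx) p + ny)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      stack <- c(stack, nb)
    }
  }
  lab
}

#' Pupil diameter trace from an eye video
#'
#' Runs [segment_pupil()] on every frame and uses the oval width (not
#' height, to reduce squinting/blinking artifacts) as pupil diameter.
#' Invalid frames are linearly interpolated from valid neighbours.
#'
#' @param video a [bf_movie] of eye frames.
#' @param min_area minimum pupil component area, pixels.
#' @return a `pupil_trace` data frame: `t` (s), `width`, `height`,
#'   `center_x`, `center_y` (pixels), `valid` (logical).
#' @export
pupil_diameter_trace <- function(video, min_area = 20L) {
  stopifnot(inherits(video, "bf_movie"))
  nt <- dim(video$data)[3]
  fits <- lapply(seq_len(nt), function(t)
    segment_pupil(video$data[, , t], min_area = min_area))
  valid <- vapply(fits, `[[`, logical(1), "valid")
  if (!any(valid)) stopf("no valid pupil fit in any frame")
  w <- vapply(fits, `[[`, numeric(1), "width")
  h <- vapply(fits, `[[`, numeric(1), "height")
  cx <- vapply(fits, function(f) f$center[1], numeric(1))
  cy <- vapply(fits, function(f) f$center[2], numeric(1))
  interp <- function(v) {
    if (all(valid)) return(v)
    stats::approx(which(valid), v[valid], xout = seq_len(nt), rule = 2)$y
  }
  structure(data.frame(
    t = (seq_len(nt) - 1) * video$frame_interval,
    width = interp(w), height = interp(h),
    center_x = interp(cx), center_y = interp(cy), valid = valid),
    class = c("pupil_trace", "data.frame"))
}
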