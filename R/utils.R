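# Internal numerical helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded phantom generation does
#' not disturb the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Full width at half maximum of a sampled 1-D profile
#'
#' Finds the half-maximum crossings on either side of the global maximum by
#' linear interpolation on the sampling grid. The half level is taken between
#' `floor` (default 0) and the profile maximum.
#'
#' @param x monotone increasing coordinate grid.
#' @param y non-negative intensity samples.
#' @param floor baseline intensity subtracted before halving.
#' @return width in the units of `x`.
#' @noRd
profile_fwhm <- function(x, y, floor = 0) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ymax <- max(y)
  if (!is.finite(ymax) || ymax <= floor)
    stopf("profile has no peak above the baseline")
  half <- floor + (ymax - floor) / 2
  imax <- which.max(y)
  # left crossing
  left <- NA_real_
  for (i in seq(imax, 2L)) {
    if (y[i - 1L] < half && y[i] >= half) {
      left <- x[i - 1L] + (half - y[i - 1L]) / (y[i] - y[i - 1L]) * (x[i] - x[i - 1L])
      break
    }
  }
  right <- NA_real_
  n <- length(y)
  if (imax < n) for (i in seq(imax, n - 1L)) {
    if (y[i] >= half && y[i + 1L] < half) {
      right <- x[i] + (y[i] - half) / (y[i] - y[i + 1L]) * (x[i + 1L] - x[i])
      break
    }
  }
  if (is.na(left) || is.na(right))
    stopf("profile does not fall below half maximum on both sides")
  right - left
}

#' Bilinear interpolation of an image at fractional pixel coordinates
#'
#' Coordinates follow the (row, col) = (y, x) convention with 1-based pixel
#' centres; points outside the image are clamped to the border.
#' @noRd
bilinear_sample <- function(img, y, x) {
  ny <- nrow(img); nx <- ncol(img)
  y <- pmin(pmax(y, 1), ny)
  x <- pmin(pmax(x, 1), nx)
  y0 <- pmin(floor(y), ny - 1L); x0 <- pmin(floor(x), nx - 1L)
  fy <- y - y0; fx <- x - x0
  i00 <- (x0 - 1) * ny + y0
  img[i00]           * (1 - fy) * (1 - fx) +
    img[i00 + 1]     * fy       * (1 - fx) +
    img[i00 + ny]    * (1 - fy) * fx +
    img[i00 + ny + 1] * fy      * fx
}

#' Sample an image along a polyline at fixed arc-length steps
#'
#' @param pts n x 2 matrix of (x, y) pixel coordinates.
#' @param step arc-length step in pixels.
#' @return list with `x`, `y` sample coordinates and `s` cumulative arc length.
#' @noRd
resample_polyline <- function(pts, step = 1) {
  stopifnot(is.matrix(pts), ncol(pts) == 2, nrow(pts) >= 2)
  d <- sqrt(rowSums(diff(pts)^2))
  if (any(d == 0)) stopf("polyline has repeated consecutive points")
  s_knots <- c(0, cumsum(d))
  total <- s_knots[length(s_knots)]
  s <- seq(0, total, by = step)
  if (s[length(s)] < total) s <- c(s, total)
  x <- stats::approx(s_knots, pts[, 1], xout = s)$y
  y <- stats::approx(s_knots, pts[, 2], xout = s)$y
  list(x = x, y = y, s = s, total = total)
}

#' Separable Gaussian blur of a 2-D image (reflecting boundaries)
#' @noRd
gaussian_blur2d <- function(img, sigma) {
  if (sigma <= 0) return(img)
  h <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-h, h), sd = sigma)
  k <- k / sum(k)
  img <- conv1d_reflect(img, k, along = 1L)
  conv1d_reflect(img, k, along = 2L)
}

# 1-D convolution along rows (along=1) or cols (along=2) with reflection.
conv1d_reflect <- function(img, k, along) {
  h <- (length(k) - 1L) / 2L
  n <- dim(img)[along]
  idx <- seq_len(n)
  out <- array(0, dim(img))
  for (j in seq_along(k)) {
    off <- j - h - 1L
    src <- idx + off
    src[src < 1L] <- 2L - src[src < 1L]
    src[src > n] <- 2L * n - src[src > n]
    if (along == 1L) out <- out + k[j] * img[src, , drop = FALSE]
    else out <- out + k[j] * img[, src, drop = FALSE]
  }
  out
}

#' 3x3 Sobel gradient magnitude (reflecting boundaries)
#' @noRd
sobel_magnitude <- function(img) {
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- conv2d_reflect(img, sx)
  gy <- conv2d_reflect(img, t(sx))
  sqrt(gx^2 + gy^2)
}

conv2d_reflect <- function(img, k) {
  hk <- (nrow(k) - 1L) / 2L
  wk <- (ncol(k) - 1L) / 2L
  ny <- nrow(img); nx <- ncol(img)
  out <- matrix(0, ny, nx)
  ry <- seq_len(ny); rx <- seq_len(nx)
  for (a in seq_len(nrow(k))) for (b in seq_len(ncol(k))) {
    if (k[a, b] == 0) next
    sy <- ry + (a - hk - 1L)
    sy[sy < 1L] <- 2L - sy[sy < 1L]; sy[sy > ny] <- 2L * ny - sy[sy > ny]
    sx2 <- rx + (b - wk - 1L)
    sx2[sx2 < 1L] <- 2L - sx2[sx2 < 1L]; sx2[sx2 > nx] <- 2L * nx - sx2[sx2 > nx]
    out <- out + k[a, b] * img[sy, sx2]
  }
  out
}

#' Integer-shift an image, filling exposed pixels
#' @noRd
shift_image <- function(img, dy, dx, fill = stats::median(img)) {
  ny <- nrow(img); nx <- ncol(img)
  out <- matrix(fill, ny, nx)
  ys <- seq_len(ny) - dy; xs <- seq_len(nx) - dx
  keep_y <- ys >= 1 & ys <= ny
  keep_x <- xs >= 1 & xs <= nx
  out[which(keep_y), which(keep_x)] <- img[ys[keep_y], xs[keep_x]]
  out
}

# Linear R^2 of y on x (squared Pearson correlation).
rsq <- function(x, y) stats::cor(x, y)^2
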