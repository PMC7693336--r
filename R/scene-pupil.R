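# Synthetic infrared eye video: a dark pupil ellipse whose width follows
# the (low-pass filtered) arousal trace on a bright iris background.

#' Simulate an infrared pupil video from the scene ground truth
#'
#' The true pupil diameter is `p(t) = base * (1 + gain * pupil_rel(t))`
#' where `pupil_rel` is the arousal trace passed through a first-order
#' low-pass with time constant `config$pupil_tau` (pupil dynamics are
#' slower than vessel dilation). Frames show a dark filled ellipse of width
#' `p(t)` and height `0.75 p(t)` on a bright iris, optionally with a small
#' bright specular reflection, plus Gaussian camera noise.
#'
#' @param truth `ground_truth` from [build_network()].
#' @param config the [scene_config].
#' @param frame_size c(rows, cols) of the video.
#' @param base_diameter mean pupil width in pixels.
#' @param gain fractional width modulation per unit `pupil_rel`.
#' @param specular add a bright specular spot inside the pupil.
#' @param noise_sd camera noise standard deviation (grey levels).
#' @return list with `movie` (a [bf_movie]) and `trace` (data frame `t`,
#'   `width_px`: the ground-truth pupil width per frame).
#' @export
simulate_pupil <- function(truth, config, frame_size = c(80, 100),
                           base_diameter = 36, gain = 0.2,
                           specular = TRUE, noise_sd = 4) {
  stopifnot(inherits(truth, "ground_truth"))
  ny <- frame_size[1]; nx <- frame_size[2]
  p <- base_diameter * (1 + gain * truth$pupil_rel)
  # the ellipse must stay inside the frame
  p <- pmin(p, 0.9 * nx, 0.9 * ny / 0.75)
  cy <- ny / 2; cx <- nx / 2
  xs <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  ys <- matrix(seq_len(ny), ny, nx)
  nt <- length(p)
  dat <- array(0, c(ny, nx, nt))
  for (t in seq_len(nt)) {
    a <- p[t] / 2; b <- 0.75 * p[t] / 2
    inside <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
    frame <- matrix(120, ny, nx)
    frame[inside] <- 20
    if (specular) {
      rs <- 0.12 * p[t]
      spot <- (xs - (cx - 0.3 * a))^2 + (ys - (cy - 0.3 * b))^2 <= rs^2
      frame[spot & inside] <- 220
    }
    dat[, , t] <- frame
  }
  if (noise_sd > 0)
    dat <- with_seed(config$seed + 91L, {
      pmax(dat + array(stats::rnorm(length(dat), sd = noise_sd), dim(dat)), 0)
    })
  list(movie = bf_movie(dat, 1, 1 / config$frame_rate),
       trace = data.frame(t = truth$t, width_px = p))
}
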