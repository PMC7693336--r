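# Vessel size/brightness measurement and dynamics.

test_that("common threshold is mean + 3 sample sd of the background", {
  img <- matrix(0, 20, 20)
  img[1:10, 1:10] <- rep(c(8, 12), 50)  # mean 10, sd ~2.005
  thr <- common_threshold(img, c(1, 1, 10, 10))
  v <- img[1:10, 1:10]
  expect_equal(thr, mean(v) + 3 * sd(v))
  expect_equal(common_threshold(matrix(5, 4, 4), c(1, 1, 4, 4)), 5)
  # noiseless phantom: zero background -> threshold 0, all lumen above
  ph <- ph_cylinder(8, pixel_size = 1, vol_y = 40)
  img2 <- render_bessel_projection(ph$net$network, ph$net$truth,
                                   ph$cfg)$data[, , 1]
  thr2 <- common_threshold(img2, c(1, 1, 10, 5))
  expect_equal(thr2, 0)
  expect_true(all(img2[18:22, 30] > thr2))
})

test_that("Bessel probe measures cylinder size within a pixel", {
  for (d in c(4, 8, 14)) {
    ph <- ph_cylinder(d)
    img <- render_bessel_projection(ph$net$network, ph$net$truth,
                                    ph$cfg)$data[, , 1]
    pr <- segment_probe(c(30, 5), c(30, 35), thickness = 1)
    thr <- common_threshold(img, c(1, 1, 10, 5))
    m <- bessel_segment_measure(img, pr, threshold = max(thr, 0.25 * max(img)))
    expect_lt(abs(m$size_px - d), 1.6, label = sprintf("diameter %d", d))
    # doubling the gain doubles brightness, size unchanged
    m2 <- bessel_segment_measure(img * 2, pr,
                                 threshold = 2 * max(thr, 0.25 * max(img)))
    expect_equal(m2$brightness, 2 * m$brightness)
    expect_equal(m2$size_px, m$size_px)
  }
  # all-background line
  img0 <- matrix(0, 40, 60); img0[35, ] <- 9
  pr0 <- segment_probe(c(10, 2), c(10, 20), thickness = 1)
  expect_equal(bessel_segment_measure(img0, pr0, threshold = 1)$size_px, 0)
  expect_error(bessel_segment_measure(img0,
    segment_probe(c(-5, 2), c(10, 2), thickness = 1), threshold = 1),
    "outside")
})

test_that("Gaussian cross-section FWHM tracks the cylinder diameter", {
  ph <- ph_cylinder(10, z0 = 40, z_render_step = 0.25)
  net <- ph$net; cfg <- ph$cfg
  stk <- render_gaussian_stack(net$network, net$truth, cfg, z_step = 1)
  pr <- segment_probe(c(30, 10), c(30, 30), thickness = 1)
  m <- gaussian_cross_section_measure(stk, pr)
  expect_equal(m$size_um, 10, tolerance = 0.1 * 10)
  # intensity scaling leaves the size unchanged
  stk2 <- bf_stack(stk$data * 7, stk$pixel_size, stk$z_step)
  expect_equal(gaussian_cross_section_measure(stk2, pr)$size_um, m$size_um)
  expect_equal(gaussian_cross_section_measure(stk2, pr)$brightness,
               7 * m$brightness)
  empty <- bf_stack(array(0, c(40, 60, 10)), 1, 1)
  expect_warning(e <- gaussian_cross_section_measure(empty, pr), "reslice|signal")
  expect_equal(e$size_um, 0)
})

test_that("diameter time series recovers static and oscillating widths", {
  # static cylinder
  ph <- ph_cylinder(8, frames = 20, noise_photons = 40, rbc = TRUE,
                    speed = 0.5)
  mov <- render_bessel_projection(ph$net$network, ph$net$truth, ph$cfg)
  sm <- moving_average(mov, 5)
  pr <- segment_probe(c(30, 6), c(30, 35), thickness = 10)
  dia <- diameter_timeseries(sm, pr, c(2, 2, 12, 6))
  expect_true(all(abs(dia - 8) <= 1.5))
  # sinusoidally dilating vessel: frequency and amplitude recovered
  cfg <- scene_config(volume_size = c(60, 40, 50), pixel_size = 1,
                      frame_rate = 15, duration = 30, vasomotion_freq = 0.2,
                      vasomotion_amp = 0.15, arousal_coupling = 0,
                      noise_photons = 60, seed = 17)
  net <- manual_network(list(rbind(c(0, 20, 25), c(60, 20, 25))),
                        radii = 5, speeds = 0.5, signs = 1, config = cfg)
  mv <- moving_average(render_bessel_projection(net$network, net$truth, cfg), 5)
  d2 <- diameter_timeseries(mv, pr, c(2, 2, 12, 6))
  sp <- spec.pegram <- stats::spec.pgram(ts(d2 - mean(d2), frequency = 15),
                                         plot = FALSE, taper = 0)
  expect_equal(sp$freq[which.max(sp$spec)], 0.2, tolerance = 0.05)
  # amplitude: fitted sine amplitude within 15% of the true 1.5 um
  tt <- net$truth$t
  fit <- lm(d2 ~ sin(2 * pi * 0.2 * tt) + cos(2 * pi * 0.2 * tt))
  amp <- sqrt(sum(coef(fit)[2:3]^2))
  expect_equal(amp, 2 * 5 * 0.15, tolerance = 0.15 * 2 * 5 * 0.15)
  # empty field -> all zero with warning
  empty <- bf_movie(array(0, c(40, 60, 6)), 1, 1 / 15)
  expect_warning(z <- diameter_timeseries(empty, pr, c(2, 2, 12, 6)),
                 "zero")
  expect_true(all(z == 0))
})

test_that("dF/F about the median behaves and validates", {
  expect_equal(dff(c(2, 4, 6)), c(-0.5, 0, 0.5))
  expect_equal(dff(rep(3, 5)), rep(0, 5))
  set.seed(4)
  x <- runif(50, 1, 2)
  expect_equal(dff(3 * x), dff(x))
  expect_equal(median(dff(x)), 0)
  expect_error(dff(c(-2, -1, 0)), "median")
})

test_that("size-brightness R^2 matches closed cases", {
  expect_equal(size_brightness_correlation(1:10, 3 + 2 * (1:10)), 1)
  set.seed(5)
  x <- rnorm(1e4); y <- rnorm(1e4)
  expect_lt(size_brightness_correlation(x, y), 0.01)
  expect_equal(size_brightness_correlation(x, y),
               size_brightness_correlation(2 * x + 1, -3 * y + 5))
  expect_error(size_brightness_correlation(rep(1, 5), 1:5), "variance")
})

test_that("temporal variation map masks dim pixels and scales as sd/mean", {
  # constant movie -> zero map
  cm <- temporal_variation_map(bf_movie(array(4, c(5, 5, 6)), 1, 1))
  expect_true(all(cm == 0))
  # one bright pixel with +-20% sinusoidal modulation -> cv = 0.2/sqrt(2)
  nt <- 200
  arr <- array(rep(matrix(runif(100, 1, 2), 10), nt), c(10, 10, nt))
  arr[5, 5, ] <- 100 * (1 + 0.2 * sin(2 * pi * (1:nt) / 25))
  tvm <- temporal_variation_map(bf_movie(arr, 1, 1))
  expect_equal(tvm[5, 5], 0.2 / sqrt(2), tolerance = 0.01)
  # exactly 20% of pixels survive the dim mask on a generic image
  expect_equal(sum(tvm != 0 | (tvm == 0 & rank(-rowMeans(matrix(arr, 100, nt)))
                               <= 20)) >= 20, TRUE)
  expect_equal(sum(rowMeans(matrix(arr, 100, nt)) >
                     quantile(rowMeans(matrix(arr, 100, nt)), 0.8)), 20)
})
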