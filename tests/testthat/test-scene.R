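# Synthetic scene: network generation, rendering physics, motion, pupil.

test_that("network generation is deterministic and respects its config", {
  cfg <- scene_config(duration = 2, seed = 42)
  a <- build_network(cfg)
  b <- build_network(cfg)
  expect_identical(a, b)
  # static world when both modulation sources are off
  cfg0 <- scene_config(duration = 2, vasomotion_amp = 0,
                       arousal_coupling = 0, seed = 1)
  n0 <- build_network(cfg0)
  expect_true(all(apply(n0$truth$radius_t, 1, function(r)
    diff(range(r)) == 0)))
  # capillaries stay below 6 um diameter
  caps <- Filter(function(s) s$type == "capillary", n0$network$segments)
  expect_true(all(vapply(caps, function(s) 2 * s$r0, numeric(1)) < 6))
  expect_error(scene_config(radius_ranges = list(pial = c(3, 8),
                                                 penetrating = c(2.5, 5),
                                                 capillary = c(1, 4))),
               "capillary")
  expect_error(build_network(scene_config(volume_size = c(10, 10, 10),
                                          duration = 1)), "too small")
})

test_that("opposite population signs give anticorrelated radius dynamics", {
  cfg <- scene_config(duration = 30, vasomotion_amp = 0.1,
                      arousal_coupling = 0.15, seed = 7)
  net <- manual_network(list(rbind(c(0, 20, 20), c(100, 20, 20)),
                             rbind(c(0, 60, 20), c(100, 60, 20))),
                        radii = 4, speeds = 1, signs = c(1, -1), config = cfg)
  expect_lt(cor(net$truth$radius_t[1, ], net$truth$radius_t[2, ]), -0.5)
})

test_that("rendering basics: empty scene, static scene, determinism", {
  cfg <- scene_config(volume_size = c(30, 30, 40), duration = 3 / 15,
                      vasomotion_amp = 0, arousal_coupling = 0,
                      noise_photons = 0, seed = 1)
  net <- manual_network(list(rbind(c(0, 15, 20), c(30, 15, 20))),
                        radii = 3, speeds = 0, signs = 1, config = cfg)
  # zero-speed RBCs, noiseless -> identical frames
  mov <- render_bessel_projection(net$network, net$truth, cfg)
  expect_equal(mov$data[, , 1], mov$data[, , 3])
  # empty network -> all-zero movie (noiseless)
  net0 <- net; net0$network$segments <- list()
  mov0 <- render_bessel_projection(net0$network, net0$truth, cfg)
  expect_true(all(mov0$data == 0))
  # Poisson rendering is reproducible under the config seed
  cfgN <- scene_config(volume_size = c(30, 30, 40), duration = 2 / 15,
                       noise_photons = 20, seed = 9)
  netN <- manual_network(list(rbind(c(0, 15, 20), c(30, 15, 20))),
                         radii = 3, speeds = 1, signs = 1, config = cfgN)
  m1 <- render_bessel_projection(netN$network, netN$truth, cfgN)
  m2 <- render_bessel_projection(netN$network, netN$truth, cfgN)
  expect_identical(m1$data, m2$data)
})

test_that("total dye signal is conserved while RBC shadows advect", {
  # slow flow keeps the recirculation track equal to the vessel length, so
  # the number of RBCs inside is fixed and only their positions change
  cfg <- scene_config(volume_size = c(120, 30, 60), pixel_size = 1,
                      frame_rate = 99, duration = 20 / 99,
                      vasomotion_amp = 0, arousal_coupling = 0,
                      noise_photons = 0, rbc_spacing = 25,
                      z_render_step = 0.5, seed = 4)
  net <- manual_network(list(rbind(c(0, 15, 30), c(120, 15, 30))),
                        radii = 2.4, speeds = 0.05, signs = 1, config = cfg)
  mov <- render_bessel_projection(net$network, net$truth, cfg)
  totals <- apply(mov$data, 3, sum)
  expect_lt(diff(range(totals)) / mean(totals), 0.01)
})

test_that("Bessel lumen brightness doubles with cylinder diameter", {
  peak_for <- function(d) {
    ph <- ph_cylinder(d)
    max(render_bessel_projection(ph$net$network, ph$net$truth,
                                 ph$cfg)$data)
  }
  expect_equal(peak_for(12) / peak_for(6), 2, tolerance = 0.02)
})

test_that("Gaussian-plane signal saturates with diameter and dies off-plane", {
  peak_g <- function(d, z0 = 40) {
    ph <- ph_cylinder(d, z0 = z0)
    max(render_gaussian_plane(ph$net$network, ph$net$truth, ph$cfg,
                              z_plane = 40)$data)
  }
  expect_equal(peak_g(12) / peak_g(6), 1, tolerance = 0.1)
  # vessel 30 um away from the focal plane: < 1% of in-plane signal
  expect_lt(peak_g(6, z0 = 70) / peak_g(6), 0.01)
})

test_that("noiseless Bessel brightness is linear in diameter, Gaussian flat", {
  diams <- seq(2, 20, by = 2)
  peaks <- vapply(diams, function(d) {
    ph <- ph_cylinder(d)
    c(max(render_bessel_projection(ph$net$network, ph$net$truth, ph$cfg)$data),
      max(render_gaussian_plane(ph$net$network, ph$net$truth, ph$cfg,
                                z_plane = 40)$data))
  }, numeric(2))
  expect_gt(cor(diams, peaks[1, ])^2, 0.95)
  g <- peaks[2, diams >= 6]
  expect_lt((max(g) - min(g)) / mean(g), 0.1)
})

test_that("apply_motion records exactly the shifts it applies", {
  cfg <- scene_config(volume_size = c(40, 40, 40), duration = 10 / 15,
                      noise_photons = 30, seed = 6)
  net <- manual_network(list(rbind(c(0, 20, 20), c(40, 20, 20))),
                        radii = 4, speeds = 1, signs = 1, config = cfg)
  mov <- render_bessel_projection(net$network, net$truth, cfg)
  # amplitude 0 -> identity
  still <- apply_motion(mov, 0)
  expect_identical(still$movie$data, mov$data)
  expect_true(all(still$shifts == 0))
  shaken <- apply_motion(mov, 3, seed = 11)
  expect_true(any(shaken$shifts != 0))
  for (t in seq_len(dim(mov$data)[3])) {
    dy <- shaken$shifts[t, 1]; dx <- shaken$shifts[t, 2]
    ref <- besselflow:::shift_image(mov$data[, , t], dy, dx)
    expect_equal(shaken$movie$data[, , t], ref)
  }
  expect_error(apply_motion(mov, 20), "10%")
})

test_that("pupil simulation follows a slow filtered arousal trace", {
  cfg <- scene_config(duration = 20, frame_rate = 15, pupil_tau = 2,
                      seed = 13)
  net <- build_network(cfg)
  sim <- simulate_pupil(net$truth, cfg, noise_sd = 0)
  # ellipse always inside the frame: border pixels stay iris-bright
  border <- c(sim$movie$data[1, , ], sim$movie$data[80, , ],
              sim$movie$data[, 1, ], sim$movie$data[, 100, ])
  expect_true(all(border > 100))
  # constant arousal -> constant pupil
  flat <- net$truth; flat$pupil_rel <- rep(0, length(flat$pupil_rel))
  sim0 <- simulate_pupil(flat, cfg, noise_sd = 0)
  expect_equal(diff(range(sim0$trace$width_px)), 0)
  # first-order step response crosses 63% at ~tau
  dt <- 0.01; tau <- 2
  step <- besselflow:::lowpass_first_order(c(0, rep(1, 1000)), tau, dt)
  t63 <- dt * (which(step >= 1 - exp(-1))[1] - 1)
  expect_equal(t63, tau, tolerance = 0.1)
})
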