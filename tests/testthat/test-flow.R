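# Kymograph extraction, skeletonization, 2D->3D remapping, Radon
# velocimetry, rejection rules, segment diameter.

test_that("kymograph extraction samples the trace per frame", {
  # static bright line along the trace -> constant columns
  img <- matrix(0, 20, 40)
  img[10, ] <- 50
  mv <- bf_movie(array(rep(img, 6), c(20, 40, 6)), 2, 0.01)
  tr <- cbind(x = c(3, 38), y = c(10, 10))
  ky <- extract_kymograph(mv, tr)
  expect_s3_class(ky, "kymograph")
  expect_equal(nrow(ky$data), 6)
  expect_equal(ncol(ky$data), round(35) + 1)  # arc length / px + 1
  expect_true(all(apply(ky$data, 2, function(cl) diff(range(cl))) == 0))
  expect_equal(ky$dx, 2)
  expect_equal(ky$dt, 0.01)
  expect_error(extract_kymograph(mv, cbind(x = c(-1, 5), y = c(1, 1))),
               "outside")
})

test_that("Radon estimator agrees with the centroid oracle on clean blocks", {
  # clean two-streak blocks: per-row darkness centroid moves at the streak
  # slope, so a least-squares fit is an independent speed oracle
  dx <- 3.25; dt <- 1 / 99
  for (v_true in c(0.1, 0.15)) {  # slopes keep both streaks inside the block
    slope <- v_true * 1000 * dt / dx
    blk <- matrix(100, 50, 60)
    for (r in 1:50) for (s0 in c(5, 35)) {
      cols <- intersect(round(s0 + slope * r) + (-1:1), 1:60)
      blk[r, cols] <- 40
    }
    v_oracle <- centroid_slope_speed(blk, dx, dt)
    expect_equal(v_oracle, v_true, tolerance = 0.05)
    v_radon <- radon_block_speed(blk, dx, dt)
    expect_equal(v_radon, v_oracle, tolerance = 0.05)
  }
  # and on a rendered kymograph block the Radon value matches the truth
  ph <- ph_flow_inplane(1, duration = 4)
  ky <- extract_kymograph(ph$movie, ph$trace)
  expect_equal(radon_block_speed(ky$data[1:50, ], ky$dx, ky$dt), 1,
               tolerance = 0.1)
})

test_that("radon block speed: synthetic streaks, statics, mirror symmetry", {
  # clean synthetic streak block at exactly 1.0 mm/s (dx 3.25, dt 1/99)
  dx <- 3.25; dt <- 1 / 99
  slope_px <- 1 * 1000 * dt / dx  # px per row
  mk_block <- function(slope, n_r = 50, n_c = 60, n_streaks = 12) {
    b <- matrix(100, n_r, n_c)
    starts <- seq(-n_r * abs(slope) - 10, n_c + 10,
                  length.out = n_streaks)
    for (s0 in starts) for (r in seq_len(n_r)) {
      cc <- round(s0 + slope * r)
      cols <- intersect(cc + (-1:1), seq_len(n_c))
      b[r, cols] <- 30
    }
    b
  }
  v <- radon_block_speed(mk_block(slope_px), dx, dt)
  expect_equal(v, 1, tolerance = 0.1)
  # vertical streaks = stationary shadows -> 0 mm/s
  v0 <- radon_block_speed(mk_block(0), dx, dt)
  expect_equal(v0, 0, tolerance = 0.02)
  # mirror flip negates the speed
  b <- mk_block(slope_px)
  expect_equal(radon_block_speed(b[, ncol(b):1], dx, dt), -v,
               tolerance = 0.02)
  # featureless noise block is flagged flat
  set.seed(7)
  flatb <- matrix(rnorm(50 * 60, 100, 0.5), 50, 60)
  expect_true(is.na(radon_block_speed(flatb, dx, dt)))
  expect_error(radon_block_speed(matrix(1, 20, 60), dx, dt), "50 rows")
  expect_error(radon_block_speed(matrix(1, 50, 5), dx, dt), "8 columns")
})

test_that("flow_trace blocks, medians, and the rejection rules", {
  ph <- ph_flow_inplane(2, duration = 4, seed = 13)
  ky <- extract_kymograph(ph$movie, ph$trace)
  fr <- flow_trace(ky)
  expect_equal(length(fr$block_speeds), nrow(ky$data) %/% 50)
  expect_equal(fr$median_speed, 2, tolerance = 0.2)
  expect_false(fr$rejected)
  # zero-speed shadows -> static streaks: detected as ~0 or flat
  ph0 <- ph_flow_inplane(0, duration = 2, seed = 14)
  ky0 <- extract_kymograph(ph0$movie, ph0$trace)
  fr0 <- flow_trace(ky0)
  ok0 <- fr0$block_speeds[is.finite(fr0$block_speeds)]
  expect_true(all(abs(ok0) < 0.05))
  # rejection arithmetic, including the exact boundary
  expect_false(reject_segment(rep(1, 9))$rejected)
  expect_true(reject_segment(c(rep(6, 4), rep(1, 6)))$rejected)   # 40% high
  expect_false(reject_segment(c(rep(6, 3), rep(1, 6)))$rejected)  # exactly 1/3
  expect_true(reject_segment(c(rep(-0.5, 4), rep(1, 6)))$rejected)  # reversed
  expect_true(reject_segment(c(rep(NA, 7), 1, 1, 1))$rejected)    # > 2/3 flat
  expect_equal(reject_segment(c(rep(NA, 7), 1, 1, 1))$reason, "no_rbc_streaks")
  expect_false(reject_segment(c(rep(NA, 6), rep(1, 3)))$rejected) # exactly 2/3
})

test_that("skeletonization reduces a clean tube to its centerline", {
  ph <- ph_cylinder(5, y0 = 20, z0 = 30, length_x = 80, pixel_size = 2,
                    z_render_step = 1, vol_y = 40, vol_z = 60)
  stk <- render_gaussian_stack(ph$net$network, ph$net$truth, ph$cfg,
                               z_step = 2)
  sk <- skeletonize_stack(stk, 0.25 * max(stk$data))
  expect_s3_class(sk, "skeleton3d")
  # one path, two endpoints, length within a few % of the 80-um axis
  main <- sk$paths[[which.max(vapply(sk$paths, `[[`, numeric(1),
                                     "length_3d"))]]
  expect_equal(length(sk$paths), 1)
  expect_equal(main$length_3d, 80, tolerance = 0.05 * 80)
  # interior centerline voxels lie within ~1 voxel of the axis (y=20, z=30)
  nvx <- nrow(main$voxels)
  interior <- main$voxels[4:(nvx - 3), , drop = FALSE]
  expect_true(all(abs(interior[, 1] * 2 - 1 - 20) <= 3))
  expect_true(all(abs(interior[, 3] * 2 - 1 - 30) <= 3))
  # skeleton is a subset of the thresholded foreground
  fg <- stk$data > 0.25 * max(stk$data)
  expect_true(all(fg[sk$voxels]))
  expect_error(skeletonize_stack(stk, max(stk$data) + 1), "empty foreground")
})

test_that("trace-to-3D matching: identity in plane, sqrt(2) at 45 degrees", {
  # in-plane tube -> u(s) = s
  ph <- ph_cylinder(5, y0 = 20, z0 = 30, length_x = 80, pixel_size = 2,
                    z_render_step = 1, vol_y = 40, vol_z = 60)
  stk <- render_gaussian_stack(ph$net$network, ph$net$truth, ph$cfg,
                               z_step = 2)
  sk <- skeletonize_stack(stk, 0.25 * max(stk$data))
  tr <- cbind(x = seq(5, 35, 1), y = rep(10.5, 31))
  map <- match_trace_to_3d(tr, sk)
  # identity over the interior (the smoothing window blunts the last ~4 um
  # at each end): unit local stretch, constant offset
  ii <- 5:(length(map$s) - 5)
  expect_equal(diff(map$u[range(ii)]) / diff(map$s[range(ii)]), 1,
               tolerance = 0.03)
  expect_lt(diff(range((map$u - map$s)[ii])), 1)
  # 45-degree descent -> u(s) = s * sqrt(2) over the interior
  cfg <- scene_config(volume_size = c(100, 40, 80), pixel_size = 2,
                      frame_rate = 15, duration = 1 / 15,
                      vasomotion_amp = 0, arousal_coupling = 0,
                      noise_photons = 0, z_render_step = 1, seed = 2)
  net <- manual_network(list(rbind(c(18, 20, 8), c(82, 20, 72))),
                        radii = 2.4, speeds = 0, signs = 1, config = cfg)
  stk45 <- render_gaussian_stack(net$network, net$truth, cfg, z_step = 2)
  sk45 <- skeletonize_stack(stk45, 0.25 * max(stk45$data))
  tr45 <- cbind(x = seq(12, 38, 1), y = rep(10.5, 27))
  m45 <- match_trace_to_3d(tr45, sk45)
  mid <- 5:(length(m45$s) - 5)
  stretch <- diff(m45$u[range(mid)]) / diff(m45$s[range(mid)])
  expect_equal(stretch, sqrt(2), tolerance = 0.02 * sqrt(2))
  # remapping never shortens: total 3D >= traced 2D span
  expect_gte(m45$total_3d_length, 0.98 * max(m45$s))
  expect_error(match_trace_to_3d(cbind(x = c(5, 30), y = c(35, 35)), sk45),
               "skeleton")
})

test_that("a helical capillary's 3D length is recovered within 3%", {
  # gentle half-turn helix so the 2D projection does not self-intersect
  t <- seq(0, pi, length.out = 41)
  R <- 18; pitch_total <- 40
  cl <- cbind(50 + R * cos(t), 20 + 0.35 * R * sin(t), 15 + pitch_total * t / pi)
  cfg <- scene_config(volume_size = c(100, 44, 70), pixel_size = 2,
                      frame_rate = 15, duration = 1 / 15,
                      vasomotion_amp = 0, arousal_coupling = 0,
                      noise_photons = 0, z_render_step = 1, seed = 3)
  net <- manual_network(list(cl), radii = 2.2, speeds = 0, signs = 1,
                        config = cfg)
  true_len <- sum(sqrt(rowSums(diff(cl)^2)))
  stk <- render_gaussian_stack(net$network, net$truth, cfg, z_step = 2)
  sk <- skeletonize_stack(stk, 0.25 * max(stk$data))
  # trace the projected centerline, trimmed away from the end caps
  proj <- cl[3:39, 1:2] / 2 + 0.5  # um -> px centres
  map <- match_trace_to_3d(cbind(x = proj[, 1], y = proj[, 2]), sk)
  true_trim <- sum(sqrt(rowSums(diff(cl[3:39, ])^2)))
  expect_equal(map$total_3d_length, true_trim, tolerance = 0.03 * true_trim)
})

test_that("remapping corrects projected speeds and conserves row mass", {
  ph <- ph_flow_45deg(2, duration = 4)
  ky <- extract_kymograph(ph$movie, ph$trace)
  # identity map leaves the kymograph unchanged
  ident <- arc_length_map(s = (seq_len(ncol(ky$data)) - 1) * ky$dx,
                          u = (seq_len(ncol(ky$data)) - 1) * ky$dx)
  ky_id <- remap_kymograph_3d(ky, ident)
  expect_equal(ky_id$data, ky$data, tolerance = 1e-6)
  # the 45-degree vessel under-reads by ~1/sqrt(2) before correction
  v2d <- flow_trace(ky)$median_speed
  expect_equal(v2d, 2 / sqrt(2), tolerance = 0.1 * 2 / sqrt(2))
  stk <- render_gaussian_stack(ph$net$network, ph$net$truth, ph$cfg,
                               z_step = 2)
  thr <- common_threshold(stk$data[, , 1], c(1, 15, 20, 20))
  map <- match_trace_to_3d(ph$trace, skeletonize_stack(stk, thr))
  ky3 <- remap_kymograph_3d(ky, map)
  v3d <- flow_trace(ky3)$median_speed
  expect_equal(v3d, 2, tolerance = 0.1 * 2)
  # per-row intensity mass is conserved up to interpolation (2%) under a
  # uniform analytic stretch
  s <- (seq_len(ncol(ky$data)) - 1) * ky$dx
  uni <- arc_length_map(s, s * sqrt(2))
  kyu <- remap_kymograph_3d(ky, uni)
  mass2 <- rowSums(ky$data) / ncol(ky$data)
  massu <- rowSums(kyu$data) / ncol(kyu$data)
  expect_lt(max(abs(massu - mass2) / mass2), 0.02)
  expect_error(remap_kymograph_3d(ky, arc_length_map(c(0, 10), c(0, 14))),
               "cover")
})

test_that("segment diameter from a cross-section line profile", {
  ph <- ph_cylinder(8, pixel_size = 1)
  img <- render_bessel_projection(ph$net$network, ph$net$truth,
                                  ph$cfg)$data[, , 1]
  d <- segment_diameter(img, c(30, 8), c(30, 33), pixel_size = 1)
  expect_equal(d, 8, tolerance = 1)
  # invariant to intensity gain
  expect_equal(segment_diameter(img * 4, c(30, 8), c(30, 33), 1), d)
  expect_error(segment_diameter(matrix(2, 40, 40), c(5, 5), c(5, 30), 1),
               "peak")
  # larger vessels measure larger: diameter ordering is preserved
  ph2 <- ph_cylinder(14, pixel_size = 1)
  img2 <- render_bessel_projection(ph2$net$network, ph2$net$truth,
                                   ph2$cfg)$data[, , 1]
  expect_gt(segment_diameter(img2, c(30, 8), c(30, 33), 1), d)
})
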