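# Shared phantom builders and independent oracles.

# single straight horizontal cylinder along x at (y0, z0), no dynamics
ph_cylinder <- function(diameter, y0 = 20, z0 = 40, length_x = 60,
                        pixel_size = 1, z_render_step = 0.25,
                        noise_photons = 0, frames = 1, frame_rate = 15,
                        speed = 0, rbc = FALSE, seed = 2,
                        vol_y = 40, vol_z = 80) {
  cfg <- scene_config(volume_size = c(length_x, vol_y, vol_z),
                      pixel_size = pixel_size, frame_rate = frame_rate,
                      duration = frames / frame_rate,
                      vasomotion_amp = 0, arousal_coupling = 0,
                      noise_photons = noise_photons,
                      z_render_step = z_render_step, seed = seed)
  net <- manual_network(list(rbind(c(0, y0, z0), c(length_x, y0, z0))),
                        radii = diameter / 2, speeds = speed, signs = 1,
                        config = cfg)
  if (!rbc) net$network$segments[[1]]$rbc_s0 <- numeric(0)
  list(cfg = cfg, net = net)
}

# in-plane flow phantom at the fast-acquisition scale (3.25 um px, 99 Hz)
ph_flow_inplane <- function(speed, duration = 10, seed = 3,
                            radius = 2.4, pixel_size = 3.25) {
  cfg <- scene_config(volume_size = c(320, 40, 60), pixel_size = pixel_size,
                      frame_rate = 99, duration = duration,
                      vasomotion_amp = 0, arousal_coupling = 0,
                      noise_photons = 50, rbc_spacing = 20, seed = seed)
  net <- manual_network(list(rbind(c(0, 20, 30), c(320, 20, 30))),
                        radii = radius, speeds = speed, signs = 1,
                        config = cfg)
  mov <- render_bessel_projection(net$network, net$truth, cfg)
  nx <- dim(mov$data)[2]
  trace <- cbind(x = seq(2, nx - 1, 1),
                 y = rep(20 / pixel_size + 0.5, nx - 2))
  list(cfg = cfg, net = net, movie = mov, trace = trace)
}

# 45-degree descending flow phantom (needs the 2D->3D correction)
ph_flow_45deg <- function(speed, duration = 10, seed = 5) {
  cfg <- scene_config(volume_size = c(100, 40, 80), pixel_size = 2,
                      frame_rate = 99, duration = duration,
                      vasomotion_amp = 0, arousal_coupling = 0,
                      noise_photons = 50, rbc_spacing = 20,
                      z_render_step = 1, seed = seed)
  net <- manual_network(list(rbind(c(18, 20, 8), c(82, 20, 72))),
                        radii = 2.4, speeds = speed, signs = 1, config = cfg)
  mov <- render_bessel_projection(net$network, net$truth, cfg)
  trace <- cbind(x = seq(10, 40, 1), y = rep(10.5, 31))
  list(cfg = cfg, net = net, movie = mov, trace = trace)
}

# independent optics oracle: on-axis intensity FWHM by numerical
# integration of the scalar Debye annular-pupil integral
debye_axial_fwhm <- function(spec) {
  th_out <- asin(spec$na_outer / spec$refractive_index)
  th_in <- asin(spec$ratio * spec$na_outer / spec$refractive_index)
  k <- 2 * pi * spec$refractive_index / spec$wavelength
  intensity <- function(z) vapply(z, function(zz) {
    re <- stats::integrate(function(th) cos(k * zz * cos(th)) * sin(th),
                           th_in, th_out, rel.tol = 1e-10)$value
    im <- stats::integrate(function(th) sin(k * zz * cos(th)) * sin(th),
                           th_in, th_out, rel.tol = 1e-10)$value
    re^2 + im^2
  }, numeric(1))
  guess <- 4 * 1.391557 / (k * (cos(th_in) - cos(th_out)))
  z <- seq(-1.5 * guess, 1.5 * guess, length.out = 4001)
  y <- intensity(z)
  besselflow:::profile_fwhm(z, y / max(y))
}

# brute-force streak-slope oracle: least-squares fit to per-row darkness
# centroids of a clean streak block
centroid_slope_speed <- function(block, dx, dt) {
  dark <- sweep(block, 2, colMeans(block))
  dark <- pmax(-dark, 0)  # darkness relative to the static profile
  rows <- seq_len(nrow(block))
  cent <- vapply(rows, function(r) {
    w <- dark[r, ]
    if (sum(w) == 0) return(NA_real_)
    sum(w * seq_along(w)) / sum(w)
  }, numeric(1))
  ok <- is.finite(cent)
  fit <- stats::lm(cent[ok] ~ rows[ok])
  unname(stats::coef(fit)[2]) * dx / dt / 1000  # px/row -> mm/s
}
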