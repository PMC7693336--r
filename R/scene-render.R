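# Rendering of the synthetic scene: axial-weight projections with RBC
# shadows, Poisson shot noise and optional rigid drift.
#
# A frame is the axial line integral of the dye concentration weighted by
# the (two-photon) axial excitation profile:
#   signal(x, y) = integral dye(x, y, z) * W(z) dz,
# evaluated on a voxel grid with lateral spacing = pixel_size and axial
# spacing = z_render_step. Voxels at the lumen edge are weighted by a
# linear partial-volume factor so that chord integrals converge with the
# step size. RBC plugs (length `rbc_length`, filling the lumen) carry zero
# dye and advect along each centerline at the segment speed, wrapping
# around to keep flux stationary.

# Per-segment candidate voxel table: every voxel whose distance to the
# centerline is below the largest radius the segment ever reaches (plus a
# partial-volume margin). Returns pix (linear pixel index), z, dist and
# arc-length s, sorted by s.
segment_voxels <- function(seg, config) {
  vol <- config$volume_size
  px <- config$pixel_size; dz <- config$z_render_step
  nx <- max(1L, round(vol[1] / px)); ny <- max(1L, round(vol[2] / px))
  nz <- max(1L, round(vol[3] / dz))
  r_cap <- max(seg$radius_t) + max(px, dz)
  pts <- seg$centerline
  acc <- vector("list", nrow(pts) - 1L)
  s_edge <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  for (e in seq_len(nrow(pts) - 1L)) {
    a <- pts[e, ]; b <- pts[e + 1L, ]
    lo <- pmin(a, b) - r_cap; hi <- pmax(a, b) + r_cap
    ix <- seq(max(1L, floor(lo[1] / px) + 1L), min(nx, ceiling(hi[1] / px)))
    iy <- seq(max(1L, floor(lo[2] / px) + 1L), min(ny, ceiling(hi[2] / px)))
    iz <- seq(max(1L, floor(lo[3] / dz) + 1L), min(nz, ceiling(hi[3] / dz)))
    if (!length(ix) || !length(iy) || !length(iz)) next
    g <- expand.grid(x = (ix - 0.5) * px, y = (iy - 0.5) * px,
                     z = (iz - 0.5) * dz, KEEP.OUT.ATTRS = FALSE)
    u <- b - a; L <- sqrt(sum(u^2)); u <- u / L
    wx <- g$x - a[1]; wy <- g$y - a[2]; wz <- g$z - a[3]
    tt <- pmin(pmax((wx * u[1] + wy * u[2] + wz * u[3]) / L, 0), 1)
    d2 <- (wx - tt * L * u[1])^2 + (wy - tt * L * u[2])^2 +
      (wz - tt * L * u[3])^2
    keep <- d2 < r_cap^2
    if (!any(keep)) next
    gi <- expand.grid(ix = ix, iy = iy, iz = iz, KEEP.OUT.ATTRS = FALSE)
    acc[[e]] <- data.frame(
      vox = (gi$iz[keep] - 1) * (as.double(nx) * ny) +
        (gi$ix[keep] - 1) * ny + gi$iy[keep],
      pix = (gi$ix[keep] - 1L) * ny + gi$iy[keep],
      z = g$z[keep], dist = sqrt(d2[keep]), s = s_edge[e] + tt[keep] * L)
  }
  tab <- do.call(rbind, acc)
  if (is.null(tab) || !nrow(tab))
    return(list(pix = integer(0), z = numeric(0), dist = numeric(0),
                s = numeric(0), ny = ny, nx = nx))
  # voxels can be claimed by several edges; keep the closest assignment
  tab <- tab[order(tab$vox, tab$dist), ]
  tab <- tab[!duplicated(tab$vox), ]
  tab <- tab[order(tab$s), ]
  list(pix = tab$pix, z = tab$z, dist = tab$dist, s = tab$s, ny = ny, nx = nx)
}

# linear partial-volume coverage of a voxel at distance `dist` from the
# axis, for radius r, with transition width h
pv_coverage <- function(dist, r, h) pmin(pmax((r - dist) / h + 0.5, 0), 1)

# Shared renderer. weight: function(z um) -> two-photon axial weight.
render_scene <- function(network, truth, config, weight,
                         time_idx = NULL, include_rbc = TRUE,
                         rng_offset = 77L) {
  stopifnot(inherits(network, "vessel_network"))
  px <- config$pixel_size; dz <- config$z_render_step
  h <- max(px, dz)
  if (is.null(time_idx)) time_idx <- seq_along(truth$t)
  nt <- length(time_idx)
  segs <- network$segments
  pre <- lapply(segs, segment_voxels, config = config)
  ny <- if (length(pre)) pre[[1]]$ny else round(config$volume_size[2] / px)
  nx <- if (length(pre)) pre[[1]]$nx else round(config$volume_size[1] / px)
  out <- array(0, c(ny, nx, nt))
  half_rbc <- config$rbc_length / 2
  for (k in seq_along(segs)) {
    v <- pre[[k]]
    if (!length(v$pix)) next
    seg <- segs[[k]]
    w_ax <- weight(v$z) * dz
    r_series <- seg$radius_t[time_idx]
    static_r <- length(unique(signif(r_series, 12))) == 1L
    base <- NULL
    if (static_r) {
      cov <- pv_coverage(v$dist, r_series[1], h)
      sel <- cov > 0
      lum <- rowsum((cov * w_ax)[sel], v$pix[sel])
      base_pix <- as.integer(rownames(lum))
      base <- list(pix = base_pix, val = lum[, 1])
    }
    L <- seg$length_3d
    v_um_s <- seg$speed * 1000
    for (j in seq_len(nt)) {
      tt <- truth$t[time_idx[j]]
      r_now <- r_series[j]
      frame_add <- matrix(0, ny, nx)
      if (static_r) {
        frame_add[base$pix] <- base$val
      } else {
        cov <- pv_coverage(v$dist, r_now, h)
        sel <- cov > 0
        if (any(sel)) {
          lum <- rowsum((cov * w_ax)[sel], v$pix[sel])
          frame_add[as.integer(rownames(lum))] <- lum[, 1]
        }
      }
      if (include_rbc && v_um_s >= 0 && length(seg$rbc_s0)) {
        track <- seg$rbc_track %||% L
        sr <- (seg$rbc_s0 + v_um_s * tt) %% track
        # wrap copies for RBCs straddling either end of the circular track
        sr <- c(sr, sr[sr > track - (half_rbc + h)] - track,
                sr[sr < half_rbc + h] + track)
        sr <- sr[sr > -(half_rbc + h) & sr < L + half_rbc + h]
        idx <- rbc_window_indices(v$s, sr, half_rbc + h, L)
        if (length(idx)) {
          ds <- abs(outer_min_plain(v$s[idx], sr))
          # dye-excluding ellipsoid: semi-axes half_rbc along the vessel
          # and min(rbc_radius, lumen radius) radially
          b <- min(config$rbc_radius, r_now)
          q <- sqrt((ds / half_rbc)^2 + (v$dist[idx] / b)^2)
          cov_s <- pmin(pmax((1 - q) * half_rbc / h + 0.5, 0), 1)
          cov_r <- pv_coverage(v$dist[idx], r_now, h)
          w_sh <- cov_s * cov_r * w_ax[idx]
          nz <- w_sh > 0
          if (any(nz)) {
            sh <- rowsum(w_sh[nz], v$pix[idx][nz])
            spix <- as.integer(rownames(sh))
            frame_add[spix] <- pmax(frame_add[spix] - sh[, 1], 0)
          }
        }
      }
      out[, , j] <- out[, , j] + frame_add
    }
  }
  # lateral blur: measured lateral two-photon PSF FWHM ~0.65 um
  sigma_px <- 0.65 / 2.3548 / px
  if (sigma_px > 0.05)
    for (j in seq_len(nt)) out[, , j] <- gaussian_blur2d(out[, , j], sigma_px)
  if (config$noise_photons > 0) {
    scale <- config$noise_photons / 10  # photons per um of weighted dye column
    out <- out * scale + config$background_photons
    out <- with_seed(config$seed + rng_offset, {
      array(stats::rpois(length(out), lambda = out), dim(out))
    })
  }
  out
}

# indices of voxels (sorted s) within +-half of any RBC position
rbc_window_indices <- function(s_sorted, sr, half, L) {
  n <- length(s_sorted)
  take <- logical(n)
  for (p in sr) {
    lo <- max(p - half, 0); hi <- min(p + half, L)
    if (hi < lo) next
    i0 <- findInterval(lo, s_sorted) + 1L
    i1 <- findInterval(hi, s_sorted)
    if (i1 >= i0) take[i0:i1] <- TRUE
  }
  which(take)
}

# arc distance of each voxel s to its nearest RBC centre
outer_min_plain <- function(s, sr) {
  d <- outer(s, sr, `-`)
  d[cbind(seq_along(s), max.col(-abs(d)))]
}

#' Render the Bessel-projection movie of a scene
#'
#' Projects the volume through the two-photon axial weight of a Bessel
#' focus (the square of the one-photon annulus profile, centred at
#' mid-depth), adds RBC shadows, a small lateral blur, and Poisson noise.
#'
#' @param network,truth output of [build_network()].
#' @param config the [scene_config].
#' @param axial_profile optional one-photon `axial_profile`; defaults to
#'   the annulus used throughout (NA 0.4, ratio 0.92, 920 nm, n 1.33).
#' @param time_idx optional subset of frame indices to render.
#' @return a [bf_movie] of photon counts (or dye-column micrometres when
#'   `noise_photons = 0`).
#' @export
render_bessel_projection <- function(network, truth, config,
                                     axial_profile = NULL, time_idx = NULL) {
  if (is.null(axial_profile))
    axial_profile <- annulus_axial_profile(annulus_spec(0.4, 0.92, 0.92, 1.33))
  zc <- config$volume_size[3] / 2
  wfun <- function(z) {
    w <- stats::approx(axial_profile$z + zc, axial_profile$intensity, xout = z,
                       rule = 2)$y
    if (identical(axial_profile$kind, "one_photon")) w^2 else w
  }
  dat <- render_scene(network, truth, config, wfun, time_idx = time_idx,
                      rng_offset = 77L)
  bf_movie(dat, config$pixel_size, 1 / config$frame_rate)
}

#' Render a single-plane Gaussian-focus movie
#'
#' Same scene rendered through a narrow Gaussian axial weight centred at
#' `z_plane`, emulating conventional single-plane two-photon imaging.
#'
#' @inheritParams render_bessel_projection
#' @param z_plane focal depth, micrometres from the top surface.
#' @param axial_fwhm axial FWHM of the Gaussian two-photon weight, um.
#' @return a [bf_movie].
#' @export
render_gaussian_plane <- function(network, truth, config, z_plane,
                                  axial_fwhm = 3.1, time_idx = NULL) {
  if (z_plane < 0 || z_plane > config$volume_size[3])
    stopf("z_plane %.1f um is outside the volume", z_plane)
  sig <- axial_fwhm / 2.3548
  wfun <- function(z) exp(-(z - z_plane)^2 / (2 * sig^2))
  dat <- render_scene(network, truth, config, wfun, time_idx = time_idx,
                      rng_offset = 78L)
  bf_movie(dat, config$pixel_size, 1 / config$frame_rate)
}

#' Render a Gaussian structural z-stack of the scene
#'
#' One plane per `z_step`, using the scene state at a single time point and
#' (by default) omitting RBC shadows, like a slow structural acquisition
#' averaged over flow.
#'
#' @inheritParams render_gaussian_plane
#' @param z_step slice spacing, micrometres.
#' @param time_index scene frame whose radii are used.
#' @param include_rbc render RBC shadows in each plane.
#' @return a [bf_stack].
#' @export
render_gaussian_stack <- function(network, truth, config, z_step = 1,
                                  axial_fwhm = 3.1, time_index = 1L,
                                  include_rbc = FALSE) {
  zs <- seq(z_step / 2, config$volume_size[3] - z_step / 2 + 1e-9, by = z_step)
  sig <- axial_fwhm / 2.3548
  planes <- lapply(zs, function(zp) {
    wfun <- function(z) exp(-(z - zp)^2 / (2 * sig^2))
    render_scene(network, truth, config, wfun, time_idx = time_index,
                 include_rbc = include_rbc, rng_offset = 79L + round(zp * 10))
  })
  d <- dim(planes[[1]])
  bf_stack(array(unlist(planes), c(d[1], d[2], length(zs))),
           config$pixel_size, z_step)
}

#' Apply a rigid lateral random-walk drift to a movie
#'
#' Integer-pixel per-frame translations following a reflected random walk
#' bounded by `amplitude`; exposed pixels are filled with the frame median.
#'
#' @param movie a [bf_movie].
#' @param amplitude drift bound in micrometres (< 10% of the field).
#' @param seed RNG seed for the walk.
#' @return list with `movie` (shifted) and `shifts` (T x 2 matrix of
#'   `(dy, dx)` pixel shifts actually applied).
#' @export
apply_motion <- function(movie, amplitude, seed = 1L) {
  stopifnot(inherits(movie, "bf_movie"))
  d <- dim(movie$data)
  amp_px <- floor(amplitude / movie$pixel_size)
  if (amp_px > 0.1 * min(d[1], d[2]))
    stopf("motion amplitude exceeds 10%% of the field")
  nt <- d[3]
  shifts <- matrix(0L, nt, 2, dimnames = list(NULL, c("dy", "dx")))
  if (amp_px >= 1) {
    shifts <- with_seed(seed, {
      step <- matrix(sample(c(-1L, 0L, 1L), 2L * nt, replace = TRUE), nt, 2)
      step[1, ] <- 0L
      w <- apply(step, 2, cumsum)
      # reflect at the amplitude bound
      w <- apply(w, 2, function(col) {
        p <- 2L * amp_px
        m <- ((col + amp_px) %% (2L * p))
        m <- ifelse(m > p, 2L * p - m, m)
        as.integer(m - amp_px)
      })
      colnames(w) <- c("dy", "dx")
      w
    })
  }
  out <- movie$data
  for (t in seq_len(nt)) {
    if (shifts[t, 1] != 0 || shifts[t, 2] != 0)
      out[, , t] <- shift_image(movie$data[, , t], shifts[t, 1], shifts[t, 2])
  }
  list(movie = bf_movie(out, movie$pixel_size, movie$frame_interval),
       shifts = shifts)
}
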