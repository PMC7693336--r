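# 3D skeletonization of the Gaussian structural stack and matching of
# hand-drawn 2D traces to skeleton paths for 3D arc-length measurement.
#
# Thinning removes "simple" border voxels — voxels whose deletion keeps
# both the foreground 26-connectivity and the background 6-connectivity of
# their 3x3x3 neighbourhood unchanged (Bertrand's characterisation) —
# while preserving curve endpoints, leaving 1-voxel-wide centerlines.

# 3x3x3 neighbourhood geometry, built once at load time
skel_env <- new.env(parent = emptyenv())

skel_tables <- function() {
  if (!is.null(skel_env$tab)) return(skel_env$tab)
  off <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dz = -1:1))
  center <- which(rowSums(abs(off)) == 0)
  cheb <- as.matrix(stats::dist(off, method = "maximum"))
  city <- as.matrix(stats::dist(off, method = "manhattan"))
  n26 <- setdiff(seq_len(27), center)
  n18 <- which(rowSums(abs(off)) <= 2 & rowSums(abs(off)) > 0)
  n6 <- which(rowSums(abs(off)) == 1)
  adj26 <- lapply(seq_len(27), function(i)
    setdiff(which(cheb[i, ] == 1), center))
  adj6 <- lapply(seq_len(27), function(i) which(city[i, ] == 1))
  skel_env$tab <- list(off = off, center = center, n26 = n26, n18 = n18,
                       n6 = n6, adj26 = adj26, adj6 = adj6)
  skel_env$tab
}

# number of connected components of `members` (indices into the 27-cell
# neighbourhood) under the given adjacency lists, optionally counting only
# components containing a seed cell
n_components <- function(members, adj, seeds = NULL) {
  if (!length(members)) return(0L)
  seen <- logical(27)
  ncomp <- 0L
  in_set <- logical(27); in_set[members] <- TRUE
  for (m in members) {
    if (seen[m]) next
    queue <- m; seen[m] <- TRUE
    comp <- m
    while (length(queue)) {
      q <- queue[length(queue)]; queue <- queue[-length(queue)]
      nb <- adj[[q]]
      nb <- nb[in_set[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
      comp <- c(comp, nb)
    }
    if (is.null(seeds) || any(comp %in% seeds)) ncomp <- ncomp + 1L
  }
  ncomp
}

# is the center voxel of a 27-cell logical neighbourhood simple?
is_simple_point <- function(nbhd) {
  tab <- skel_tables()
  fg <- which(nbhd & seq_len(27) != tab$center)
  if (!length(fg)) return(FALSE)
  if (n_components(fg, tab$adj26) != 1L) return(FALSE)
  bg18 <- intersect(tab$n18, which(!nbhd))
  if (!any(tab$n6 %in% bg18)) return(FALSE)
  n_components(bg18, tab$adj6, seeds = tab$n6) == 1L
}

#' Skeletonize a binarized structural stack to 1-voxel centerlines
#'
#' Thresholds the stack, then iteratively deletes simple border voxels
#' (sequentially, in six directional subpasses) while preserving curve
#' endpoints, and finally organises the skeleton into paths between
#' branch/end points.
#'
#' @param stack a [bf_stack].
#' @param threshold binarization intensity (e.g. from [common_threshold()]
#'   on a slice with a vessel-free region).
#' @param min_component discard foreground components smaller than this
#'   many voxels (noise specks).
#' @param prune_um remove terminal skeleton spurs shorter than this length
#'   (micrometres) after thinning.
#' @return a `skeleton3d`: list with `voxels` (n x 3 index matrix: row,
#'   col, slice), `paths` (list; each with `voxels`, projected `xy` pixel
#'   coordinates, `cum3d` cumulative micrometre length, `length_3d`),
#'   `pixel_size`, `z_step`.
#' @export
skeletonize_stack <- function(stack, threshold, min_component = 10L,
                              prune_um = 8) {
  stopifnot(inherits(stack, "bf_stack"))
  fg <- stack$data > threshold
  if (!any(fg)) stopf("empty foreground after thresholding")
  fg <- binary_majority3d(fg)   # smooth speckle and surface bumps
  fg <- drop_small_components(fg, min_component)
  if (!any(fg)) stopf("empty foreground after cleaning")
  d <- dim(fg)
  # pad with background so every voxel has a full neighbourhood
  P <- array(FALSE, d + 2L)
  P[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- fg
  tab <- skel_tables()
  dirs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                c(0, 0, -1), c(0, 0, 1))
  dp <- dim(P)
  stride <- c(1L, dp[1], dp[1] * dp[2])
  nb_off <- tab$off %*% stride  # linear offsets of the 27 neighbourhood
  repeat {
    deleted <- 0L
    for (k in seq_len(nrow(dirs))) {
      doff <- sum(dirs[k, ] * stride)
      idx <- which(P)
      if (!length(idx)) break
      border <- idx[!P[idx + doff]]
      for (v in border) {
        if (!P[v]) next
        nbhd <- P[v + nb_off]
        # curve preservation: voxels with <= 2 remaining neighbours are
        # part of a 1-voxel chain (or its tip) and are never deleted —
        # deleting 2-neighbour voxels lets diagonal chains collapse
        if (sum(nbhd) - 1L <= 2L) next
        if (is_simple_point(nbhd)) {
          P[v] <- FALSE
          deleted <- deleted + 1L
        }
      }
    }
    if (deleted == 0L) break
  }
  vox_pad <- which(P, arr.ind = TRUE)
  vox <- vox_pad - 1L
  colnames(vox) <- c("row", "col", "slice")
  sk <- skeleton_graph(vox, stack$pixel_size, stack$z_step)
  # prune short terminal spurs left by surface bumps, then rebuild
  for (round in 1:3) {
    pruned <- prune_spurs(sk, prune_um)
    if (is.null(pruned)) break
    sk <- skeleton_graph(pruned, stack$pixel_size, stack$z_step)
  }
  sk
}

# speckle clean on the binary volume: drop near-isolated foreground
# voxels, fill well-surrounded holes; thresholds chosen to preserve
# capillary-thin (1-2 voxel wide) tubes
binary_majority3d <- function(fg) {
  d <- dim(fg)
  P <- array(0L, d + 2L)
  P[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- fg
  cnt <- array(0L, d)
  for (a in 0:2) for (b in 0:2) for (k in 0:2)
    cnt <- cnt + P[a + seq_len(d[1]), b + seq_len(d[2]), k + seq_len(d[3])]
  (fg & cnt >= 5L) | cnt >= 18L
}

# keep only 26-connected foreground components of at least min_size voxels
drop_small_components <- function(fg, min_size) {
  d <- dim(fg)
  lab <- array(0L, d)
  idx_all <- which(fg)
  if (!length(idx_all)) return(fg)
  stride <- c(1L, d[1], d[1] * d[2])
  tab <- skel_tables()
  offs <- tab$off[tab$n26, , drop = FALSE] %*% stride
  cur <- 0L
  for (s0 in idx_all) {
    if (lab[s0] != 0L) next
    cur <- cur + 1L
    queue <- s0; lab[s0] <- cur
    while (length(queue)) {
      q <- queue[length(queue)]; queue <- queue[-length(queue)]
      # guard against crossing array edges via arithmetic wraparound
      ai <- arrayInd(q, d)
      nb <- q + offs
      ok <- ai[1] + tab$off[tab$n26, 1] >= 1 & ai[1] + tab$off[tab$n26, 1] <= d[1] &
        ai[2] + tab$off[tab$n26, 2] >= 1 & ai[2] + tab$off[tab$n26, 2] <= d[2] &
        ai[3] + tab$off[tab$n26, 3] >= 1 & ai[3] + tab$off[tab$n26, 3] <= d[3]
      nb <- nb[ok]
      nb <- nb[fg[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size)
  array(lab %in% keep, d)
}

# voxels remaining after removing short terminal spurs and short cycles;
# NULL when nothing needs pruning. Voxels shared with a longer path (or
# with any other path) are always kept so the main line stays connected.
prune_spurs <- function(sk, prune_um) {
  if (length(sk$paths) <= 1) return(NULL)
  vox_lin <- function(v) (v[, 3] - 1) * 1e10 + (v[, 2] - 1) * 1e5 + v[, 1]
  lin <- vox_lin(sk$voxels)
  path_lins <- lapply(sk$paths, function(p) vox_lin(p$voxels))
  lens <- vapply(sk$paths, `[[`, numeric(1), "length_3d")
  drop_lin <- numeric(0)
  for (i in seq_along(sk$paths)) {
    p <- sk$paths[[i]]
    if (lens[i] >= prune_um || nrow(p$voxels) < 2) next
    pl <- path_lins[[i]]
    is_cycle <- all(p$voxels[1, ] == p$voxels[nrow(p$voxels), ])
    ends <- pl[c(1, length(pl))]
    in_other <- unique(unlist(path_lins[-i]))
    # spur: a free endpoint not shared with any other path; cycle: closed
    if (!is_cycle && all(ends %in% in_other)) next
    drop_lin <- c(drop_lin, setdiff(pl, in_other))
  }
  drop_lin <- unique(drop_lin)
  if (!length(drop_lin) || length(drop_lin) >= nrow(sk$voxels)) return(NULL)
  sk$voxels[!(lin %in% drop_lin), , drop = FALSE]
}

# organise skeleton voxels into paths between endpoints/branch points
skeleton_graph <- function(vox, pixel_size, z_step) {
  n <- nrow(vox)
  lin <- (vox[, 3] - 1) * 1e10 + (vox[, 2] - 1) * 1e5 + vox[, 1]
  ord <- order(lin)
  lin_s <- lin[ord]
  tab <- skel_tables()
  offs <- tab$off[tab$n26, , drop = FALSE]
  nb_id <- matrix(NA_integer_, n, 26)
  for (j in seq_len(26)) {
    nl <- (vox[, 3] - 1 + offs[j, 3]) * 1e10 +
      (vox[, 2] - 1 + offs[j, 2]) * 1e5 + (vox[, 1] + offs[j, 1])
    pos <- findInterval(nl, lin_s)
    hit <- pos > 0 & lin_s[pmax(pos, 1)] == nl
    nb_id[hit, j] <- ord[pos[hit]]
  }
  deg <- rowSums(!is.na(nb_id))
  nodes <- which(deg != 2L)
  visited_edge <- new.env(parent = emptyenv())
  ekey <- function(a, b) paste0(min(a, b), "_", max(a, b))
  paths <- list()
  walk <- function(start, nxt) {
    path <- c(start, nxt)
    prev <- start; cur <- nxt
    while (deg[cur] == 2L) {
      nb <- nb_id[cur, ]; nb <- nb[!is.na(nb)]
      nxt2 <- nb[nb != prev][1]
      if (is.na(nxt2)) break
      path <- c(path, nxt2)
      prev <- cur; cur <- nxt2
      if (cur == start) break  # cycle
    }
    path
  }
  for (s in nodes) {
    nb <- nb_id[s, ]; nb <- nb[!is.na(nb)]
    for (b in nb) {
      k <- ekey(s, b)
      if (!is.null(visited_edge[[k]])) next
      p <- walk(s, b)
      for (i in seq_len(length(p) - 1L))
        visited_edge[[ekey(p[i], p[i + 1L])]] <- TRUE
      paths[[length(paths) + 1L]] <- p
    }
  }
  if (!length(paths) && n > 1) {
    # pure cycle: open it at an arbitrary voxel
    paths[[1]] <- walk(1L, nb_id[1L, which(!is.na(nb_id[1L, ]))[1]])
  }
  mk <- function(p) {
    pv <- vox[p, , drop = FALSE]
    # smooth the voxel chain so staircase jitter does not inflate length
    sm <- pv
    if (nrow(pv) >= 5) sm <- apply(pv, 2, moving_average, window = 5L)
    steps <- if (nrow(sm) > 1)
      sqrt((diff(sm[, 1]) * pixel_size)^2 + (diff(sm[, 2]) * pixel_size)^2 +
             (diff(sm[, 3]) * z_step)^2) else numeric(0)
    cum3d <- c(0, cumsum(steps))
    list(voxels = pv, xy = cbind(x = sm[, 2], y = sm[, 1]),
         cum3d = cum3d, length_3d = cum3d[length(cum3d)])
  }
  structure(list(voxels = vox, paths = lapply(paths, mk), nb = nb_id,
                 pixel_size = pixel_size, z_step = z_step),
            class = "skeleton3d")
}

# shortest route (micrometre edge weights, 26-adjacency) between two
# skeleton voxels; plain Dijkstra, fine for phantom-sized skeletons
skeleton_route <- function(sk, from, to) {
  n <- nrow(sk$voxels)
  px <- sk$pixel_size; dz <- sk$z_step
  dist <- rep(Inf, n); prev <- rep(NA_integer_, n); done <- logical(n)
  dist[from] <- 0
  while (TRUE) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!length(u) || !is.finite(dist[u])) return(NULL)
    if (u == to) break
    done[u] <- TRUE
    nb <- sk$nb[u, ]; nb <- nb[!is.na(nb)]
    nb <- nb[!done[nb]]
    if (length(nb)) {
      w <- sqrt(((sk$voxels[nb, 1] - sk$voxels[u, 1]) * px)^2 +
                  ((sk$voxels[nb, 2] - sk$voxels[u, 2]) * px)^2 +
                  ((sk$voxels[nb, 3] - sk$voxels[u, 3]) * dz)^2)
      upd <- dist[u] + w < dist[nb]
      dist[nb[upd]] <- dist[u] + w[upd]
      prev[nb[upd]] <- u
    }
  }
  route <- to
  while (!is.na(prev[route[1]])) route <- c(prev[route[1]], route)
  route
}

#' Match a 2-D vessel trace to a skeleton path and build its 2D -> 3D map
#'
#' Finds the skeleton path whose 2-D projection lies closest to the trace
#' (minimum mean nearest-point distance), orients it to run with the
#' trace, and builds the arc-length map `u(s)`: for every 1-pixel step of
#' projected arc length `s` along the trace, the cumulative 3-D length of
#' the nearest path voxel.
#'
#' @param trace n x 2 `(x, y)` pixel polyline drawn on the projection.
#' @param skeleton a `skeleton3d` from [skeletonize_stack()].
#' @param tol maximum admissible mean trace-to-path distance in pixels.
#' @return an `arc_length_map` (micrometre units; `s` steps of one pixel).
#' @export
match_trace_to_3d <- function(trace, skeleton, tol = 3) {
  stopifnot(inherits(skeleton, "skeleton3d"), is.matrix(trace))
  rs <- resample_polyline(trace, step = 1)
  tx <- rs$x; ty <- rs$y
  vx <- skeleton$voxels[, 2]; vy <- skeleton$voxels[, 1]
  d_start <- (vx - tx[1])^2 + (vy - ty[1])^2
  d_end <- (vx - tx[length(tx)])^2 + (vy - ty[length(ty)])^2
  # thinning can erode the ends of the centerline, so the endpoint check is
  # generous; the mean trace-to-route distance below enforces `tol`
  if (sqrt(min(d_start)) > 3 * tol || sqrt(min(d_end)) > 3 * tol)
    stopf("trace endpoints are not within %.1f px of the skeleton", 3 * tol)
  route <- skeleton_route(skeleton, which.min(d_start), which.min(d_end))
  if (is.null(route) || length(route) < 2)
    stopf("trace endpoints fall on disconnected skeleton parts")
  rv <- skeleton$voxels[route, , drop = FALSE]
  sm <- rv
  # heavy smoothing: period-2 staircase jitter inflates arc length
  win <- min(9L, nrow(rv) - (1 - nrow(rv) %% 2))
  if (nrow(rv) >= 5) sm <- apply(rv, 2, moving_average, window = win)
  cum3d <- c(0, cumsum(sqrt((diff(sm[, 1]) * skeleton$pixel_size)^2 +
                              (diff(sm[, 2]) * skeleton$pixel_size)^2 +
                              (diff(sm[, 3]) * skeleton$z_step)^2)))
  pr <- project_onto_path(tx, ty, cbind(x = sm[, 2], y = sm[, 1]), cum3d)
  if (mean(pr$dist) > tol)
    stopf("skeleton route lies %.2f px from the trace (tolerance %.1f px)",
          mean(pr$dist), tol)
  u <- pr$u
  if (u[1] > u[length(u)]) u <- max(cum3d) - u  # orient with the trace
  if (length(u) >= 5) u <- moving_average(u, 5L)
  s_um <- rs$s * skeleton$pixel_size
  arc_length_map(s_um, cummax(u - u[1]))
}

# closest point of each (x, y) on the projected path polyline: 2-D
# distance plus interpolated cumulative 3-D arc length
project_onto_path <- function(tx, ty, xy, cum3d) {
  ax <- xy[-nrow(xy), 1]; ay <- xy[-nrow(xy), 2]
  bx <- xy[-1, 1]; by <- xy[-1, 2]
  ex <- bx - ax; ey <- by - ay
  len2 <- ex^2 + ey^2
  len2[len2 == 0] <- 1e-12
  n <- length(tx)
  dist <- numeric(n); u <- numeric(n)
  for (i in seq_len(n)) {
    tt <- pmin(pmax(((tx[i] - ax) * ex + (ty[i] - ay) * ey) / len2, 0), 1)
    dx <- ax + tt * ex - tx[i]; dy <- ay + tt * ey - ty[i]
    d2 <- dx^2 + dy^2
    j <- which.min(d2)
    dist[i] <- sqrt(d2[j])
    u[i] <- cum3d[j] + tt[j] * (cum3d[j + 1L] - cum3d[j])
  }
  list(dist = dist, u = u)
}
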