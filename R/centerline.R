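#' Extract the aortic centerline from a label volume
#'
#' Computes an ordered, smoothed, arc-length-parameterised centerline of the
#' whole-aorta mask (TL + CFL + TH) and its total length, from the aortic
#' root to the aorto-iliac bifurcation (orientation is metadata only: all
#' downstream measures use absolute arc distances).
#'
#' The algorithm is a distance-penalised minimal path with cross-section
#' recentring:
#' \enumerate{
#'   \item a double Dijkstra sweep over the 26-connected foreground voxel
#'     graph finds the two geodesically most distant voxels (the vessel
#'     extremities);
#'   \item the path between them is re-traced with per-voxel weight
#'     `1 / (1 + d)^2`, `d` the Euclidean distance transform (mm), which
#'     biases the path toward the medial axis;
#'   \item path ends are trimmed where the path is closer to the boundary
#'     than 90% of the median interior radius (this removes the oblique
#'     run-in from the boundary extremity toward the axis);
#'   \item each sample is replaced by the centroid of the connected
#'     component containing it in the plane orthogonal to the local
#'     tangent, twice: a minimal path through a wide lumen legitimately
#'     cuts corners, and recentring restores the cross-sectional axis;
#'   \item the curve is smoothed with a moving average, extended straight
#'     along the end tangents until it leaves the mask (so the reported
#'     length spans cap to cap), and resampled at a uniform arc-length
#'     step.
#' }
#'
#' @param vol A [label_volume()] whose union mask is a single connected
#'   component.
#' @param step Resampling interval in mm (default 1).
#' @param smooth_window Moving-average window (samples, odd) applied to the
#'   voxel path before resampling.
#' @param min_component Voxel count under which a disconnected speck is
#'   ignored (with a warning) rather than treated as a second component.
#' @return An object of class `aorta_centerline`: list with `points`
#'   (n x 3 world mm), `arclen` (cumulative mm, `arclen[1] = 0`),
#'   `tangents` (n x 3 unit vectors), `step`, and `ao_length` (mm).
#' @export
extract_centerline <- function(vol, step = 1, smooth_window = 5,
                               min_component = 27) {
  mask <- label_mask(vol)
  dims <- dim(mask)
  mask_i <- as.integer(mask)
  if (sum(mask_i) == 0) abort("union mask TL+CFL+TH is empty")

  comp <- cpp_label_components(mask_i, dims)
  sizes <- comp$sizes
  large <- which(sizes >= min_component)
  if (length(large) > 1) {
    abort(paste0("union mask has ", length(large),
                 " disconnected components (sizes: ",
                 paste(sort(sizes[large], decreasing = TRUE), collapse = ", "),
                 " voxels); measurement needs a single connected aorta"))
  }
  keep <- which.max(sizes)
  if (length(sizes) > 1) {
    warn(paste0("ignoring ", length(sizes) - 1, " small disconnected speck(s) (",
                paste(sizes[-keep], collapse = ", "), " voxels)"))
    mask_i <- as.integer(comp$labels == keep)
  }
  if (sum(mask_i) < 3) abort("mask too thin to trace (fewer than 3 voxels)")

  spacing <- vol$spacing
  edt <- cpp_edt(mask_i, dims, spacing)

  # double sweep: most interior voxel -> farthest A -> farthest B
  seed0 <- which.max(edt) - 1L
  dA <- cpp_grid_dijkstra(mask_i, dims, spacing, seed0, numeric(0))$dist
  a <- farthest_voxel(dA)
  sweep2 <- cpp_grid_dijkstra(mask_i, dims, spacing, a, numeric(0))
  b <- farthest_voxel(sweep2$dist)

  # medial-axis-penalised path from a to b
  wt <- rep(1, length(edt))
  fg <- mask_i != 0L
  wt[fg] <- 1 / (1 + edt[fg])^2
  pen <- cpp_grid_dijkstra(mask_i, dims, spacing, a, wt)
  path_idx <- backtrack_path(pen$parent, b)
  if (length(path_idx) < 3) abort("mask too thin to trace (fewer than 3 path voxels)")

  pts <- voxel_to_world(vol, linear_to_ijk(path_idx, dims))
  path_dt <- edt[path_idx + 1L]

  # trim boundary run-ins at both ends
  r_ref <- stats::median(path_dt)
  thresh <- 0.9 * r_ref
  n <- nrow(pts)
  i0 <- 1L
  while (i0 < n - 1L && path_dt[i0] < thresh) i0 <- i0 + 1L
  i1 <- n
  while (i1 > i0 + 1L && path_dt[i1] < thresh) i1 <- i1 - 1L
  if (i1 - i0 + 1L >= 3L) pts <- pts[i0:i1, , drop = FALSE]

  pts <- smooth_polyline(pts, smooth_window)
  pts <- resample_polyline(pts, step)$points

  # alternate cross-sectional recentring with end extension: recentring
  # restores the axis where the minimal path cut corners, extension pushes
  # the (recentred) ends back out to the caps, and the next recentring pass
  # straightens the newly added end segments
  rmax <- max(edt)
  extent <- 4 * rmax + 8
  fg <- array(as.numeric(mask_i), dims)
  h <- min(spacing)
  max_ext <- 3 * r_ref + 5 * h
  mask_arr <- array(mask_i != 0L, dims)
  guard <- max(0.75 * r_ref, 4)
  pts <- recenter_curve(vol, fg, pts, extent = extent)
  pts <- smooth_polyline(pts, smooth_window)
  pts <- resample_polyline(pts, step)$points
  for (it in 1:2) {
    pts <- add_extensions(pts, vol, mask_arr, h, max_ext)
    pts <- resample_polyline(pts, step)$points
    pts <- recenter_curve(vol, fg, pts, extent = extent)
    pts <- smooth_polyline(pts, smooth_window)
    pts <- resample_polyline(pts, step)$points
    # sections within ~a radius of the caps are clipped by the cap, so their
    # recentred positions are biased: drop them and re-extend from the
    # well-recentred interior
    pts <- drop_ends(pts, guard)
  }
  pts <- add_extensions(pts, vol, mask_arr, h, max_ext)

  res <- resample_polyline(pts, step)
  new_centerline(res$points, step)
}

drop_ends <- function(pts, g) {
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  keep <- s >= g & s <= total - g
  if (sum(keep) < 3) return(pts)
  pts[keep, , drop = FALSE]
}

add_extensions <- function(pts, vol, mask_arr, h, max_ext) {
  ext_head <- extend_end(pts, head = TRUE, vol, mask_arr, h, max_ext)
  ext_tail <- extend_end(pts, head = FALSE, vol, mask_arr, h, max_ext)
  rbind(ext_head, pts, ext_tail)
}

# replace each curve sample by the centroid of the in-plane connected
# component containing it (orthogonal cross-section); samples whose section
# is empty are left in place
recenter_curve <- function(vol, fg, pts, extent, res = NULL) {
  if (is.null(res)) res <- max(min(vol$spacing), 0.8)
  n <- nrow(pts)
  tang <- polyline_tangents(pts)
  frames <- transport_frames(tang)
  half <- extent / 2
  ax <- seq(-half, half, by = res)
  np <- length(ax)
  pg <- as.matrix(expand.grid(a = ax, b = ax))
  centre_px <- which.min(pg[, 1]^2 + pg[, 2]^2)
  dims <- dim(vol$grid)
  out <- pts
  for (i in seq_len(n)) {
    u <- frames$normal[i, ]; v <- frames$binormal[i, ]
    plane_world <- cbind(
      pts[i, 1] + pg[, 1] * u[1] + pg[, 2] * v[1],
      pts[i, 2] + pg[, 1] * u[2] + pg[, 2] * v[2],
      pts[i, 3] + pg[, 1] * u[3] + pg[, 2] * v[3]
    )
    vals <- cpp_interp_trilinear(fg, dims, world_to_voxel(vol, plane_world))
    sec <- as.integer(vals >= 0.5)
    if (sec[centre_px] == 0L) next
    lab <- cpp_label_components(sec, c(np, np, 1L))$labels
    comp <- lab == lab[centre_px]
    ca <- mean(pg[comp, 1]); cb <- mean(pg[comp, 2])
    out[i, ] <- pts[i, ] + ca * u + cb * v
  }
  out
}

polyline_tangents <- function(pts) {
  n <- nrow(pts)
  tang <- matrix(0, n, 3)
  tang[1, ] <- pts[2, ] - pts[1, ]
  tang[n, ] <- pts[n, ] - pts[n - 1, ]
  if (n > 2) tang[2:(n - 1), ] <- pts[3:n, , drop = FALSE] - pts[1:(n - 2), , drop = FALSE]
  tang / sqrt(rowSums(tang^2))
}

farthest_voxel <- function(dist) {
  finite <- is.finite(dist)
  dmax <- max(dist[finite])
  which(finite & dist == dmax)[1] - 1L   # lexicographically smallest index
}

backtrack_path <- function(parent, target) {
  path <- integer(0)
  v <- target
  while (v >= 0) {
    path <- c(path, v)
    v <- parent[v + 1L]
  }
  rev(path)
}

linear_to_ijk <- function(idx0, dims) {
  nx <- dims[1]; ny <- dims[2]
  cbind(idx0 %% nx, (idx0 %/% nx) %% ny, idx0 %/% (nx * ny)) + 1
}

smooth_polyline <- function(pts, window) {
  n <- nrow(pts)
  if (window <= 1 || n < window) return(pts)
  half <- window %/% 2
  out <- pts
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    out[i, ] <- colMeans(pts[lo:hi, , drop = FALSE])
  }
  out
}

extend_end <- function(pts, head, vol, mask_arr, h, max_ext) {
  n <- nrow(pts)
  k <- min(10L, n - 1L)
  if (head) {
    p0 <- pts[1, ]
    dir <- pts[1, ] - pts[1 + k, ]
  } else {
    p0 <- pts[n, ]
    dir <- pts[n, ] - pts[n - k, ]
  }
  dn <- sqrt(sum(dir^2))
  if (dn < 1e-9) return(NULL)
  dir <- dir / dn
  stepl <- h / 2
  added <- NULL
  t <- stepl
  while (t <= max_ext) {
    p <- p0 + t * dir
    v <- round(world_to_voxel(vol, matrix(p, 1))) + 1
    if (any(v < 1) || any(v > dim(mask_arr)) || !mask_arr[v[1], v[2], v[3]]) break
    added <- rbind(added, p)
    t <- t + stepl
  }
  if (is.null(added)) return(NULL)
  if (head) added[rev(seq_len(nrow(added))), , drop = FALSE] else added
}

resample_polyline <- function(pts, step) {
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  keep <- c(TRUE, seg > 1e-9)
  pts <- pts[keep, , drop = FALSE]
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  n_int <- max(2L, round(total / step))
  grid <- seq(0, total, length.out = n_int + 1L)
  out <- cbind(
    stats::approx(s, pts[, 1], xout = grid)$y,
    stats::approx(s, pts[, 2], xout = grid)$y,
    stats::approx(s, pts[, 3], xout = grid)$y
  )
  list(points = out, s = grid)
}

new_centerline <- function(points, step) {
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  arclen <- c(0, cumsum(seg))
  n <- nrow(points)
  tang <- matrix(0, n, 3)
  tang[1, ] <- points[2, ] - points[1, ]
  tang[n, ] <- points[n, ] - points[n - 1, ]
  if (n > 2) tang[2:(n - 1), ] <- points[3:n, , drop = FALSE] - points[1:(n - 2), , drop = FALSE]
  tang <- tang / sqrt(rowSums(tang^2))
  structure(
    list(points = points, arclen = arclen, tangents = tang, step = step,
         ao_length = arclen[n]),
    class = "aorta_centerline"
  )
}

#' @export
print.aorta_centerline <- function(x, ...) {
  cat("<aorta_centerline> ", nrow(x$points), " samples, step ", x$step,
      " mm, Ao_length ", round(x$ao_length, 1), " mm\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.aorta_centerline <- function(x, ...) {
  as.data.frame(tibble::as_tibble(x))
}

#' Tabular view of a centerline
#'
#' @param x An `aorta_centerline`.
#' @param ... Unused.
#' @return Tibble with columns `x`, `y`, `z`, `arclen` (mm) and the unit
#'   tangent components `tx`, `ty`, `tz`.
#' @export
as_tibble.aorta_centerline <- function(x, ...) {
  pts <- x$points
  tang <- x$tangents
  s <- x$arclen
  tibble::tibble(
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    arclen = s,
    tx = tang[, 1], ty = tang[, 2], tz = tang[, 3]
  )
}

#' Export a centerline as CSV
#'
#' Writes `x`, `y`, `z` (mm) and `arclen` columns.
#'
#' @param cl An `aorta_centerline`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_centerline_csv <- function(cl, path) {
  readr::write_csv(tibble::as_tibble(cl)[, c("x", "y", "z", "arclen")], path)
  invisible(path)
}
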