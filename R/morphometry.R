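#' Orthogonal cross-section diameter profile
#'
#' For every centerline sample, the whole-aorta mask is resampled on a 2D
#' plane orthogonal to the local tangent (bilinear/trilinear interpolation of
#' the binary mask, thresholded at 0.5), the connected component containing
#' the centerline point is kept, and its maximal Feret diameter is recorded
#' in mm. This reproduces the clinical double-oblique convention for maximal
#' diameter: planes follow the vessel axis, not the scanner axes.
#'
#' Samples within `end_guard` mm of either end of the centerline are flagged
#' invalid for peak search (planes near an open tube end cut obliquely
#' through the cap and inflate the Feret diameter); they keep their measured
#' value but are excluded from `d_max` and from the local-volume peak
#' selection. Samples with an empty cross-section are flagged invalid with a
#' warning.
#'
#' @param vol A [label_volume()].
#' @param cl An `aorta_centerline` extracted from the same volume.
#' @param end_guard Arc-length guard at both ends in mm (default 10).
#' @param plane_extent Side length of the sampling plane in mm; must be at
#'   least twice the largest expected diameter (default 120).
#' @param plane_res In-plane sampling resolution in mm; default
#'   `min(0.5, min(spacing))`.
#' @return A tibble of class `diameter_profile` with columns `arclen` (mm),
#'   `diameter` (mm, `NA` where the section was empty) and `valid`.
#' @export
diameter_profile <- function(vol, cl, end_guard = 10, plane_extent = 120,
                             plane_res = NULL) {
  if (end_guard < 0) abort("end_guard must be >= 0")
  if (is.null(plane_res)) plane_res <- min(0.5, min(vol$spacing))
  dims <- dim(vol$grid)
  fg <- array(as.numeric(label_mask(vol)), dims)

  half <- plane_extent / 2
  ax <- seq(-half, half, by = plane_res)
  np <- length(ax)
  pg <- as.matrix(expand.grid(a = ax, b = ax))
  centre_px <- which(pg[, 1] == 0 & pg[, 2] == 0)[1]

  frames <- transport_frames(cl$tangents)
  n <- nrow(cl$points)
  diam <- rep(NA_real_, n)
  touched_border <- FALSE
  for (i in seq_len(n)) {
    u <- frames$normal[i, ]; v <- frames$binormal[i, ]
    plane_world <- cbind(
      cl$points[i, 1] + pg[, 1] * u[1] + pg[, 2] * v[1],
      cl$points[i, 2] + pg[, 1] * u[2] + pg[, 2] * v[2],
      cl$points[i, 3] + pg[, 1] * u[3] + pg[, 2] * v[3]
    )
    vals <- cpp_interp_trilinear(fg, dims, world_to_voxel(vol, plane_world))
    sec <- as.integer(vals >= 0.5)
    if (sec[centre_px] == 0L) next
    lab <- cpp_label_components(sec, c(np, np, 1L))$labels
    comp <- lab == lab[centre_px]
    idx <- which(comp)
    row <- (idx - 1L) %% np + 1L
    col <- (idx - 1L) %/% np + 1L
    if (any(row == 1L | row == np | col == 1L | col == np)) touched_border <- TRUE
    diam[i] <- feret_diameter(ax[row], ax[col])
  }
  if (touched_border) {
    abort(paste0("cross-section reaches the edge of the sampling plane; ",
                 "increase plane_extent (currently ", plane_extent, " mm)"))
  }
  n_empty <- sum(is.na(diam))
  if (n_empty > 0) {
    warn(paste0(n_empty, " centerline sample(s) had an empty cross-section; ",
                "flagged invalid"))
  }
  valid <- !is.na(diam) &
    cl$arclen >= end_guard & cl$arclen <= cl$ao_length - end_guard
  out <- tibble::tibble(arclen = cl$arclen, diameter = diam, valid = valid)
  class(out) <- c("diameter_profile", class(out))
  attr(out, "end_guard") <- end_guard
  attr(out, "plane_res") <- plane_res
  out
}

# maximal pairwise distance between section pixels (via convex hull),
# in the plane's (a, b) mm coordinates
feret_diameter <- function(a, b) {
  if (length(a) == 1) return(0)
  hull <- grDevices::chull(a, b)
  ha <- a[hull]; hb <- b[hull]
  if (length(hull) == 1) return(0)
  d2 <- outer(ha, ha, "-")^2 + outer(hb, hb, "-")^2
  sqrt(max(d2))
}

# parallel (rotation-minimising) frames along a polyline given unit tangents
transport_frames <- function(tangents) {
  n <- nrow(tangents)
  normal <- matrix(0, n, 3)
  binormal <- matrix(0, n, 3)
  t1 <- tangents[1, ]
  ref <- if (abs(t1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * t1) * t1
  u <- u / sqrt(sum(u^2))
  normal[1, ] <- u
  binormal[1, ] <- cross3(t1, u)
  for (i in 2:n) {
    ti <- tangents[i, ]
    u <- normal[i - 1, ]
    u <- u - sum(u * ti) * ti
    nu <- sqrt(sum(u^2))
    if (nu < 1e-9) {
      ref <- if (abs(ti[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      u <- ref - sum(ref * ti) * ti
      nu <- sqrt(sum(u^2))
    }
    normal[i, ] <- u / nu
    binormal[i, ] <- cross3(ti, normal[i, ])
  }
  list(normal = normal, binormal = binormal)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Global aortic measures for one scan
#'
#' Component volumes are voxel counts times the voxel volume (mL), so
#' `ao_glo = v_tl + v_cfl + v_th` and `fl_glo = v_cfl + v_th` hold exactly.
#' `d_max` is the maximum of the diameter profile over valid samples, with
#' its arc-length position. The local false-lumen volume column `fl_loc` is
#' left `NA`; fill it with [fl_loc()] or use [measure_aorta()] for the full
#' pipeline.
#'
#' @param vol A [label_volume()].
#' @param cl An `aorta_centerline`.
#' @param profile A [diameter_profile()].
#' @return One-row tibble of class `aorta_measures` with columns `d_max`,
#'   `d_max_position`, `ao_length` (mm), `v_tl`, `v_cfl`, `v_th`, `ao_glo`,
#'   `fl_glo`, `fl_loc` (mL), `fl_glo_over_ao_glo` (dimensionless) and
#'   `fl_glo_over_ao_length` (mL/mm).
#' @export
global_measures <- function(vol, cl, profile) {
  if (!any(profile$valid)) abort("no valid diameter-profile samples")
  vols <- component_volumes(vol)
  i <- which(profile$valid)
  imax <- i[which.max(profile$diameter[i])]
  out <- tibble::tibble(
    d_max = profile$diameter[imax],
    d_max_position = profile$arclen[imax],
    ao_length = cl$ao_length,
    v_tl = vols[["v_tl"]],
    v_cfl = vols[["v_cfl"]],
    v_th = vols[["v_th"]],
    ao_glo = vols[["ao_glo"]],
    fl_glo = vols[["fl_glo"]],
    fl_loc = NA_real_,
    fl_glo_over_ao_glo = if (vols[["ao_glo"]] > 0) vols[["fl_glo"]] / vols[["ao_glo"]] else 0,
    fl_glo_over_ao_length = vols[["fl_glo"]] / cl$ao_length
  )
  class(out) <- c("aorta_measures", class(out))
  out
}
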