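#' Select the two largest-diameter positions
#'
#' `s1` is the arc-length position of the global maximum of the diameter
#' profile over valid samples. `s2` is the position of the largest diameter
#' among valid samples at least `min_separation` mm away from `s1` (the
#' second candidate is the second-largest diameter outside the exclusion
#' zone, not necessarily a local maximum), or `NA` when no such sample
#' exists. Diameter ties break toward the smaller arc length.
#'
#' @param profile A [diameter_profile()] (any data frame with `arclen`,
#'   `diameter`, `valid` columns).
#' @param min_separation Minimum arc-length separation in mm (default 10).
#' @return Named list with `s1` and `s2` (mm; `s2` may be `NA`).
#' @export
select_diameter_positions <- function(profile, min_separation = 10) {
  if (min_separation < 0) abort("min_separation must be >= 0")
  ok <- which(profile$valid & !is.na(profile$diameter))
  if (!length(ok)) abort("no valid samples in the diameter profile")
  i1 <- ok[which.max(profile$diameter[ok])]
  s1 <- profile$arclen[i1]
  eligible <- ok[abs(profile$arclen[ok] - s1) >= min_separation]
  s2 <- if (length(eligible)) {
    profile$arclen[eligible[which.max(profile$diameter[eligible])]]
  } else {
    NA_real_
  }
  list(s1 = s1, s2 = s2)
}

#' Arc-length section window
#'
#' A window of `2 * half_width` mm centred on an arc-length position,
#' clipped to the available centerline span `[0, ao_length]` without
#' re-centering, so an end-truncated window keeps its reduced span.
#'
#' @param center Window centre, arc length in mm.
#' @param ao_length Total centerline length in mm.
#' @param half_width Half-width in mm (default 15, i.e. the 30-mm section).
#' @return Named list `center`, `lo`, `hi`, `effective_span` (mm).
#' @export
section_window <- function(center, ao_length, half_width = 15) {
  if (center < 0 || center > ao_length) {
    abort("window center must lie within [0, ao_length]")
  }
  lo <- max(0, center - half_width)
  hi <- min(ao_length, center + half_width)
  list(center = center, lo = lo, hi = hi, effective_span = hi - lo)
}

# assignment of false-lumen voxels (CFL + TH) to their nearest centerline
# sample; returns per-voxel sample arclen and the voxel volume in mL
fl_voxel_assignment <- function(vol, cl) {
  fl <- label_mask(vol, c("CFL", "TH"))
  idx <- which(fl, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(list(arclen = numeric(0), voxel_ml = voxel_volume_ml(vol)))
  }
  world <- voxel_to_world(vol, idx)
  nearest <- cpp_nearest_sample(world, cl$points)
  list(arclen = cl$arclen[nearest], voxel_ml = voxel_volume_ml(vol))
}

#' Local false-lumen volume in one arc-length window
#'
#' Every CFL and TH voxel is assigned to its nearest resampled centerline
#' point (Euclidean distance in world mm); the volumes of voxels whose
#' assigned arc length falls inside the clipped window are summed. Nearest-
#' point assignment (rather than normal-plane slabs) avoids double counting
#' at high curvature and partitions the false lumen exactly, so summing over
#' a disjoint tiling of windows reproduces the global false-lumen volume.
#'
#' @param vol A [label_volume()].
#' @param cl An `aorta_centerline`.
#' @param window A [section_window()], or a numeric window centre in mm
#'   (combined with `half_width`).
#' @param half_width Half-width in mm used when `window` is a plain centre.
#' @param assignment Optional precomputed result of the internal voxel
#'   assignment, to reuse across windows.
#' @return Volume in mL (0 when the volume has no false-lumen voxels).
#' @export
local_false_lumen_volume <- function(vol, cl, window, half_width = 15,
                                     assignment = NULL) {
  if (is.numeric(window)) window <- section_window(window, cl$ao_length, half_width)
  if (is.null(assignment)) assignment <- fl_voxel_assignment(vol, cl)
  s <- assignment$arclen
  if (!length(s)) return(0)
  sum(s >= window$lo & s <= window$hi) * assignment$voxel_ml
}

#' Local false-lumen volume radiomarker (FL_Loc)
#'
#' The false-lumen volume restricted to an arc-length section (default
#' 30 mm: 15 mm proximal to 15 mm distal) around the largest-diameter
#' position; the measurement is repeated at the second-largest diameter at
#' least `min_separation` mm away, and the larger of the two local volumes
#' is retained.
#'
#' @inheritParams local_false_lumen_volume
#' @param profile A [diameter_profile()].
#' @param section_length Full section length in mm. The values studied are
#'   10, 15, 30 (default) and 50; any positive value is accepted with a
#'   warning.
#' @param min_separation Minimum separation between the two candidate
#'   positions in mm (default 10).
#' @return Volume in mL, with attributes `s1`, `s2` (candidate positions)
#'   and `winner` (1 or 2).
#' @export
fl_loc <- function(vol, cl, profile, section_length = 30, min_separation = 10) {
  if (section_length <= 0) abort("section_length must be positive (mm)")
  if (!section_length %in% c(10, 15, 30, 50)) {
    warn(paste0("section_length ", section_length,
                " mm is outside the studied set {10, 15, 30, 50}"))
  }
  pos <- select_diameter_positions(profile, min_separation)
  assignment <- fl_voxel_assignment(vol, cl)
  hw <- section_length / 2
  v1 <- local_false_lumen_volume(vol, cl, section_window(pos$s1, cl$ao_length, hw),
                                 assignment = assignment)
  v2 <- if (!is.na(pos$s2)) {
    local_false_lumen_volume(vol, cl, section_window(pos$s2, cl$ao_length, hw),
                             assignment = assignment)
  } else {
    -Inf
  }
  out <- max(v1, v2)
  attr(out, "s1") <- pos$s1
  attr(out, "s2") <- pos$s2
  attr(out, "winner") <- if (v2 > v1) 2L else 1L
  out
}

#' FL_Loc across a sweep of section lengths
#'
#' @inheritParams fl_loc
#' @param section_lengths Numeric vector of full section lengths in mm.
#' @return Tibble with columns `section_length` and `fl_loc` (mL).
#' @export
fl_loc_sweep <- function(vol, cl, profile, section_lengths = c(10, 15, 30, 50),
                         min_separation = 10) {
  pos <- select_diameter_positions(profile, min_separation)
  assignment <- fl_voxel_assignment(vol, cl)
  vals <- vapply(section_lengths, function(L) {
    hw <- L / 2
    v1 <- local_false_lumen_volume(vol, cl, section_window(pos$s1, cl$ao_length, hw),
                                   assignment = assignment)
    v2 <- if (!is.na(pos$s2)) {
      local_false_lumen_volume(vol, cl, section_window(pos$s2, cl$ao_length, hw),
                               assignment = assignment)
    } else {
      -Inf
    }
    max(v1, v2)
  }, numeric(1))
  tibble::tibble(section_length = section_lengths, fl_loc = vals)
}

#' Measure one scan end-to-end
#'
#' Convenience wrapper: centerline, diameter profile, global measures and
#' FL_Loc (plus an optional section-length sweep) for a single label volume.
#'
#' @param vol A [label_volume()].
#' @param step Centerline resampling step in mm.
#' @param end_guard Diameter-profile end guard in mm.
#' @param section_length FL_Loc section length in mm (default 30).
#' @param min_separation Candidate-position separation in mm.
#' @param sweep Optional numeric vector of additional section lengths; adds
#'   `fl_loc_<L>` columns.
#' @param plane_extent Passed to [diameter_profile()].
#' @return One-row `aorta_measures` tibble (see [global_measures()]).
#' @export
measure_aorta <- function(vol, step = 1, end_guard = 10, section_length = 30,
                          min_separation = 10, sweep = NULL,
                          plane_extent = 120) {
  cl <- extract_centerline(vol, step = step)
  profile <- diameter_profile(vol, cl, end_guard = end_guard,
                              plane_extent = plane_extent)
  meas <- global_measures(vol, cl, profile)
  v <- fl_loc(vol, cl, profile, section_length = section_length,
              min_separation = min_separation)
  meas$fl_loc <- as.numeric(v)
  if (!is.null(sweep)) {
    sw <- fl_loc_sweep(vol, cl, profile, section_lengths = sweep,
                       min_separation = min_separation)
    for (k in seq_len(nrow(sw))) {
      meas[[paste0("fl_loc_", sw$section_length[k])]] <- sw$fl_loc[k]
    }
  }
  meas
}
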