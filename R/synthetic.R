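#' Specification of a synthetic dissected-aorta phantom
#'
#' A voxelisable tube phantom with known analytic measures, standing in for
#' patient segmentations. The tube follows a parametric centerline with
#' radius profile `r(s) = r0 + A * exp(-(s - s0)^2 / (2 w^2))`; every cross
#' section is split by a plane through the local axis so the false lumen
#' occupies `fl_fraction` of the area, and an angular sub-sector of the
#' false lumen covering `th_fraction` of it is labelled thrombus.
#'
#' @param centerline_kind `"straight"`, `"quarter_arc"` (quarter circle of
#'   radius `arch_radius`) or `"candy_cane"` (semicircular arch of radius
#'   `arch_radius` joined tangent-continuously to a straight descending
#'   limb).
#' @param length Tube length in mm (straight tubes).
#' @param arch_radius Arch radius in mm (curved kinds).
#' @param descending_length Descending limb length in mm (candy cane).
#' @param r0 Baseline tube radius in mm.
#' @param bulge `NULL`, or `list(amplitude, center, width)` in mm for a
#'   Gaussian bulge.
#' @param fl_fraction Cross-section area fraction assigned to the false
#'   lumen, in `[0, 1]`.
#' @param th_fraction Fraction of the false lumen assigned to thrombus, in
#'   `[0, 1]`.
#' @param spacing Isotropic voxel spacing in mm.
#' @param rotation Optional 3x3 rotation matrix applied to the phantom
#'   geometry (used to test grid-orientation invariance).
#' @param margin Background padding around the tube in mm.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(centerline_kind = c("straight", "quarter_arc", "candy_cane"),
                         length = 100, arch_radius = 40, descending_length = 120,
                         r0 = 15, bulge = NULL, fl_fraction = 0.5,
                         th_fraction = 0, spacing = 0.5, rotation = NULL,
                         margin = 5) {
  centerline_kind <- match.arg(centerline_kind)
  if (r0 <= 0) abort("r0 must be positive")
  if (spacing <= 0) abort("spacing must be positive")
  if (fl_fraction < 0 || fl_fraction > 1) abort("fl_fraction must be in [0, 1]")
  if (th_fraction < 0 || th_fraction > 1) abort("th_fraction must be in [0, 1]")
  if (!is.null(bulge)) {
    stopifnot(all(c("amplitude", "center", "width") %in% names(bulge)))
    if (bulge$width <= 0) abort("bulge width must be positive")
  }
  structure(
    list(centerline_kind = centerline_kind, length = length,
         arch_radius = arch_radius, descending_length = descending_length,
         r0 = r0, bulge = bulge, fl_fraction = fl_fraction,
         th_fraction = th_fraction, spacing = spacing, rotation = rotation,
         margin = margin),
    class = "phantom_spec"
  )
}

phantom_radius_fun <- function(spec) {
  if (is.null(spec$bulge)) {
    function(s) rep(spec$r0, length(s))
  } else {
    A <- spec$bulge$amplitude; s0 <- spec$bulge$center; w <- spec$bulge$width
    function(s) spec$r0 + A * exp(-(s - s0)^2 / (2 * w^2))
  }
}

phantom_curve <- function(spec, ds) {
  L <- switch(spec$centerline_kind,
    straight = spec$length,
    quarter_arc = pi * spec$arch_radius / 2,
    candy_cane = pi * spec$arch_radius + spec$descending_length
  )
  s <- seq(0, L, by = ds)
  if (s[length(s)] < L) s <- c(s, L)
  R <- spec$arch_radius
  pts <- switch(spec$centerline_kind,
    straight = cbind(0, 0, s),
    quarter_arc = cbind(R * sin(s / R), 0, R * (1 - cos(s / R))),
    candy_cane = {
      arc_len <- pi * R
      on_arc <- s <= arc_len
      th <- s[on_arc] / R
      p_arc <- cbind(R * (1 - cos(th)), 0, R * sin(th))
      d <- s[!on_arc] - arc_len
      p_desc <- cbind(2 * R, 0, -d)
      rbind(p_arc, p_desc)
    }
  )
  if (!is.null(spec$rotation)) pts <- pts %*% t(spec$rotation)
  list(s = s, points = pts, total_length = L)
}

#' Voxelise a phantom and return its analytic ground truth
#'
#' Builds the parametric tube of a [phantom_spec()] on a voxel grid and
#' returns both the label volume and the closed-form measures: length from
#' the curve, volumes from the quadrature of `pi * r(s)^2` times the label
#' fractions, `d_max = 2 * max r(s)`, and the analytic local false-lumen
#' volume for the requested section length (windowed quadrature around the
#' radius peak).
#'
#' @param spec A [phantom_spec()].
#' @param section_length Section length (mm) for the analytic `fl_loc`.
#' @return List with `volume` (a [label_volume()]) and `analytic` (a
#'   one-row `aorta_measures` tibble).
#' @export
voxelize_phantom <- function(spec, section_length = 30) {
  h <- spec$spacing
  if (2 * spec$r0 / h < 6) {
    abort("spacing too coarse: fewer than 6 voxels across the smallest diameter")
  }
  ds <- min(0.25, h / 2)
  crv <- phantom_curve(spec, ds)
  rfun <- phantom_radius_fun(spec)
  radii <- rfun(crv$s)

  n <- nrow(crv$points)
  tang <- matrix(0, n, 3)
  tang[1, ] <- crv$points[2, ] - crv$points[1, ]
  tang[n, ] <- crv$points[n, ] - crv$points[n - 1, ]
  tang[2:(n - 1), ] <- crv$points[3:n, , drop = FALSE] - crv$points[1:(n - 2), , drop = FALSE]
  tang <- tang / sqrt(rowSums(tang^2))
  frames <- transport_frames(tang)

  pad <- max(radii) + spec$margin
  lo <- apply(crv$points, 2, min) - pad
  hi <- apply(crv$points, 2, max) + pad
  dims <- as.integer(ceiling((hi - lo) / h)) + 1L
  codes <- c(TL = 1L, CFL = 2L, TH = 3L)

  labels <- cpp_voxelize_tube(dims, rep(h, 3), lo, crv$points, tang,
                              frames$normal, frames$binormal, radii, ds,
                              spec$fl_fraction, spec$th_fraction,
                              unname(codes))
  vol <- label_volume(array(labels, dims), spacing = rep(h, 3), origin = lo)
  list(volume = vol, analytic = phantom_analytic(spec, section_length))
}

#' Analytic measures of a phantom
#'
#' @inheritParams voxelize_phantom
#' @return One-row `aorta_measures` tibble (all volumes in mL, lengths mm).
#' @export
phantom_analytic <- function(spec, section_length = 30) {
  crv <- phantom_curve(spec, 0.1)
  L <- crv$total_length
  rfun <- phantom_radius_fun(spec)
  area <- function(s) pi * rfun(s)^2
  v_total <- integrate(area, 0, L, rel.tol = 1e-10)$value / 1000
  v_fl <- spec$fl_fraction * v_total
  v_th <- spec$th_fraction * v_fl
  v_cfl <- v_fl - v_th
  v_tl <- v_total - v_fl

  if (is.null(spec$bulge)) {
    d_max <- 2 * spec$r0
    peak <- L / 2   # uniform profile: any interior position
  } else {
    d_max <- 2 * (spec$r0 + spec$bulge$amplitude)
    peak <- spec$bulge$center
  }
  win <- section_window(min(max(peak, 0), L), L, section_length / 2)
  fl_loc_an <- spec$fl_fraction *
    integrate(area, win$lo, win$hi, rel.tol = 1e-10)$value / 1000

  out <- tibble::tibble(
    d_max = d_max, d_max_position = peak, ao_length = L,
    v_tl = v_tl, v_cfl = v_cfl, v_th = v_th,
    ao_glo = v_total, fl_glo = v_fl, fl_loc = fl_loc_an,
    fl_glo_over_ao_glo = if (v_total > 0) v_fl / v_total else 0,
    fl_glo_over_ao_length = v_fl / L
  )
  class(out) <- c("aorta_measures", class(out))
  out
}

#' Two-group marker summaries used as simulation defaults
#'
#' Printed group means and standard deviations of the three baseline
#' markers in the two clinical validation cohorts (internal, `"center1"`,
#' 39 adverse-remodeling events / 44 event-free; external, `"center2"`,
#' 33 / 46). These define the default conditions for the binormal cohort
#' simulator.
#'
#' @param center `"center1"` or `"center2"`.
#' @return List with `params` (tibble: `marker`, `mean_event`, `sd_event`,
#'   `mean_nonevent`, `sd_nonevent`), `n_event`, `n_nonevent`.
#' @export
remodeling_cohort_params <- function(center = c("center1", "center2")) {
  center <- match.arg(center)
  if (center == "center1") {
    list(
      params = tibble::tribble(
        ~marker,  ~mean_event, ~sd_event, ~mean_nonevent, ~sd_nonevent,
        "d_max",         44.0,       5.1,           40.0,          4.5,
        "fl_glo",       185.0,      87.9,          110.7,         56.9,
        "fl_loc",        22.4,       9.9,           10.0,          8.1
      ),
      n_event = 39L, n_nonevent = 44L
    )
  } else {
    list(
      params = tibble::tribble(
        ~marker,  ~mean_event, ~sd_event, ~mean_nonevent, ~sd_nonevent,
        "d_max",         43.3,       6.4,           40.9,          5.6,
        "fl_glo",       193.6,      70.8,          143.5,         73.8,
        "fl_loc",        22.4,       8.8,           14.3,          7.6
      ),
      n_event = 33L, n_nonevent = 46L
    )
  }
}

#' Simulate a two-group marker cohort
#'
#' Draws event-group and event-free marker values from Gaussian
#' distributions with the given group means and SDs (markers are drawn
#' independently of each other). Normality is the minimal assumption
#' consistent with summary-level group statistics and makes the binormal
#' AUC [binormal_auc()] a closed-form oracle.
#'
#' @param params Tibble with columns `marker`, `mean_event`, `sd_event`,
#'   `mean_nonevent`, `sd_nonevent` (see [remodeling_cohort_params()]).
#' @param n_event,n_nonevent Group sizes (`>= 2`).
#' @param seed Optional integer seed (local to this call).
#' @return Tibble: `patient_id`, `outcome` (1 = event), one column per
#'   marker.
#' @export
simulate_marker_cohort <- function(params, n_event, n_nonevent, seed = NULL) {
  stopifnot(all(c("marker", "mean_event", "sd_event", "mean_nonevent",
                  "sd_nonevent") %in% names(params)))
  if (n_event < 2 || n_nonevent < 2) abort("need n >= 2 per group")
  if (any(params$sd_event <= 0) || any(params$sd_nonevent <= 0)) {
    abort("group SDs must be positive")
  }
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  out <- tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n_event + n_nonevent)),
    outcome = c(rep(1L, n_event), rep(0L, n_nonevent))
  )
  for (k in seq_len(nrow(params))) {
    out[[params$marker[k]]] <- c(
      rnorm(n_event, params$mean_event[k], params$sd_event[k]),
      rnorm(n_nonevent, params$mean_nonevent[k], params$sd_nonevent[k])
    )
  }
  out
}

#' Closed-form binormal AUC
#'
#' For Gaussian event and non-event groups the population AUC is
#' `pnorm((mean_event - mean_nonevent) / sqrt(sd_event^2 + sd_nonevent^2))`.
#'
#' @param mean_event,sd_event,mean_nonevent,sd_nonevent Group parameters.
#' @return AUC in `[0, 1]`.
#' @export
binormal_auc <- function(mean_event, sd_event, mean_nonevent, sd_nonevent) {
  pnorm((mean_event - mean_nonevent) / sqrt(sd_event^2 + sd_nonevent^2))
}

#' Replicate-averaged simulated AUC for one marker
#'
#' Repeatedly simulates a two-group Gaussian cohort and averages the
#' midrank/trapezoid AUC over the replicates.
#'
#' @inheritParams binormal_auc
#' @param n_event,n_nonevent Group sizes.
#' @param replicates Number of replicates (default 2000).
#' @param seed Integer seed (local to this call).
#' @return List with `auc_mean`, `auc_sd`, `replicates`.
#' @export
simulate_auc <- function(mean_event, sd_event, n_event,
                         mean_nonevent, sd_nonevent, n_nonevent,
                         replicates = 2000, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  aucs <- vapply(seq_len(replicates), function(i) {
    pair_auc(rnorm(n_event, mean_event, sd_event),
             rnorm(n_nonevent, mean_nonevent, sd_nonevent))
  }, numeric(1))
  list(auc_mean = mean(aucs), auc_sd = sd(aucs), replicates = replicates)
}

#' Simulate a paired (two-scan) cohort
#'
#' T1 values come from the two-group Gaussian model; the inter-scan
#' interval is drawn per patient (truncated to more than 30 days); T2 is T1
#' plus the group's annual change scaled by the interval, plus optional
#' measurement noise. Supports end-to-end testing of the annualise-then-
#' evaluate chain.
#'
#' @param params One-marker parameter tibble (as in
#'   [simulate_marker_cohort()]).
#' @param n_event,n_nonevent Group sizes.
#' @param growth_event,growth_nonevent Length-2 numeric `c(mean, sd)` of
#'   the annual change per group (marker units / year).
#' @param delta_days_mean,delta_days_sd Interval distribution in days
#'   (default 194 +/- 77).
#' @param noise_sd Measurement noise SD added to T2 (default 0).
#' @param seed Optional integer seed (local to this call).
#' @return Tibble: `patient_id`, `outcome`, `<marker>_t1`, `<marker>_t2`,
#'   `delta_days`.
#' @export
simulate_paired_cohort <- function(params, n_event, n_nonevent,
                                   growth_event, growth_nonevent,
                                   delta_days_mean = 194, delta_days_sd = 77,
                                   noise_sd = 0, seed = NULL) {
  if (nrow(params) != 1) abort("simulate_paired_cohort expects a single marker")
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  base <- simulate_marker_cohort(params, n_event, n_nonevent)
  n <- nrow(base)
  delta <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      d <- rnorm(1, delta_days_mean, delta_days_sd)
      if (d > 30) break
    }
    delta[i] <- d
  }
  growth <- ifelse(base$outcome == 1,
                   rnorm(n, growth_event[1], growth_event[2]),
                   rnorm(n, growth_nonevent[1], growth_nonevent[2]))
  m <- params$marker[1]
  t1 <- base[[m]]
  t2 <- t1 + growth * delta / 365 + rnorm(n, 0, noise_sd)
  tibble::tibble(
    patient_id = base$patient_id,
    outcome = base$outcome,
    !!paste0(m, "_t1") := t1,
    !!paste0(m, "_t2") := t2,
    delta_days = delta
  )
}
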