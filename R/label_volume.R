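#' Default label coding for dissected-aorta segmentations
#'
#' A dissected-aorta label map distinguishes the true lumen (TL), the
#' circulating false lumen (CFL) and mural thrombus (TH), with 0 as
#' background. Codes are remappable for segmentations exported with other
#' conventions.
#'
#' @return Named integer vector with entries `background`, `TL`, `CFL`, `TH`.
#' @export
#' @examples
#' default_label_map()
default_label_map <- function() {
  c(background = 0L, TL = 1L, CFL = 2L, TH = 3L)
}

validate_label_map <- function(label_map) {
  needed <- c("background", "TL", "CFL", "TH")
  if (!all(needed %in% names(label_map))) {
    abort(paste0("label_map must name codes for: ",
                 paste(setdiff(needed, names(label_map)), collapse = ", ")))
  }
  if (anyDuplicated(label_map[needed])) abort("label_map codes must be distinct")
  vapply(label_map[needed], as.integer, integer(1))
}

#' Construct a label volume
#'
#' Wraps a 3D integer array of segmentation labels together with its voxel
#' spacing and voxel-to-world affine. All geometry downstream (centerline,
#' diameters, volumes) is computed in world millimetres, so anisotropic
#' spacing is handled uniformly.
#'
#' @param grid 3D integer array of label codes.
#' @param spacing Numeric length-3 voxel spacing in mm, all `> 0`.
#' @param origin World coordinates (mm) of the centre of voxel `[1, 1, 1]`.
#'   Ignored when `affine` is given.
#' @param affine Optional 4x4 voxel-to-world matrix acting on 0-based voxel
#'   indices; defaults to `diag(spacing)` with translation `origin`.
#' @param label_map Named integer vector of label codes
#'   (see [default_label_map()]).
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(grid, spacing, origin = c(0, 0, 0), affine = NULL,
                         label_map = default_label_map()) {
  label_map <- validate_label_map(label_map)
  if (length(dim(grid)) != 3L) abort("grid must be a 3D array")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("spacing must be three positive finite values (mm)")
  }
  storage.mode(grid) <- "integer"
  bad <- setdiff(unique(as.vector(grid)), unname(label_map))
  if (length(bad)) {
    abort(paste0("grid contains voxel values outside the label map: {",
                 paste(sort(bad), collapse = ", "), "}"))
  }
  if (is.null(affine)) {
    affine <- diag(4)
    affine[1:3, 1:3] <- diag(spacing, 3)
    affine[1:3, 4] <- origin
  }
  structure(
    list(grid = grid, spacing = as.numeric(spacing), affine = affine,
         label_map = label_map),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$grid), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  counts <- label_counts(x)
  cat("  voxels per label: ",
      paste(names(counts), counts, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

label_counts <- function(vol) {
  vapply(vol$label_map, function(code) sum(vol$grid == code), numeric(1))
}

#' Read a label volume from NIfTI
#'
#' Reads an integer-valued NIfTI segmentation, extracts spacing and affine
#' from the header, and validates every voxel value against the label map.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @inheritParams label_volume
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, label_map = default_label_map()) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1L]
  if (length(dim(arr)) != 3L) abort("expected a 3D NIfTI volume")
  if (max(abs(arr - round(arr))) > 1e-6) {
    abort("NIfTI data are not integer-valued labels")
  }
  arr <- array(as.integer(round(arr)), dim(arr))
  spacing <- RNifti::pixdim(img)[1:3]
  affine <- unclass(RNifti::xform(img))
  label_volume(arr, spacing = spacing, affine = affine, label_map = label_map)
}

#' Write a label volume to NIfTI
#'
#' @param vol A [label_volume()].
#' @param path Output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$grid)
  RNifti::pixdim(img) <- vol$spacing
  aff <- structure(vol$affine, code = 2L)
  RNifti::sform(img) <- aff
  RNifti::qform(img) <- aff
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Binary mask for a set of labels
#'
#' @param vol A [label_volume()].
#' @param labels Character vector among `"TL"`, `"CFL"`, `"TH"`,
#'   `"background"`. The default is the whole-aorta union TL + CFL + TH.
#' @return Logical 3D array.
#' @export
label_mask <- function(vol, labels = c("TL", "CFL", "TH")) {
  codes <- vol$label_map[labels]
  if (anyNA(codes)) abort("unknown label names")
  array(vol$grid %in% codes, dim = dim(vol$grid))
}

# world coordinates (mm) of 1-based voxel indices (n x 3 matrix)
voxel_to_world <- function(vol, idx) {
  idx0 <- cbind(idx - 1, 1)
  t(vol$affine %*% t(idx0))[, 1:3, drop = FALSE]
}

# continuous 0-based voxel coordinates of world points (n x 3, mm)
world_to_voxel <- function(vol, pts) {
  inv <- solve(vol$affine)
  t(inv %*% t(cbind(pts, 1)))[, 1:3, drop = FALSE]
}

# voxel volume in mL
voxel_volume_ml <- function(vol) prod(vol$spacing) / 1000

#' Per-component volumes in mL
#'
#' Volumes are voxel counts times the voxel volume, in world units, so the
#' conservation identity `ao_glo = v_tl + v_cfl + v_th` holds exactly.
#'
#' @param vol A [label_volume()].
#' @return Named numeric vector `v_tl`, `v_cfl`, `v_th`, `ao_glo`, `fl_glo`
#'   (mL).
#' @export
component_volumes <- function(vol) {
  vv <- voxel_volume_ml(vol)
  counts <- label_counts(vol)
  v_tl <- counts[["TL"]] * vv
  v_cfl <- counts[["CFL"]] * vv
  v_th <- counts[["TH"]] * vv
  c(v_tl = v_tl, v_cfl = v_cfl, v_th = v_th,
    ao_glo = v_tl + v_cfl + v_th, fl_glo = v_cfl + v_th)
}

#' Read a cohort table from CSV
#'
#' Expects one row per patient with at least a `patient_id` column, marker
#' columns, and a binary `outcome` column; optional `t1_date` / `t2_date`
#' columns are parsed as dates.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"patient_id" %in% names(df)) abort("cohort CSV must have a patient_id column")
  if ("outcome" %in% names(df)) {
    ok <- df$outcome %in% c(0, 1) | is.na(df$outcome)
    if (!all(ok)) abort("outcome must be coded 0/1")
  }
  df
}
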