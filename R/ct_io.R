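# CT volume input/output, image quality filtering, Hounsfield-unit
# harmonization, and lung-region cropping.

#' Construct a CT volume object
#'
#' A `ct_volume` bundles a 3D voxel grid in Hounsfield Units with its
#' physical geometry: per-axis voxel spacing in mm and the physical
#' position of the first voxel. Patch geometry downstream is always
#' computed in physical mm and converted to voxel counts through the
#' spacing.
#'
#' @param voxels 3D numeric array of CT intensities in Hounsfield Units.
#' @param spacing Numeric length-3, voxel spacing in mm (x, y, z); all
#'   components must be positive.
#' @param origin Numeric length-3, physical coordinate (mm) of voxel
#'   (1,1,1). Defaults to the origin.
#' @param patient_id Patient identifier string.
#' @param meta Optional named list of scanner/acquisition tags.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                      patient_id = "unknown", meta = list()) {
  assert_that(is.array(voxels) && length(dim(voxels)) == 3,
              "voxels must be a 3D array")
  assert_that(length(spacing) == 3 && all(is.finite(spacing)) &&
                all(spacing > 0),
              "spacing must be 3 positive finite values (mm)")
  assert_that(length(origin) == 3 && all(is.finite(origin)),
              "origin must be 3 finite values (mm)")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 patient_id = as.character(patient_id), meta = meta),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s: %s voxels, spacing %s mm, HU range [%g, %g]\n",
              x$patient_id, paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Construct a lung region-of-interest mask
#'
#' The mask lives on the same voxel lattice as its companion volume. A
#' `bounding_box` kind means the foreground is the filled axis-aligned
#' box enclosing the lung (the coarse annotation mode); `mask` means a
#' voxel-wise lung segmentation.
#'
#' @param mask 3D logical/0-1 array; at least one foreground voxel.
#' @param kind `"mask"` or `"bounding_box"`.
#' @return An object of class `lung_roi`.
#' @export
lung_roi <- function(mask, kind = c("mask", "bounding_box")) {
  kind <- match.arg(kind)
  assert_that(is.array(mask) && length(dim(mask)) == 3,
              "mask must be a 3D array")
  m <- array(as.logical(mask), dim = dim(mask))
  assert_that(!anyNA(m), "mask contains NA")
  assert_that(any(m), "mask has no foreground voxel")
  structure(list(mask = m, kind = kind), class = "lung_roi")
}

check_companion <- function(vol, roi) {
  assert_that(inherits(vol, "ct_volume") && inherits(roi, "lung_roi"),
              "expected a ct_volume and a lung_roi")
  assert_that(identical(dim(vol$voxels), dim(roi$mask)),
              "volume and ROI are not on the same voxel lattice")
  invisible(TRUE)
}

#' Read a CT volume or lung mask from a NIfTI-1 file
#'
#' Spacing is taken from the stored transform (pixdim); the physical
#' origin from the translation column of the xform. Voxel values are
#' returned untouched.
#'
#' @param path Path to a `.nii`/`.nii.gz` file holding 3D data.
#' @param patient_id Patient identifier to attach; defaults to the file
#'   base name.
#' @return A `ct_volume`.
#' @export
read_volume <- function(path, patient_id = NULL) {
  assert_that(file.exists(path), "file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  assert_that(length(d) == 3, "expected 3D NIfTI data, got %dD in %s",
              length(d), path)
  spacing <- abs(RNifti::pixdim(img))
  assert_that(all(spacing > 0), "non-positive voxel spacing in %s", path)
  origin <- RNifti::xform(img)[1:3, 4]
  if (is.null(patient_id)) {
    patient_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  ct_volume(as.array(img), spacing = spacing, origin = origin,
            patient_id = patient_id)
}

#' Write a CT volume to a NIfTI-1 file
#'
#' @param vol A `ct_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  assert_that(inherits(vol, "ct_volume"), "vol must be a ct_volume")
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  aff <- diag(c(vol$spacing, 1))
  aff[1:3, 4] <- vol$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a lung mask from a NIfTI-1 file
#'
#' @param path Path to a `{0,1}` NIfTI mask.
#' @param kind `"mask"` or `"bounding_box"`.
#' @return A `lung_roi`.
#' @export
read_mask <- function(path, kind = "mask") {
  vol <- read_volume(path)
  lung_roi(vol$voxels != 0, kind = kind)
}

#' Write a lung mask to a NIfTI-1 file
#'
#' @param roi A `lung_roi`.
#' @param vol The companion `ct_volume` supplying the geometry.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(roi, vol, path) {
  check_companion(vol, roi)
  mvol <- ct_volume(array(as.integer(roi$mask), dim = dim(roi$mask)),
                    spacing = vol$spacing, origin = vol$origin,
                    patient_id = vol$patient_id)
  write_volume(mvol, path)
}

#' Image quality filter on acquisition resolution
#'
#' Excludes scans whose in-plane resolution exceeds 1 mm or whose slice
#' thickness (out-of-plane resolution) exceeds 10 mm. Comparisons are
#' strict, so boundary values (exactly 1 mm / 10 mm) are retained. For
#' anisotropic in-plane grids the in-plane resolution is summarized
#' conservatively as the larger of the two in-plane spacings.
#'
#' @param meta A data.frame with columns `patient_id`, `in_plane_mm`,
#'   `slice_mm` (one row per patient), or a single patient's values via
#'   `in_plane_mm`/`slice_mm`.
#' @param in_plane_mm,slice_mm Alternative scalar/vector interface when
#'   `meta` is NULL.
#' @param max_in_plane_mm,max_slice_mm Exclusion thresholds in mm.
#' @return A data.frame with columns `patient_id`, `eligible`, and a
#'   list-column `reasons` containing the violated rule identifiers
#'   (`"in_plane"`, `"slice"`); `eligible` is `TRUE` iff `reasons` is
#'   empty.
#' @export
qc_filter <- function(meta = NULL, in_plane_mm = NULL, slice_mm = NULL,
                      max_in_plane_mm = 1.0, max_slice_mm = 10.0) {
  if (is.null(meta)) {
    meta <- data.frame(patient_id = as.character(seq_along(in_plane_mm)),
                       in_plane_mm = in_plane_mm, slice_mm = slice_mm,
                       stringsAsFactors = FALSE)
  }
  assert_that(all(c("patient_id", "in_plane_mm", "slice_mm") %in%
                    names(meta)),
              "meta needs columns patient_id, in_plane_mm, slice_mm")
  ip <- meta$in_plane_mm
  sl <- meta$slice_mm
  assert_that(!anyNA(ip) && !anyNA(sl) && all(ip > 0) && all(sl > 0),
              "resolution values must be present and positive")
  reasons <- mapply(function(i, s) {
    r <- character(0)
    if (i > max_in_plane_mm) r <- c(r, "in_plane")
    if (s > max_slice_mm) r <- c(r, "slice")
    r
  }, ip, sl, SIMPLIFY = FALSE)
  out <- data.frame(patient_id = as.character(meta$patient_id),
                    eligible = lengths(reasons) == 0,
                    stringsAsFactors = FALSE)
  out$reasons <- reasons
  out
}

#' Clip CT intensities to a Hounsfield-unit range
#'
#' Intensity harmonization across scanners: gray values are saturated to
#' `[low, high]` HU (default `[-120, 300]`, the soft-tissue window used
#' for lung analysis). Clipped voxels are kept, not masked out; the
#' operation is idempotent.
#'
#' @param vol A `ct_volume`.
#' @param low,high Clip bounds in HU, `low < high`.
#' @return The clipped `ct_volume`; the applied range is recorded in
#'   `meta$clip_range`.
#' @export
clip_hu <- function(vol, low = -120, high = 300) {
  assert_that(inherits(vol, "ct_volume"), "vol must be a ct_volume")
  assert_that(is.numeric(low) && is.numeric(high) && low < high,
              "clip range requires low < high")
  vol$voxels[] <- pmin(high, pmax(low, vol$voxels))
  vol$meta$clip_range <- c(low, high)
  vol
}

# 1-based inclusive index ranges of the mask's tight bounding box,
# expanded by `margin` voxels and clamped to the grid.
roi_bounds <- function(mask, margin = 0) {
  idx <- which(mask, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, dim(mask))
  list(lo = as.integer(lo), hi = as.integer(hi))
}

#' Crop a volume and its ROI to the lung bounding box
#'
#' Returns the minimal axis-aligned sub-grid containing all foreground
#' voxels, expanded by `margin_voxels` on each side and clamped to the
#' grid; the mask is cropped identically and the physical origin is
#' shifted consistently.
#'
#' @param vol A `ct_volume`.
#' @param roi Companion `lung_roi`.
#' @param margin_voxels Non-negative integer margin.
#' @return A list with elements `vol` and `roi`.
#' @export
crop_to_roi <- function(vol, roi, margin_voxels = 0) {
  check_companion(vol, roi)
  assert_that(is.numeric(margin_voxels) && margin_voxels >= 0,
              "margin_voxels must be >= 0")
  b <- roi_bounds(roi$mask, as.integer(margin_voxels))
  vox <- vol$voxels[b$lo[1]:b$hi[1], b$lo[2]:b$hi[2], b$lo[3]:b$hi[3],
                    drop = FALSE]
  msk <- roi$mask[b$lo[1]:b$hi[1], b$lo[2]:b$hi[2], b$lo[3]:b$hi[3],
                  drop = FALSE]
  new_origin <- vol$origin + (b$lo - 1) * vol$spacing
  list(vol = ct_volume(vox, spacing = vol$spacing, origin = new_origin,
                       patient_id = vol$patient_id, meta = vol$meta),
       roi = lung_roi(msk, kind = roi$kind))
}
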