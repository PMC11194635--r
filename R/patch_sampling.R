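# Uniform sampling of fixed-physical-size 3D patches from the lung
# region of a harmonized CT volume.

#' Sampling configuration for whole-lung patches
#'
#' Defaults follow the study design: 80 patches per patient, each a cube
#' of 5 cm^3 volume in physical space (edge length 5^(1/3) cm ~ 17.1
#' mm). The alternate reading of "5 cm" as the edge length is a single
#' configuration change (`patch_edge_mm = 50`).
#'
#' @param n_patches Number of patches per patient (>= 1).
#' @param patch_edge_mm Physical edge length of the cubic patch in mm.
#' @param center_domain Where patch centers may fall: `"mask"`
#'   (voxel-wise lung mask) or `"bounding_box"`; `"auto"` uses the mask
#'   when the ROI is a true mask and the box otherwise.
#' @param allow_overlap Patches may overlap (they are sampled by center
#'   without replacement, not packed).
#' @param seed Integer seed for the patch-center draw.
#' @return A `sampling_config` list.
#' @export
sampling_config <- function(n_patches = 80,
                            patch_edge_mm = 10 * 5^(1 / 3),
                            center_domain = c("auto", "mask",
                                              "bounding_box"),
                            allow_overlap = TRUE, seed = 1L) {
  center_domain <- match.arg(center_domain)
  assert_that(is_count(n_patches), "n_patches must be a positive integer")
  assert_that(is.numeric(patch_edge_mm) && patch_edge_mm > 0,
              "patch_edge_mm must be > 0")
  structure(list(n_patches = as.integer(n_patches),
                 patch_edge_mm = patch_edge_mm,
                 center_domain = center_domain,
                 allow_overlap = isTRUE(allow_overlap),
                 seed = as.integer(seed)),
            class = "sampling_config")
}

#' Convert a physical patch edge to per-axis voxel counts
#'
#' Per axis, the voxel count is `round(edge_mm / spacing_axis)` floored
#' at 2, so a patch always has at least one voxel pair along every axis
#' on anisotropic grids (e.g. thick-slice CT).
#'
#' @param spacing Voxel spacing in mm (length 3).
#' @param edge_mm Physical edge length in mm.
#' @return Integer length-3 voxel counts.
#' @export
patch_shape_voxels <- function(spacing, edge_mm) {
  assert_that(all(spacing > 0) && edge_mm > 0,
              "spacing and edge_mm must be positive")
  pmax(2L, as.integer(round(edge_mm / spacing)))
}

# Patch placement is half-open: a patch of size n centered at c (1-based)
# occupies indices [c - floor(n/2), c - floor(n/2) + n - 1].
patch_start <- function(center, shape) center - shape %/% 2L

#' Enumerate valid patch centers inside an ROI
#'
#' A center is valid when it is foreground in the requested domain and
#' the full patch around it fits inside the grid.
#'
#' @param roi A `lung_roi`.
#' @param shape_voxels Integer length-3 patch shape.
#' @param center_domain `"mask"` or `"bounding_box"`.
#' @return Integer matrix with one row per valid center (1-based i,j,k);
#'   zero rows when no placement fits.
#' @export
valid_centers <- function(roi, shape_voxels,
                          center_domain = c("mask", "bounding_box")) {
  center_domain <- match.arg(center_domain)
  assert_that(inherits(roi, "lung_roi"), "roi must be a lung_roi")
  d <- dim(roi$mask)
  shape <- as.integer(shape_voxels)
  # a patch starts at c - floor(n/2) and spans n voxels, so feasible
  # centers are c in [floor(n/2) + 1, d - n + floor(n/2) + 1] (1-based)
  lo <- shape %/% 2L + 1L
  hi <- d - shape + shape %/% 2L + 1L
  if (any(hi < lo)) {
    return(matrix(integer(0), ncol = 3,
                  dimnames = list(NULL, c("i", "j", "k"))))
  }
  domain <- roi$mask
  if (center_domain == "bounding_box") {
    b <- roi_bounds(roi$mask, 0)
    domain <- array(FALSE, dim = d)
    domain[b$lo[1]:b$hi[1], b$lo[2]:b$hi[2], b$lo[3]:b$hi[3]] <- TRUE
  }
  fits <- array(FALSE, dim = d)
  fits[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  centers <- which(domain & fits, arr.ind = TRUE)
  colnames(centers) <- c("i", "j", "k")
  centers
}

#' Uniformly sample 3D patches from the lung region
#'
#' Draws `cfg$n_patches` patch centers uniformly at random from the
#' valid centers, without replacement when enough distinct centers
#' exist, otherwise with replacement (with a warning). Identical inputs
#' and seed give an identical patch list, order included.
#'
#' @param vol Harmonized, cropped `ct_volume`.
#' @param roi Companion `lung_roi`.
#' @param cfg A [sampling_config()].
#' @return List of `patch` objects, each with elements `voxels`,
#'   `center_voxel`, `center_mm`, `shape_voxels`, `patient_id`,
#'   `patch_index`.
#' @export
sample_patches <- function(vol, roi, cfg = sampling_config()) {
  check_companion(vol, roi)
  shape <- patch_shape_voxels(vol$spacing, cfg$patch_edge_mm)
  domain <- cfg$center_domain
  if (domain == "auto") {
    domain <- if (roi$kind == "mask") "mask" else "bounding_box"
  }
  centers <- valid_centers(roi, shape, domain)
  if (nrow(centers) == 0) {
    stopf("no valid %s-voxel patch placement for patient %s",
          paste(shape, collapse = "x"), vol$patient_id)
  }
  n <- cfg$n_patches
  idx <- with_seed(cfg$seed, {
    if (nrow(centers) >= n) {
      sample.int(nrow(centers), n, replace = FALSE)
    } else {
      warnf("patient %s: only %d valid centers for %d patches; sampling with replacement",
            vol$patient_id, nrow(centers), n)
      sample.int(nrow(centers), n, replace = TRUE)
    }
  })
  lapply(seq_len(n), function(p) {
    ctr <- centers[idx[p], ]
    st <- patch_start(ctr, shape)
    en <- st + shape - 1L
    structure(list(
      voxels = vol$voxels[st[1]:en[1], st[2]:en[2], st[3]:en[3],
                          drop = FALSE],
      center_voxel = unname(ctr),
      center_mm = unname(vol$origin + (ctr - 1) * vol$spacing),
      shape_voxels = unname(shape),
      patient_id = vol$patient_id,
      patch_index = p), class = "patch")
  })
}

#' Tabulate a patch list as a manifest data.frame
#'
#' @param patches List of `patch` objects from [sample_patches()].
#' @param seed Seed recorded alongside (for provenance).
#' @return A data.frame with one row per patch: identifiers, voxel and
#'   physical centers, and shape.
#' @export
patch_manifest <- function(patches, seed = NA_integer_) {
  do.call(rbind, lapply(patches, function(p) {
    data.frame(patient_id = p$patient_id, patch_index = p$patch_index,
               center_i = p$center_voxel[1], center_j = p$center_voxel[2],
               center_k = p$center_voxel[3],
               center_x_mm = p$center_mm[1], center_y_mm = p$center_mm[2],
               center_z_mm = p$center_mm[3],
               nx = p$shape_voxels[1], ny = p$shape_voxels[2],
               nz = p$shape_voxels[3], seed = seed,
               stringsAsFactors = FALSE)
  }))
}
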