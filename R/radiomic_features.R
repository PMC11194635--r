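# Per-patch first-order and texture-matrix radiomic features (GLCM,
# GLRLM, GLSZM, GLDM, NGTDM), IBSI-style definitions on the quantized
# gray-level grid.
#
# Degenerate inputs are resolved explicitly so feature vectors never
# contain NaN/Inf: correlation is 0 when a marginal variance vanishes,
# busyness is 0 when its denominator vanishes, and coarseness saturates
# at 1e6 on perfectly flat patches (its supremum stand-in).

COARSENESS_MAX <- 1e6

#' Gray-level quantization configuration
#'
#' Defaults quantize with a fixed bin width of 25 HU anchored at the
#' clip floor (-120 HU), giving the same `N_g = 17` level set for every
#' patch and patient under the default `[-120, 300]` clip range; this
#' keeps texture features comparable across the cohort.
#' `fixed_bin_count` instead spreads `n_bins` equal-width bins over each
#' patch's own intensity range.
#'
#' @param mode `"fixed_bin_width"` or `"fixed_bin_count"`.
#' @param bin_width Bin width in HU (fixed_bin_width mode).
#' @param n_bins Number of bins (fixed_bin_count mode), >= 2.
#' @param anchor Left edge of bin 1 in HU (fixed_bin_width mode).
#' @param clip_range Intensity range spanned by the level set; defines
#'   `N_g` in fixed_bin_width mode.
#' @return A `quantization_config` list.
#' @export
quantization_config <- function(mode = c("fixed_bin_width",
                                         "fixed_bin_count"),
                                bin_width = 25, n_bins = 16,
                                anchor = -120, clip_range = c(-120, 300)) {
  mode <- match.arg(mode)
  if (mode == "fixed_bin_width") {
    assert_that(bin_width > 0, "bin_width must be > 0")
  } else {
    assert_that(is_count(n_bins) && n_bins >= 2, "n_bins must be >= 2")
  }
  structure(list(mode = mode, bin_width = bin_width,
                 n_bins = as.integer(n_bins), anchor = anchor,
                 clip_range = clip_range),
            class = "quantization_config")
}

#' Quantize a patch to integer gray levels
#'
#' Fixed bin width: `level(v) = floor((v - anchor)/bin_width) + 1`,
#' capped to the `N_g` bins spanning the clip range (the top edge of the
#' range falls in the last bin). Fixed bin count: `n_bins` equal-width
#' bins over the patch's own `[min, max]`; a constant patch maps to a
#' single level.
#'
#' @param patch A `patch` (or plain 3D numeric array).
#' @param cfg A [quantization_config()].
#' @return A `quantized_patch` with integer array `levels` in
#'   `1..n_levels`, `n_levels`, and the source patch.
#' @export
quantize <- function(patch, cfg = quantization_config()) {
  vox <- if (inherits(patch, "patch")) patch$voxels else patch
  assert_that(is.array(vox) && length(dim(vox)) == 3,
              "patch voxels must be a 3D array")
  if (cfg$mode == "fixed_bin_width") {
    ng <- as.integer(floor(diff(cfg$clip_range) / cfg$bin_width)) + 1L
    lv <- floor((vox - cfg$anchor) / cfg$bin_width) + 1
    lv <- pmin(pmax(lv, 1), ng)
  } else {
    ng <- cfg$n_bins
    rng <- range(vox)
    if (rng[1] == rng[2]) {
      lv <- array(1, dim = dim(vox))
    } else {
      w <- diff(rng) / ng
      lv <- pmin(floor((vox - rng[1]) / w) + 1, ng)
    }
  }
  structure(list(levels = array(as.integer(lv), dim = dim(vox)),
                 n_levels = ng, source = patch),
            class = "quantized_patch")
}

#' First-order intensity statistics of a patch
#'
#' Intensity statistics on the raw (harmonized) HU values, plus
#' histogram entropy (bits) and uniformity on the quantized levels.
#' Skewness and excess kurtosis use the population (bias-uncorrected)
#' moment definitions and are 0 for zero-variance patches.
#'
#' @param patch A `patch` or 3D numeric array.
#' @param qcfg Quantization used for the histogram features.
#' @return Named numeric vector with names `firstorder.*`.
#' @export
first_order_features <- function(patch, qcfg = quantization_config()) {
  v <- as.numeric(if (inherits(patch, "patch")) patch$voxels else patch)
  assert_that(length(v) > 0, "empty patch")
  m <- mean(v)
  dv <- v - m
  m2 <- mean(dv^2)
  skew <- if (m2 > 0) mean(dv^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean(dv^4) / m2^2 - 3 else 0
  q <- quantile(v, c(0.10, 0.25, 0.5, 0.75, 0.90), names = FALSE)
  lv <- quantize(patch, qcfg)$levels
  p <- tabulate(lv, nbins = max(lv)) / length(lv)
  p <- p[p > 0]
  c(firstorder.mean = m,
    firstorder.variance = m2,
    firstorder.skewness = skew,
    firstorder.kurtosis = kurt,
    firstorder.minimum = min(v),
    firstorder.maximum = max(v),
    firstorder.median = q[3],
    firstorder.p10 = q[1],
    firstorder.p90 = q[5],
    firstorder.iqr = q[4] - q[2],
    firstorder.energy = sum(v^2),
    firstorder.entropy = -sum(p * log2(p)),
    firstorder.uniformity = sum(p^2))
}

#' Gray-level co-occurrence matrices of a quantized patch
#'
#' Counts symmetrized level pairs at unit voxel offset along each of the
#' 13 unique 3D directions of the voxel lattice (no mm-distance
#' correction on anisotropic grids), normalized to probabilities.
#' Directions along which the patch is too thin to form any pair yield
#' an all-zero matrix and are excluded from feature averaging.
#'
#' @param q A `quantized_patch`.
#' @return List of `n_levels x n_levels` probability matrices, one per
#'   direction; each has attribute `"n_pairs"` (symmetrized pair count).
#' @export
glcm_matrices <- function(q) {
  assert_that(inherits(q, "quantized_patch"), "q must be a quantized_patch")
  counts <- cpp_glcm_counts(as.integer(q$levels), dim(q$levels),
                            q$n_levels)
  lapply(counts, function(M) {
    tot <- sum(M)
    P <- if (tot > 0) M / tot else M
    attr(P, "n_pairs") <- tot
    P
  })
}

# Feature formulas evaluated on one probability-normalized GLCM.
glcm_features_one <- function(P) {
  ng <- nrow(P)
  i <- seq_len(ng)
  D <- outer(i, i, "-")
  px <- rowSums(P)
  py <- colSums(P)
  mux <- sum(i * px); muy <- sum(i * py)
  sx <- sqrt(sum((i - mux)^2 * px)); sy <- sqrt(sum((i - muy)^2 * py))
  covxy <- sum(outer(i, i) * P) - mux * muy
  pp <- P[P > 0]
  c(glcm.contrast = sum(D^2 * P),
    glcm.joint_entropy = -sum(pp * log2(pp)),
    glcm.inverse_difference_moment = sum(P / (1 + D^2)),
    glcm.energy = sum(P^2),
    glcm.correlation = if (sx > 0 && sy > 0) covxy / (sx * sy) else 0)
}

#' GLCM features averaged over directions
#'
#' Contrast, joint entropy (bits), inverse difference moment, energy
#' (angular second moment), and correlation, each computed per direction
#' and averaged over the directions with nonzero pair mass.
#'
#' @param matrices Output of [glcm_matrices()].
#' @return Named numeric vector `glcm.*`.
#' @export
glcm_features <- function(matrices) {
  keep <- Filter(function(P) attr(P, "n_pairs") > 0, matrices)
  assert_that(length(keep) > 0, "no direction with a valid voxel pair")
  rowMeans(vapply(keep, glcm_features_one, numeric(5)))
}

glrlm_features <- function(q) {
  counts <- cpp_glrlm_counts(as.integer(q$levels), dim(q$levels),
                             q$n_levels)
  np <- length(q$levels)
  feats <- vapply(counts, function(R) {
    nr <- sum(R)
    l <- seq_len(ncol(R))
    rl <- colSums(R)   # runs per length
    rg <- rowSums(R)   # runs per gray level
    c(sum(rl / l^2) / nr,
      sum(rl * l^2) / nr,
      sum(rg^2) / nr,
      sum(rl^2) / nr,
      nr / np)
  }, numeric(5))
  stats::setNames(rowMeans(feats),
                  c("glrlm.short_run_emphasis", "glrlm.long_run_emphasis",
                    "glrlm.gray_level_nonuniformity",
                    "glrlm.run_length_nonuniformity",
                    "glrlm.run_percentage"))
}

glszm_features <- function(q) {
  Z <- cpp_glszm_zones(as.integer(q$levels), dim(q$levels))
  np <- length(q$levels)
  nz <- nrow(Z)
  s <- Z[, 2]
  g <- Z[, 1]
  zones_per_level <- tabulate(g, nbins = q$n_levels)
  c(glszm.small_area_emphasis = sum(1 / s^2) / nz,
    glszm.large_area_emphasis = sum(s^2) / nz,
    glszm.zone_percentage = nz / np,
    glszm.gray_level_nonuniformity = sum(zones_per_level^2) / nz)
}

gldm_features <- function(q, alpha = 0) {
  M <- cpp_gldm_counts(as.integer(q$levels), dim(q$levels), q$n_levels,
                       as.integer(alpha))
  nd <- sum(M)  # == number of voxels; every voxel has one dependence
  jj <- seq_len(ncol(M))
  dj <- colSums(M)
  c(gldm.small_dependence_emphasis = sum(dj / jj^2) / nd,
    gldm.large_dependence_emphasis = sum(dj * jj^2) / nd,
    gldm.dependence_nonuniformity = sum(dj^2) / nd)
}

ngtdm_features <- function(q) {
  res <- cpp_ngtdm(as.integer(q$levels), dim(q$levels), q$n_levels)
  s <- res$s
  n <- res$n
  N <- sum(n)
  p <- n / N
  i <- seq_along(p)
  act <- p > 0
  ngp <- sum(act)
  coarse_den <- sum(p * s)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else COARSENESS_MAX
  contrast <- if (ngp > 1) {
    (sum(outer(p[act], p[act]) * outer(i[act], i[act], "-")^2) /
       (ngp * (ngp - 1))) * (sum(s) / N)
  } else 0
  busy_den <- sum(abs(outer(i[act] * p[act], i[act] * p[act], "-")))
  busyness <- if (busy_den > 0) coarse_den / busy_den else 0
  c(ngtdm.coarseness = min(coarseness, COARSENESS_MAX),
    ngtdm.contrast = contrast,
    ngtdm.busyness = busyness)
}

#' Texture features for one matrix family
#'
#' GLRLM runs are counted per direction and the features averaged over
#' the 13 directions; GLSZM zones are 26-connected; GLDM uses dependence
#' threshold `alpha` (default 0) over the 26-neighborhood; NGTDM
#' differences are taken against the mean of the available 26-neighbors
#' (edge voxels use the neighbors that exist).
#'
#' @param q A `quantized_patch`.
#' @param family One of `"GLRLM"`, `"GLSZM"`, `"GLDM"`, `"NGTDM"`.
#' @param params Family parameters (`alpha` for GLDM).
#' @return Named numeric vector for the family.
#' @export
texture_family_features <- function(q, family, params = list()) {
  assert_that(inherits(q, "quantized_patch"), "q must be a quantized_patch")
  switch(family,
         GLRLM = glrlm_features(q),
         GLSZM = glszm_features(q),
         GLDM = gldm_features(q, alpha = params$alpha %||% 0),
         NGTDM = ngtdm_features(q),
         stopf("unknown texture family: %s", family))
}

#' Default per-patch feature specification
#'
#' The 33 features extracted by default: 13 first-order statistics and
#' 20 texture features across the five matrix families.
#'
#' @return Character vector of namespaced feature names.
#' @export
default_feature_spec <- function() {
  c(paste0("firstorder.",
           c("mean", "variance", "skewness", "kurtosis", "minimum",
             "maximum", "median", "p10", "p90", "iqr", "energy",
             "entropy", "uniformity")),
    paste0("glcm.",
           c("contrast", "joint_entropy", "inverse_difference_moment",
             "energy", "correlation")),
    paste0("glrlm.",
           c("short_run_emphasis", "long_run_emphasis",
             "gray_level_nonuniformity", "run_length_nonuniformity",
             "run_percentage")),
    paste0("glszm.",
           c("small_area_emphasis", "large_area_emphasis",
             "zone_percentage", "gray_level_nonuniformity")),
    paste0("gldm.",
           c("small_dependence_emphasis", "large_dependence_emphasis",
             "dependence_nonuniformity")),
    paste0("ngtdm.", c("coarseness", "contrast", "busyness")))
}

#' Extract the requested radiomic features from one patch
#'
#' Quantizes the patch and runs every family extractor needed by
#' `feature_spec`, returning exactly the requested features in the
#' requested order. All values are finite by construction.
#'
#' @param patch A `patch` or 3D numeric array.
#' @param qcfg A [quantization_config()].
#' @param feature_spec Character vector of feature names (see
#'   [default_feature_spec()]).
#' @param gldm_alpha Dependence threshold for GLDM.
#' @return Named numeric vector in `feature_spec` order.
#' @export
extract_patch_features <- function(patch, qcfg = quantization_config(),
                                   feature_spec = default_feature_spec(),
                                   gldm_alpha = 0) {
  assert_that(length(feature_spec) > 0, "feature_spec is empty")
  unknown <- setdiff(feature_spec, default_feature_spec())
  assert_that(length(unknown) == 0, "unknown feature name(s): %s",
              paste(unknown, collapse = ", "))
  fams <- unique(sub("\\..*$", "", feature_spec))
  q <- quantize(patch, qcfg)
  out <- numeric(0)
  if ("firstorder" %in% fams) {
    out <- c(out, first_order_features(patch, qcfg))
  }
  if ("glcm" %in% fams) out <- c(out, glcm_features(glcm_matrices(q)))
  if ("glrlm" %in% fams) {
    out <- c(out, texture_family_features(q, "GLRLM"))
  }
  if ("glszm" %in% fams) {
    out <- c(out, texture_family_features(q, "GLSZM"))
  }
  if ("gldm" %in% fams) {
    out <- c(out, texture_family_features(q, "GLDM",
                                          list(alpha = gldm_alpha)))
  }
  if ("ngtdm" %in% fams) {
    out <- c(out, texture_family_features(q, "NGTDM"))
  }
  out[feature_spec]
}
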