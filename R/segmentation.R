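#' Normalise intensities to a 0-100 per-subject percent scale
#'
#' Linearly rescales the image so that the minimum intensity inside the
#' brain mask maps to 0 and the maximum to 100; voxels outside the mask
#' are carried through the same linear transform (and may fall outside
#' 0-100). This puts every subject on a common percent-of-maximum scale,
#' with the maximum fixed at 100 for all subjects.
#'
#' With `robust = TRUE` the floor and ceiling are taken at the
#' `robust_limits` quantiles of the in-mask intensities instead of the
#' extremes, which stabilises the scale on noisy images (a handful of
#' extreme voxels no longer define it); values beyond the quantiles then
#' map slightly outside 0-100.
#'
#' @param image A [vol_image()].
#' @param brain_mask A `vol_mask` aligned with `image` (non-empty).
#' @param robust Use quantile limits instead of min/max.
#' @param robust_limits Length-2 probabilities for the robust floor and
#'   ceiling.
#' @return A `vol_image` on the percent scale.
#' @export
normalize_intensity <- function(image, brain_mask, robust = FALSE,
                                robust_limits = c(0.001, 0.999)) {
  stopifnot(inherits(image, "vol_image"), inherits(brain_mask, "vol_mask"))
  check_aligned(image, brain_mask, "image and brain mask")
  inb <- image$values[brain_mask$values]
  if (length(inb) == 0) stop("brain mask is empty", call. = FALSE)
  if (robust) {
    lim <- stats::quantile(inb, robust_limits, names = FALSE)
  } else {
    lim <- range(inb)
  }
  if (diff(lim) <= 0) {
    stop("cannot normalise: image is constant within the brain mask",
      call. = FALSE
    )
  }
  vol_image(
    (image$values - lim[1]) / (lim[2] - lim[1]) * 100,
    image$voxel_size, image$affine
  )
}

#' Threshold segmentation within a search mask
#'
#' Returns exactly the voxels of `search_mask` whose normalised
#' intensity lies in the closed interval
#' \[`min_percent`, `max_percent`\]. The upper bound defaults to 100
#' (the fixed per-subject maximum); the lower bound is the per-subject
#' operating point, chosen by the operator or suggested by
#' [suggest_min_percent()].
#'
#' @param image A normalised `vol_image` (0-100 percent scale).
#' @param search_mask `vol_mask` delimiting where lesions may exist.
#' @param min_percent,max_percent Closed threshold interval, 0-100,
#'   `min_percent <= max_percent`.
#' @return A `vol_mask` of segmented voxels.
#' @export
threshold_segment <- function(image, search_mask, min_percent,
                              max_percent = 100) {
  stopifnot(inherits(image, "vol_image"), inherits(search_mask, "vol_mask"))
  check_aligned(image, search_mask, "image and search mask")
  if (!is.numeric(min_percent) || !is.numeric(max_percent) ||
    min_percent < 0 || max_percent > 100 || min_percent > max_percent) {
    stop("need 0 <= min_percent <= max_percent <= 100", call. = FALSE)
  }
  if (!any(search_mask$values)) {
    warning("search mask is empty; returning an empty segmentation")
    return(vol_mask(array(FALSE, dim(image$values)), image$voxel_size,
      image$affine
    ))
  }
  sel <- search_mask$values &
    image$values >= min_percent & image$values <= max_percent
  vol_mask(sel, image$voxel_size, image$affine)
}

#' Suggest a per-subject minimum threshold
#'
#' Estimates the boundary between normal white matter and lesion
#' intensities inside `search_mask` with a fully deterministic robust
#' rule. Normal tissue dominates the mask, so its centre and scale are
#' estimated by the in-mask median and the MAD (scaled to be
#' consistent with a normal SD); lesion intensities are the values
#' more than 3 MAD above the centre, summarised by their median. The
#' suggested threshold is the midpoint between the two centres plus
#' 0.35 x the normal-tissue scale. The upward offset reflects the
#' asymmetric cost around the midpoint: normal tissue outnumbers
#' lesion tissue many-fold, so below the midpoint its noise tail
#' floods the segmentation with false-positive clusters, while above
#' it the only loss is a thin false-negative skin on lesion
#' boundaries; the offset size was calibrated on noisy phantoms with
#' known truth (see the package vignette). On a noise-free image the
#' scale is zero and the rule reduces to the exact class midpoint.
#'
#' Intended as a reproducible default for the per-subject minimum
#' threshold, which the original procedure chose interactively; always
#' overridable. The rule presumes hyperintense lesions are actually
#' present in the search mask; on a lesion-free image it degrades to
#' segmenting the upper noise tail (removed downstream by the
#' component-size filter).
#'
#' @param image A normalised `vol_image`.
#' @param search_mask `vol_mask` of candidate tissue.
#' @return Suggested `min_percent` (scalar).
#' @export
suggest_min_percent <- function(image, search_mask) {
  stopifnot(inherits(image, "vol_image"), inherits(search_mask, "vol_mask"))
  check_aligned(image, search_mask, "image and search mask")
  x <- image$values[search_mask$values]
  if (length(x) < 2 || diff(range(x)) == 0) {
    stop("cannot suggest a threshold: in-mask intensities are constant",
      call. = FALSE
    )
  }
  centre <- stats::median(x)
  scale <- stats::mad(x)
  hi <- x[x > centre + 3 * scale]
  if (length(hi) == 0) {
    return(min(centre + 3 * scale, max(x)))
  }
  (centre + stats::median(hi)) / 2 + 0.35 * scale
}

#' Scripted brush stroke
#'
#' A reproducible stand-in for one freehand brush gesture: a set of voxel
#' coordinates plus the spatial and intensity-range reach of the brush.
#'
#' @param label `"add"` or `"remove"`.
#' @param voxels Integer matrix, one row per stroke voxel, columns x,y,z
#'   (1-based voxel indices).
#' @param spatial_radius Spatial reach in mm (> 0).
#' @param range_width Intensity reach in image units (> 0).
#' @return An object of class `stroke`.
#' @export
stroke <- function(label = c("add", "remove"), voxels, spatial_radius,
                   range_width) {
  label <- match.arg(label)
  voxels <- matrix(as.integer(voxels), ncol = 3)
  if (nrow(voxels) == 0) stop("stroke has no voxels", call. = FALSE)
  stopifnot(spatial_radius > 0, range_width > 0)
  structure(
    list(
      label = label, voxels = voxels,
      spatial_radius = spatial_radius, range_width = range_width
    ),
    class = "stroke"
  )
}

#' Apply a brush stroke to a segmentation mask
#'
#' Emulates the 3D brush edit: each voxel receives a membership weight
#' that decreases linearly both with the Euclidean distance to the
#' nearest stroke voxel and with the absolute intensity difference from
#' the mean intensity under the stroke, clamped to zero beyond
#' `spatial_radius` / `range_width`:
#' \deqn{w = (1 - d / r_s)_+ \times (1 - |\Delta I| / r_I)_+}{
#'   w = max(0, 1 - d/rs) * max(0, 1 - |dI|/rI)}
#' Voxels with \eqn{w \ge 0.5} are added to (label `"add"`) or removed
#' from (label `"remove"`) the mask. The edit acts in full 3D across
#' slices; voxels farther than `spatial_radius` from every stroke voxel
#' are never touched.
#'
#' @param image The intensity `vol_image` the mask belongs to.
#' @param mask The `vol_mask` being edited.
#' @param stroke A [stroke()].
#' @return The edited `vol_mask`.
#' @export
paint <- function(image, mask, stroke) {
  stopifnot(
    inherits(image, "vol_image"), inherits(mask, "vol_mask"),
    inherits(stroke, "stroke")
  )
  check_aligned(image, mask, "image and mask")
  d <- dim(image$values)
  v <- stroke$voxels
  if (any(v < 1) || any(v[, 1] > d[1]) || any(v[, 2] > d[2]) ||
    any(v[, 3] > d[3])) {
    stop("stroke voxels fall outside the image grid", call. = FALSE)
  }
  stroke_mask <- array(FALSE, dim = d)
  stroke_mask[v] <- TRUE
  dist <- distance_to(vol_mask(stroke_mask, image$voxel_size))
  mean_int <- mean(image$values[stroke_mask])
  w_spatial <- pmax(0, 1 - dist / stroke$spatial_radius)
  w_range <- pmax(0, 1 - abs(image$values - mean_int) / stroke$range_width)
  sel <- (w_spatial * w_range) >= 0.5
  out <- if (stroke$label == "add") mask$values | sel else mask$values & !sel
  vol_mask(out, mask$voxel_size, mask$affine)
}

#' Segment the lateral ventricles by seeded region growing
#'
#' Grows a connected low-intensity (CSF) region from one seed per
#' ventricle: voxels join if they are connected to a seed through voxels
#' whose intensity lies within `tolerance` of the mean seed intensity.
#' Seed intensities are averaged over each seed's 3x3x3 neighbourhood so
#' a single noisy voxel does not shift the growth window. Each seed must
#' itself sit in CSF-like tissue (neighbourhood mean at most
#' `csf_ceiling`), otherwise an error names the offending seed. Growth
#' can be restricted to a brain mask.
#'
#' @param image A normalised `vol_image`.
#' @param seeds Integer matrix, one row per seed, columns x,y,z (1-based).
#' @param tolerance Intensity half-window around the mean seed intensity.
#' @param csf_ceiling Largest seed intensity accepted as CSF.
#' @param connectivity 6 or 26 (default).
#' @param brain_mask Optional `vol_mask` restricting growth.
#' @return A `vol_mask` containing the union of the grown regions.
#' @export
segment_ventricles <- function(image, seeds, tolerance = 15,
                               csf_ceiling = 35, connectivity = 26,
                               brain_mask = NULL) {
  stopifnot(inherits(image, "vol_image"))
  connectivity <- match_connectivity(connectivity)
  seeds <- matrix(as.integer(seeds), ncol = 3)
  d <- dim(image$values)
  if (any(seeds < 1) || any(seeds[, 1] > d[1]) || any(seeds[, 2] > d[2]) ||
    any(seeds[, 3] > d[3])) {
    stop("seed voxels fall outside the image grid", call. = FALSE)
  }
  # robust per-seed intensity: mean over the 3x3x3 neighbourhood
  seed_int <- vapply(seq_len(nrow(seeds)), function(i) {
    s <- seeds[i, ]
    mean(image$values[
      max(1, s[1] - 1):min(d[1], s[1] + 1),
      max(1, s[2] - 1):min(d[2], s[2] + 1),
      max(1, s[3] - 1):min(d[3], s[3] + 1)
    ])
  }, numeric(1))
  bad <- which(seed_int > csf_ceiling)
  if (length(bad) > 0) {
    stop(
      "seed ", bad[1], " at (", paste(seeds[bad[1], ], collapse = ", "),
      ") has intensity ", format(seed_int[bad[1]], digits = 4),
      ", above the CSF ceiling of ", csf_ceiling,
      call. = FALSE
    )
  }
  m <- mean(seed_int)
  allowed <- if (is.null(brain_mask)) {
    logical(0)
  } else {
    check_aligned(image, brain_mask, "image and brain mask")
    as.logical(brain_mask$values)
  }
  # grow from the full 3x3x3 neighbourhood of every seed so that a
  # single noisy voxel at the nominal seed cannot suppress a region
  starts <- do.call(rbind, lapply(seq_len(nrow(seeds)), function(i) {
    s <- seeds[i, ]
    as.matrix(expand.grid(
      max(1, s[1] - 1):min(d[1], s[1] + 1),
      max(1, s[2] - 1):min(d[2], s[2] + 1),
      max(1, s[3] - 1):min(d[3], s[3] + 1)
    ))
  }))
  grown <- cpp_region_grow(
    as.numeric(image$values), d, starts - 1L,
    m - tolerance, m + tolerance, connectivity, allowed
  )
  vol_mask(array(grown, dim = d), image$voxel_size, image$affine)
}

#' Remove the pencil-thin ependymal lining from a WMC segmentation
#'
#' A thin hyperintense rim along the ventricle surface is a normal
#' finding in the elderly and must not count as white matter change.
#' The rule works on distance-transform values from the ventricle
#' surface. Candidate voxels are WMC voxels that lie within
#' `max_thickness` of the surface and belong to a connected WMC
#' component touching it. Lesion "cores" are WMC voxels farther than
#' `max_thickness` from the surface, grouped into components of at
#' least `core_min_voxels` voxels (a size floor that keeps isolated
#' noise voxels from acting as cores). A candidate voxel is removed
#' unless it is anchored to a core: anchoring propagates outward from
#' the cores through the WMC mask itself for a bounded number of
#' one-voxel steps, so the basal and tapering edge layers of a thick
#' adjacent lesion (cap or halo) are retained voxel-for-voxel, while a
#' free-standing thin rim — which has no lesion path to any core — is
#' removed whole. Components
#' not touching the ventricles are never modified, and the output is
#' always a subset of the input mask.
#'
#' @param wmc `vol_mask` of segmented WMC.
#' @param ventricles `vol_mask` of the lateral ventricles.
#' @param max_thickness Largest rim thickness (mm) that is removed
#'   (> 0).
#' @param connectivity Component connectivity, 6 or 26 (default).
#' @param core_min_voxels Minimum component size (voxels) of
#'   beyond-`max_thickness` WMC that counts as a lesion core.
#' @return The cleaned `vol_mask`.
#' @export
remove_pencil_thin_lining <- function(wmc, ventricles, max_thickness,
                                      connectivity = 26,
                                      core_min_voxels = 10) {
  stopifnot(inherits(wmc, "vol_mask"), inherits(ventricles, "vol_mask"))
  check_aligned(wmc, ventricles, "WMC and ventricle masks")
  if (!is.numeric(max_thickness) || max_thickness <= 0) {
    stop("`max_thickness` must be > 0 (mm)", call. = FALSE)
  }
  connectivity <- match_connectivity(connectivity)
  if (!any(wmc$values)) {
    return(wmc)
  }
  d_v <- distance_to(ventricles)
  touch_tol <- sqrt(sum(wmc$voxel_size^2)) + 1e-9

  # connected WMC components touching the ventricle surface
  lab <- label_components(wmc, connectivity)
  labs <- lab[lab > 0L]
  min_d <- tapply(d_v[lab > 0L], labs, min)
  touching <- as.integer(names(min_d))[min_d <= touch_tol]
  thin <- wmc$values & d_v <= max_thickness &
    array(lab %in% touching, dim = dim(lab))
  if (!any(thin)) {
    return(wmc)
  }

  # cores: thick WMC components of at least core_min_voxels
  core <- wmc$values & d_v > max_thickness
  if (any(core)) {
    core_lab <- label_components(
      vol_mask(core, wmc$voxel_size), connectivity
    )
    sizes <- tabulate(core_lab[core_lab > 0L])
    core <- array(
      core_lab > 0L & sizes[pmax(core_lab, 1L)] >= core_min_voxels,
      dim = dim(core_lab)
    )
  }
  # anchoring: grow from the cores through the WMC mask itself for a
  # bounded number of one-voxel steps. The basal and tapering layers of
  # a thick lesion are geodesically contiguous with its core and become
  # anchored; a free-standing rim has no lesion path to any core and is
  # removed whole, whatever the Euclidean gap between them.
  anchored <- core
  if (any(core)) {
    steps <- as.integer(ceiling(max_thickness / min(wmc$voxel_size))) + 1L
    for (s in seq_len(steps)) {
      anchored <- wmc$values &
        distance_to(vol_mask(anchored, wmc$voxel_size)) <= touch_tol
    }
  }
  out <- wmc$values & !(thin & !anchored)
  vol_mask(out, wmc$voxel_size, wmc$affine)
}
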