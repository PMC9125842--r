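#' Build the periventricular (PVH) search mask
#'
#' The region where only periventricular hyperintensities can exist:
#' the ventricles dilated outward by `width_mm`, intersected with the
#' brain mask and with the ventricles themselves removed. Dilation is
#' done by thresholding the Euclidean distance transform, so it is
#' isotropic in millimetres even under anisotropic voxels. The mask is
#' monotone in `width_mm` (a larger width always yields a superset).
#'
#' @param ventricles `vol_mask` of the lateral ventricles.
#' @param brain_mask `vol_mask` of the cerebrum.
#' @param width_mm Dilation width in mm (>= 0); this is the per-subject
#'   parameter matching the observed width of the periventricular
#'   changes.
#' @return A `vol_mask`.
#' @export
build_pvh_mask <- function(ventricles, brain_mask, width_mm) {
  stopifnot(
    inherits(ventricles, "vol_mask"), inherits(brain_mask, "vol_mask"),
    is.numeric(width_mm), width_mm >= 0
  )
  check_aligned(ventricles, brain_mask, "ventricle and brain masks")
  if (width_mm == 0 || !any(ventricles$values)) {
    return(vol_mask(
      array(FALSE, dim(ventricles$values)),
      ventricles$voxel_size, ventricles$affine
    ))
  }
  d_v <- distance_to(ventricles)
  sel <- d_v > 0 & d_v <= width_mm & brain_mask$values
  vol_mask(sel, ventricles$voxel_size, ventricles$affine)
}

#' Partition WMC into PVH and DWMH with a PVH mask
#'
#' The default partition rule: WMC voxels inside the PVH mask are
#' periventricular, all remaining WMC voxels are deep. The two parts are
#' disjoint and their union is exactly the input, so volumes are
#' conserved by construction (deep volume = total minus periventricular).
#'
#' @param wmc `vol_mask` of white matter changes.
#' @param pvh_mask `vol_mask` from [build_pvh_mask()].
#' @return A list with `vol_mask` elements `pvh` and `dwmh`.
#' @export
partition_wmc <- function(wmc, pvh_mask) {
  stopifnot(inherits(wmc, "vol_mask"), inherits(pvh_mask, "vol_mask"))
  check_aligned(wmc, pvh_mask, "WMC and PVH masks")
  pvh <- wmc$values & pvh_mask$values
  dwmh <- wmc$values & !pvh_mask$values
  list(
    pvh = vol_mask(pvh, wmc$voxel_size, wmc$affine),
    dwmh = vol_mask(dwmh, wmc$voxel_size, wmc$affine)
  )
}

#' Partition WMC by the continuity-to-ventricle rule
#'
#' The widely used alternative definition: a whole connected WMC lesion
#' is periventricular if any of its voxels is adjacent (within the
#' chosen connectivity) to the ventricle surface, deep otherwise.
#' Confluent lesions that span both compartments are therefore assigned
#' entirely to PVH under this rule, while the mask rule splits them —
#' keeping both results supports agreement analyses between the rules.
#'
#' @param wmc `vol_mask` of white matter changes.
#' @param ventricles `vol_mask` of the lateral ventricles.
#' @param connectivity Adjacency/component connectivity, 6 or 26
#'   (default).
#' @return A list with `vol_mask` elements `pvh` and `dwmh`.
#' @export
continuity_partition <- function(wmc, ventricles, connectivity = 26) {
  stopifnot(inherits(wmc, "vol_mask"), inherits(ventricles, "vol_mask"))
  check_aligned(wmc, ventricles, "WMC and ventricle masks")
  connectivity <- match_connectivity(connectivity)
  empty <- function() {
    vol_mask(array(FALSE, dim(wmc$values)), wmc$voxel_size, wmc$affine)
  }
  if (!any(wmc$values)) {
    return(list(pvh = empty(), dwmh = empty()))
  }
  lab <- label_components(wmc, connectivity)
  d_v <- distance_to(ventricles)
  touch_tol <- if (connectivity == 26) {
    sqrt(sum(wmc$voxel_size^2)) + 1e-9
  } else {
    max(wmc$voxel_size) + 1e-9
  }
  labs <- lab[lab > 0L]
  min_d <- tapply(d_v[lab > 0L], labs, min)
  pvh_ids <- as.integer(names(min_d))[min_d <= touch_tol]
  pvh <- array(lab %in% pvh_ids & lab > 0L, dim = dim(wmc$values))
  list(
    pvh = vol_mask(pvh, wmc$voxel_size, wmc$affine),
    dwmh = vol_mask(wmc$values & !pvh, wmc$voxel_size, wmc$affine)
  )
}

#' Compartment volumes for one subject
#'
#' Applies a partition result and the ventricle mask to produce the
#' per-subject volume record: total WMC, PVH, DWMH and lateral-ventricle
#' volumes in ml (voxel counts times the single-voxel volume).
#'
#' @param wmc,ventricles `vol_mask` objects.
#' @param pvh_mask `vol_mask` from [build_pvh_mask()], or NULL to use
#'   the continuity rule.
#' @param connectivity Connectivity for the continuity rule.
#' @return A one-row tibble with columns `total_wmc_ml`, `pvh_ml`,
#'   `dwmh_ml`, `ventricles_ml`.
#' @export
lesion_volumes <- function(wmc, ventricles, pvh_mask = NULL,
                           connectivity = 26) {
  parts <- if (is.null(pvh_mask)) {
    continuity_partition(wmc, ventricles, connectivity)
  } else {
    partition_wmc(wmc, pvh_mask)
  }
  tibble::tibble(
    total_wmc_ml = volume_ml(wmc),
    pvh_ml = volume_ml(parts$pvh),
    dwmh_ml = volume_ml(parts$dwmh),
    ventricles_ml = volume_ml(ventricles)
  )
}

#' Full per-subject volumetry pipeline
#'
#' Runs the complete measurement chain on one FLAIR-like volume:
#' intensity normalisation, ventricle region growing from seeds,
#' threshold segmentation of hyperintense tissue inside the search
#' mask, removal of scattered small components and of the pencil-thin
#' ependymal lining, construction of the PVH mask, and partition into
#' PVH and DWMH.
#'
#' @param image Raw `vol_image`.
#' @param brain_mask `vol_mask` of the cerebrum (normalisation
#'   reference).
#' @param ventricle_seeds Integer matrix of seed voxels (x,y,z rows).
#' @param pvh_width_mm PVH mask width in mm.
#' @param search_mask Optional `vol_mask` delimiting where WMC are
#'   sought (defaults to `brain_mask`); pass a white-matter mask to
#'   emulate the operator's removal of hyperintense grey matter.
#' @param min_percent Minimum threshold (percent); NULL uses
#'   [suggest_min_percent()].
#' @param max_percent Maximum threshold (percent), default 100.
#' @param rim_max_thickness_mm Thickness limit for lining removal, mm.
#' @param min_component_voxels Small-component cleanup threshold
#'   (voxels); 0 disables.
#' @param method `"mask"` (default) or `"continuity"` partition rule.
#' @param grow_tolerance,csf_ceiling Passed to [segment_ventricles()].
#' @param connectivity 6 or 26.
#' @return A list: `volumes` (one-row tibble as [lesion_volumes()]),
#'   `masks` (wmc, pvh, dwmh, ventricles, pvh_mask), and the
#'   `min_percent` actually used.
#' @export
quantify_wmc <- function(image, brain_mask, ventricle_seeds, pvh_width_mm,
                         search_mask = NULL, min_percent = NULL,
                         max_percent = 100, rim_max_thickness_mm = 3,
                         min_component_voxels = 10,
                         method = c("mask", "continuity"),
                         grow_tolerance = 15, csf_ceiling = 35,
                         connectivity = 26) {
  method <- match.arg(method)
  if (is.null(search_mask)) search_mask <- brain_mask
  norm <- normalize_intensity(image, brain_mask)
  ventricles <- segment_ventricles(norm, ventricle_seeds,
    tolerance = grow_tolerance, csf_ceiling = csf_ceiling,
    connectivity = connectivity, brain_mask = brain_mask
  )
  if (is.null(min_percent)) {
    min_percent <- suggest_min_percent(norm, search_mask)
  }
  wmc <- threshold_segment(norm, search_mask, min_percent, max_percent)
  if (min_component_voxels > 0) {
    wmc <- filter_small_components(wmc, min_component_voxels, connectivity)
  }
  wmc <- remove_pencil_thin_lining(wmc, ventricles, rim_max_thickness_mm,
    connectivity
  )
  pvh_mask <- NULL
  if (method == "mask") {
    pvh_mask <- build_pvh_mask(ventricles, brain_mask, pvh_width_mm)
    parts <- partition_wmc(wmc, pvh_mask)
  } else {
    parts <- continuity_partition(wmc, ventricles, connectivity)
  }
  list(
    volumes = tibble::tibble(
      total_wmc_ml = volume_ml(wmc),
      pvh_ml = volume_ml(parts$pvh),
      dwmh_ml = volume_ml(parts$dwmh),
      ventricles_ml = volume_ml(ventricles)
    ),
    masks = list(
      wmc = wmc, pvh = parts$pvh, dwmh = parts$dwmh,
      ventricles = ventricles, pvh_mask = pvh_mask
    ),
    min_percent = min_percent
  )
}
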