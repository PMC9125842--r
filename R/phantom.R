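#' Specification of a FLAIR-like brain phantom
#'
#' Describes a synthetic 3D head: an ellipsoidal cerebrum with a thin
#' grey-matter ribbon, two ellipsoidal lateral ventricles filled with
#' CSF, a hyperintense periventricular halo restricted to a band around
#' the ventricle body, hyperintense caps attached to ventricle poles,
#' isolated deep white-matter lesions (spheres), and a pencil-thin
#' hyperintense ependymal rim along the exposed ventricle surface.
#' Every compartment is recorded as an exact voxel mask, so segmentation
#' results can be scored against known truth.
#'
#' Geometry notes: the rim is generated with a `rim_gap` clearance to the
#' halo band and the caps, so the truth compartments are distinct
#' connected components (real ependymal linings are confluent with
#' adjacent lesions; the idealisation is what makes voxel-exact scoring
#' possible). Deep lesions must stay clear of the dilated ventricle
#' region: each sphere is required to lie further than
#' `pvh_halo_width` + 2 voxels from the ventricle surface.
#'
#' @param grid_shape Integer length-3, grid size in voxels.
#' @param voxel_size Numeric length-3, voxel edge lengths in mm.
#' @param brain_axes Semi-axes (mm) of the cerebrum ellipsoid.
#' @param gm_thickness_frac Fraction of the brain radius occupied by the
#'   outer grey-matter ribbon.
#' @param ventricle_axes Semi-axes (mm) of each lateral ventricle.
#' @param ventricle_offset Centre of the right ventricle (mm, mirrored in
#'   x for the left).
#' @param pvh_halo_width Width (mm) of the periventricular halo.
#' @param halo_band_halfwidth Half-extent (mm) along y of the band around
#'   the ventricle body in which the halo exists.
#' @param cap_specs List of caps; each a list with `side` ("left"/"right"),
#'   `pole` ("anterior"/"posterior") and `radius` (mm).
#' @param dwmh_specs List of deep lesions; each a list with `center`
#'   (mm, world coordinates) and `radius` (mm).
#' @param rim_thickness Thickness of the ependymal rim in voxels.
#' @param rim_gap Clearance (mm) kept between the rim and the halo/caps.
#' @param intensity_means Named vector of tissue-class means: background,
#'   csf, white_matter, grey_matter, wmc.
#' @param noise_sd SD of additive Gaussian noise (intensity units).
#' @param seed Integer seed for the noise stream.
#' @return An object of class `phantom_spec` (a validated list).
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(grid_shape = c(80, 96, 80),
                         voxel_size = c(2, 2, 2),
                         brain_axes = c(65, 82, 60),
                         gm_thickness_frac = 0.06,
                         ventricle_axes = c(18, 50, 17),
                         ventricle_offset = c(22, 0, 2),
                         pvh_halo_width = 8,
                         halo_band_halfwidth = 6,
                         cap_specs = list(
                           list(side = "left", pole = "anterior", radius = 7),
                           list(side = "right", pole = "anterior", radius = 7)
                         ),
                         dwmh_specs = list(
                           list(center = c(0, -44, -30), radius = 6),
                           list(center = c(-2, 60, -20), radius = 6)
                         ),
                         rim_thickness = 1,
                         rim_gap = 6,
                         intensity_means = c(
                           background = 0, csf = 10, white_matter = 50,
                           grey_matter = 60, wmc = 90
                         ),
                         noise_sd = 0,
                         seed = 1L) {
  spec <- list(
    grid_shape = as.integer(grid_shape), voxel_size = as.numeric(voxel_size),
    brain_axes = as.numeric(brain_axes),
    gm_thickness_frac = gm_thickness_frac,
    ventricle_axes = as.numeric(ventricle_axes),
    ventricle_offset = as.numeric(ventricle_offset),
    pvh_halo_width = pvh_halo_width,
    halo_band_halfwidth = halo_band_halfwidth,
    cap_specs = cap_specs, dwmh_specs = dwmh_specs,
    rim_thickness = rim_thickness, rim_gap = rim_gap,
    intensity_means = intensity_means, noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    stopifnot(
      length(grid_shape) == 3, all(grid_shape >= 8),
      length(voxel_size) == 3, all(voxel_size > 0),
      all(brain_axes > 0), all(ventricle_axes > 0),
      pvh_halo_width > 0, halo_band_halfwidth > 0,
      rim_thickness > 0, rim_gap >= 0, noise_sd >= 0,
      gm_thickness_frac > 0, gm_thickness_frac < 1
    )
    im <- intensity_means
    needed <- c("background", "csf", "white_matter", "grey_matter", "wmc")
    if (!all(needed %in% names(im))) {
      stop("intensity_means must name: ", paste(needed, collapse = ", "),
        call. = FALSE
      )
    }
    if (!(im["wmc"] > im["white_matter"] && im["white_matter"] > im["csf"])) {
      stop("intensity ordering violated: need wmc > white_matter > csf",
        call. = FALSE
      )
    }
    fov_half <- grid_shape * voxel_size / 2
    if (any(brain_axes > fov_half - voxel_size)) {
      stop("grid too small to contain the brain ellipsoid: semi-axes ",
        paste(brain_axes, collapse = "/"), " mm vs half field-of-view ",
        paste(fov_half, collapse = "/"), " mm",
        call. = FALSE
      )
    }
    if (any(abs(ventricle_offset) + ventricle_axes > brain_axes)) {
      stop("ventricles do not fit inside the brain ellipsoid", call. = FALSE)
    }
  })
  invisible(spec)
}

# world coordinate arrays (mm, grid-centred) for each axis of the grid
coord_arrays <- function(grid_shape, voxel_size) {
  n <- grid_shape
  cx <- (seq_len(n[1]) - (n[1] + 1) / 2) * voxel_size[1]
  cy <- (seq_len(n[2]) - (n[2] + 1) / 2) * voxel_size[2]
  cz <- (seq_len(n[3]) - (n[3] + 1) / 2) * voxel_size[3]
  list(
    x = array(rep(cx, times = n[2] * n[3]), dim = n),
    y = array(rep(rep(cy, each = n[1]), times = n[3]), dim = n),
    z = array(rep(cz, each = n[1] * n[2]), dim = n)
  )
}

ellipsoid_mask <- function(co, center, axes) {
  ((co$x - center[1]) / axes[1])^2 +
    ((co$y - center[2]) / axes[2])^2 +
    ((co$z - center[3]) / axes[3])^2 <= 1
}

# nearest voxel index (1-based) of a world coordinate
world_to_voxel <- function(pt, grid_shape, voxel_size) {
  as.integer(round(pt / voxel_size + (grid_shape + 1) / 2))
}

#' Phantom spec with seeded between-subject geometry variation
#'
#' Real cohorts vary anatomically; a family of phantoms emulates that
#' by scaling the ventricle axes, halo width and cap radii of a base
#' spec with seeded multiplicative jitter. Truth volumes then differ
#' between subjects while every phantom remains exactly scored.
#'
#' @param seed Integer seed (also used for the phantom's noise stream).
#' @param jitter Relative half-range of the scaling factors.
#' @param ... Overrides passed to [phantom_spec()] after jittering.
#' @return A `phantom_spec`.
#' @export
jittered_phantom_spec <- function(seed, jitter = 0.08, ...) {
  jit <- withr::with_seed(
    as.integer(seed), stats::runif(3, 1 - jitter, 1 + jitter)
  )
  base <- formals(phantom_spec)
  caps <- eval(base$cap_specs)
  caps <- lapply(caps, function(cp) {
    cp$radius <- cp$radius * jit[3]
    cp
  })
  args <- override_list(
    list(
      seed = as.integer(seed),
      ventricle_axes = eval(base$ventricle_axes) * jit[1],
      pvh_halo_width = eval(base$pvh_halo_width) * jit[2],
      cap_specs = caps
    ),
    list(...)
  )
  do.call(phantom_spec, args)
}

#' Generate a FLAIR-like phantom with exact ground truth
#'
#' Renders the geometry described by a [phantom_spec()] into a noisy
#' intensity volume plus voxel-exact truth masks for every compartment.
#' Truth volumes are exact voxel counts times the single-voxel volume.
#' The same spec (including `seed`) always yields bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements
#'   * `image`: the `vol_image`,
#'   * `truth`: a list of `vol_mask` objects (`ventricle_mask`,
#'     `pvh_mask`, `dwmh_mask`, `rim_mask`, `wmc_mask` = PVH + DWMH,
#'     `hyper_mask` = every hyperintense voxel including the rim,
#'     `brain_mask`, `wm_mask`), the voxel coordinates
#'     `ventricle_seeds` (one row per
#'     ventricle centre), and `volumes`, a tibble of exact compartment
#'     volumes in ml.
#' @examples
#' ph <- generate_phantom(phantom_spec(
#'   grid_shape = c(48, 56, 48), brain_axes = c(40, 50, 38),
#'   ventricle_axes = c(10, 26, 9), ventricle_offset = c(13, 0, 0),
#'   pvh_halo_width = 6, halo_band_halfwidth = 5,
#'   cap_specs = list(list(side = "left", pole = "anterior", radius = 5)),
#'   dwmh_specs = list(list(center = c(0, -30, -16), radius = 4))
#' ))
#' ph$truth$volumes
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  n <- spec$grid_shape
  vx <- spec$voxel_size
  co <- coord_arrays(n, vx)
  im <- spec$intensity_means

  r2_brain <- ((co$x) / spec$brain_axes[1])^2 +
    ((co$y) / spec$brain_axes[2])^2 +
    ((co$z) / spec$brain_axes[3])^2
  brain <- r2_brain <= 1
  gm <- brain & r2_brain > (1 - spec$gm_thickness_frac)^2

  off <- spec$ventricle_offset
  centers <- list(
    right = c(off[1], off[2], off[3]),
    left = c(-off[1], off[2], off[3])
  )
  vent <- ellipsoid_mask(co, centers$right, spec$ventricle_axes) |
    ellipsoid_mask(co, centers$left, spec$ventricle_axes)
  vent <- vent & brain & !gm
  wm <- brain & !gm & !vent

  vmask <- vol_mask(vent, vx)
  d_v <- distance_to(vmask)

  # the halo hugs the outward-facing ventricle surface; the medial
  # region around the septum between the two ventricles carries no
  # lesion, excluded by a midline slab so the halo never degenerates
  # into sub-lining-thickness slivers at the exclusion boundary
  x_cut <- off[1] - spec$ventricle_axes[1] + spec$pvh_halo_width
  halo <- d_v > 0 & d_v <= spec$pvh_halo_width &
    abs(co$y - off[2]) <= spec$halo_band_halfwidth & wm &
    abs(co$x) >= x_cut

  caps <- array(FALSE, dim = n)
  for (cp in spec$cap_specs) {
    ctr <- centers[[cp$side]]
    pole <- ctr + c(0, if (cp$pole == "anterior") 1 else -1, 0) *
      spec$ventricle_axes[2]
    caps <- caps |
      (ellipsoid_mask(co, pole, rep(cp$radius, 3)) & wm)
  }
  pvh <- halo | caps

  rim_limit <- spec$rim_thickness * min(vx) * (1 + 1e-9)
  rim <- d_v > 0 & d_v <= rim_limit & wm
  if (any(pvh)) {
    d_pc <- distance_to(vol_mask(pvh, vx))
    rim <- rim & d_pc > spec$rim_gap
  }

  dwmh <- array(FALSE, dim = n)
  clearance <- spec$pvh_halo_width + 2 * max(vx)
  for (i in seq_along(spec$dwmh_specs)) {
    sp <- spec$dwmh_specs[[i]]
    sph <- ellipsoid_mask(co, sp$center, rep(sp$radius, 3))
    if (!any(sph)) {
      stop("deep lesion ", i, " lies outside the grid", call. = FALSE)
    }
    if (any(sph & !wm)) {
      stop("deep lesion ", i, " extends outside normal white matter",
        call. = FALSE
      )
    }
    min_d <- min(d_v[sph])
    if (min_d <= clearance) {
      stop(
        "deep lesion ", i, " violates non-adjacency: nearest distance to ",
        "the ventricle surface is ", format(min_d, digits = 4),
        " mm but must exceed the halo width plus 2 voxels (",
        format(clearance, digits = 4), " mm)",
        call. = FALSE
      )
    }
    dwmh <- dwmh | sph
  }

  wmc <- rim | pvh | dwmh

  values <- array(im[["background"]], dim = n)
  values[brain] <- im[["white_matter"]]
  values[gm] <- im[["grey_matter"]]
  values[vent] <- im[["csf"]]
  values[wmc] <- im[["wmc"]]
  if (spec$noise_sd > 0) {
    values <- values + withr::with_seed(
      spec$seed,
      array(stats::rnorm(prod(n), 0, spec$noise_sd), dim = n)
    )
  }

  seeds <- rbind(
    world_to_voxel(centers$right, n, vx),
    world_to_voxel(centers$left, n, vx)
  )

  masks <- list(
    ventricle_mask = vol_mask(vent, vx),
    pvh_mask = vol_mask(pvh, vx),
    dwmh_mask = vol_mask(dwmh, vx),
    rim_mask = vol_mask(rim, vx),
    wmc_mask = vol_mask(pvh | dwmh, vx),
    hyper_mask = vol_mask(wmc, vx),
    brain_mask = vol_mask(brain, vx),
    wm_mask = vol_mask(wm, vx)
  )
  vols <- tibble::tibble(
    compartment = c("total_wmc", "pvh", "dwmh", "ventricles", "rim"),
    ml = c(
      volume_ml(masks$wmc_mask), volume_ml(masks$pvh_mask),
      volume_ml(masks$dwmh_mask), volume_ml(masks$ventricle_mask),
      volume_ml(masks$rim_mask)
    )
  )
  list(
    image = vol_image(values, vx),
    truth = c(masks, list(ventricle_seeds = seeds, volumes = vols))
  )
}
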