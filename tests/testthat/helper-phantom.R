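# compact phantom (48 x 56 x 48 voxels @ 2 mm) used across imaging tests:
# same structure as the default geometry, scaled down for speed
small_phantom_spec <- function(...) {
  args <- wmcvol:::override_list(
    list(
      grid_shape = c(48, 56, 48), voxel_size = c(2, 2, 2),
      brain_axes = c(40, 50, 38), ventricle_axes = c(10, 26, 9),
      ventricle_offset = c(13, 0, 0),
      cap_specs = list(list(side = "left", pole = "anterior", radius = 5)),
      dwmh_specs = list(list(center = c(0, -30, -16), radius = 4)),
      pvh_halo_width = 6, halo_band_halfwidth = 5
    ),
    list(...)
  )
  do.call(phantom_spec, args)
}

# 1 mm fixture with a blunt ventricle, a pencil-thin rim and one 6 mm
# cap (no halo): the geometry for lining-removal contract tests
cap_rim_spec <- function(...) {
  phantom_spec(
    grid_shape = c(64, 72, 64), voxel_size = c(1, 1, 1),
    brain_axes = c(28, 32, 26), ventricle_axes = c(10, 12, 9),
    ventricle_offset = c(10, 0, 0),
    cap_specs = list(list(side = "right", pole = "anterior", radius = 6)),
    dwmh_specs = list(), pvh_halo_width = 4, halo_band_halfwidth = 0.1,
    rim_thickness = 1, rim_gap = 5,
    ...
  )
}

truth_ml <- function(ph, compartment) {
  v <- ph$truth$volumes
  v$ml[v$compartment == compartment]
}
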