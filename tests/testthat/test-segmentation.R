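test_that("normalisation rescales the in-mask range to 0-100", {
  arr <- array(0, c(3, 2, 2))
  arr[, 1, 1] <- c(10, 55, 100)
  img <- vol_image(arr, c(1, 1, 1))
  mask <- vol_mask(array(TRUE, c(3, 2, 2)), c(1, 1, 1))
  mask$values[, 2, ] <- FALSE
  mask$values[, , 2] <- FALSE
  out <- normalize_intensity(img, mask)
  expect_equal(out$values[, 1, 1], c(0, 50, 100))
  # out-of-mask voxels carried through the same linear transform
  expect_equal(out$values[1, 2, 1], (0 - 10) / 90 * 100)

  # an already 0-100 image is unchanged
  arr2 <- array(runif(27, 0, 100), c(3, 3, 3))
  arr2[1] <- 0
  arr2[27] <- 100
  img2 <- vol_image(arr2, c(1, 1, 1))
  full <- vol_mask(array(TRUE, c(3, 3, 3)), c(1, 1, 1))
  expect_equal(normalize_intensity(img2, full)$values, arr2)

  # constant image is degenerate
  expect_error(
    normalize_intensity(vol_image(array(5, c(3, 3, 3))), full),
    "constant"
  )
})

test_that("threshold segmentation honours the closed interval and mask", {
  set.seed(1)
  arr <- array(runif(5^3, 0, 100), c(5, 5, 5))
  img <- vol_image(arr, c(1, 1, 1))
  mask <- vol_mask(array(rep(c(TRUE, FALSE), length.out = 5^3), c(5, 5, 5)))
  # full range returns the search mask itself
  expect_identical(
    threshold_segment(img, mask, 0, 100)$values, mask$values
  )
  # min = max = 100 keeps only global-maximum voxels
  arr2 <- arr
  arr2[2, 2, 2] <- 100
  arr2[4, 4, 4] <- 100
  img2 <- vol_image(arr2)
  full <- vol_mask(array(TRUE, c(5, 5, 5)))
  top <- threshold_segment(img2, full, 100, 100)
  expect_identical(which(top$values), which(arr2 == 100))
  # empty search mask warns and returns empty
  empty <- vol_mask(array(FALSE, c(5, 5, 5)))
  expect_warning(res <- threshold_segment(img, empty, 50), "empty")
  expect_false(any(res$values))
  expect_error(threshold_segment(img, mask, 80, 60), "min_percent")
})

test_that("raising the minimum threshold never adds voxels", {
  set.seed(2)
  arr <- array(runif(6^3, 0, 100), c(6, 6, 6))
  img <- vol_image(arr)
  mask <- vol_mask(array(TRUE, c(6, 6, 6)))
  prev <- threshold_segment(img, mask, 0)
  for (cut in c(20, 40, 60, 80, 99)) {
    cur <- threshold_segment(img, mask, cut)
    expect_true(all(prev$values | !cur$values)) # cur subset of prev
    prev <- cur
  }
})

test_that("paint removes and adds tissue-consistent regions locally", {
  arr <- array(50, c(20, 20, 20))
  arr[8:12, 8:12, 8:12] <- 80 # uniform misclassified blob
  img <- vol_image(arr, c(1, 1, 1))
  blob <- vol_mask(arr > 70)
  st <- stroke("remove", matrix(c(10, 10, 10), ncol = 3),
    spatial_radius = 12, range_width = 10
  )
  # remove-stroke with radius >= blob diameter clears the whole blob
  expect_equal(sum(paint(img, blob, st)$values), 0)

  # other mask voxels are unchanged: full mask keeps everything outside
  # the blob's intensity class
  full <- vol_mask(array(TRUE, c(20, 20, 20)))
  removed <- paint(img, full, st)
  expect_identical(removed$values[arr == 50], full$values[arr == 50])

  # add-stroke with a narrow range only adds the stroke's tissue class
  st_add <- stroke("add", matrix(c(10, 10, 10), ncol = 3),
    spatial_radius = 12, range_width = 10
  )
  none <- vol_mask(array(FALSE, c(20, 20, 20)))
  added <- paint(img, none, st_add)
  expect_identical(added$values, arr > 70)

  # add then identical remove restores the prior state
  back <- paint(img, added, st)
  expect_identical(back$values, none$values)

  # locality: voxels beyond spatial_radius are never modified
  st_small <- stroke("remove", matrix(c(10, 10, 10), ncol = 3),
    spatial_radius = 3, range_width = 100
  )
  out <- paint(img, full, st_small)
  d <- wmcvol:::distance_to(vol_mask(
    array(seq_len(20^3) == (10 - 1) * 400 + (10 - 1) * 20 + 10, c(20, 20, 20))
  ))
  expect_identical(out$values[d > 3], full$values[d > 3])

  expect_error(
    stroke("add", matrix(numeric(0), ncol = 3), 5, 5), "no voxels"
  )
  expect_error(
    paint(img, full, stroke("add", matrix(c(25, 10, 10), ncol = 3), 5, 5)),
    "outside"
  )
})

test_that("ventricle region growing recovers CSF exactly at zero noise", {
  ph <- generate_phantom(small_phantom_spec())
  norm <- normalize_intensity(ph$image, ph$truth$brain_mask)
  seeds <- ph$truth$ventricle_seeds
  # both seeds: union of the two lateral ventricles, voxel-exact
  both <- segment_ventricles(norm, seeds)
  expect_identical(both$values, ph$truth$ventricle_mask$values)
  # one seed: just that ventricle (a strict, non-empty subset)
  one <- segment_ventricles(norm, seeds[1, , drop = FALSE])
  expect_true(all(ph$truth$ventricle_mask$values[one$values]))
  expect_lt(sum(one$values), sum(both$values))
  expect_gt(sum(one$values), 0)
  # the other seed gives the complement component
  other <- segment_ventricles(norm, seeds[2, , drop = FALSE])
  expect_identical(one$values | other$values, both$values)
  # a seed inside a lesion is rejected by name
  lesion_vox <- which(ph$truth$dwmh_mask$values, arr.ind = TRUE)[1, , drop = FALSE]
  expect_error(
    segment_ventricles(norm, lesion_vox), "above the CSF ceiling"
  )
})

test_that("pencil-thin lining removal clears the rim and keeps thick lesions", {
  ph <- generate_phantom(cap_rim_spec())
  hyper <- ph$truth$hyper_mask
  cleaned <- remove_pencil_thin_lining(
    hyper, ph$truth$ventricle_mask, max_thickness = 2
  )
  # rim removed entirely
  expect_false(any(cleaned$values & ph$truth$rim_mask$values))
  # the 6 mm cap is untouched, voxel for voxel
  expect_identical(cleaned$values, ph$truth$pvh_mask$values)
  # output is always a subset of the input
  expect_true(all(hyper$values[cleaned$values]))

  # no ventricle-touching voxels: identity
  far <- ph$truth$dwmh_mask
  far$values[] <- FALSE
  far$values[5:8, 5:8, 5:8] <- TRUE
  out <- remove_pencil_thin_lining(far, ph$truth$ventricle_mask, 2)
  expect_identical(out$values, far$values)

  # max_thickness beyond every adjacent structure removes it all
  small <- generate_phantom(small_phantom_spec())
  all_gone <- remove_pencil_thin_lining(
    small$truth$hyper_mask, small$truth$ventricle_mask,
    max_thickness = 30
  )
  expect_false(any(all_gone$values & small$truth$pvh_mask$values))
  expect_false(any(all_gone$values & small$truth$rim_mask$values))
  # deep lesions, not ventricle-adjacent, survive even then
  expect_identical(
    all_gone$values & small$truth$dwmh_mask$values,
    small$truth$dwmh_mask$values
  )

  expect_error(
    remove_pencil_thin_lining(hyper, ph$truth$ventricle_mask, 0),
    "max_thickness"
  )
})

test_that("the suggested threshold separates the classes on phantoms", {
  ph <- generate_phantom(small_phantom_spec())
  norm <- normalize_intensity(ph$image, ph$truth$brain_mask)
  cut <- suggest_min_percent(norm, ph$truth$wm_mask)
  expect_gt(cut, 50) # above normalised WM
  expect_lt(cut, 100) # below the lesion class
  seg <- threshold_segment(norm, ph$truth$wm_mask, cut)
  expect_identical(seg$values, ph$truth$hyper_mask$values)
})
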