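test_that("PVH mask construction: zero width, saturation, monotonicity", {
  ph <- generate_phantom(small_phantom_spec())
  vent <- ph$truth$ventricle_mask
  brain <- ph$truth$brain_mask
  expect_false(any(build_pvh_mask(vent, brain, 0)$values))
  # width beyond the brain diameter saturates at brain minus ventricles
  sat <- build_pvh_mask(vent, brain, 1000)
  expect_identical(sat$values, brain$values & !vent$values)
  # monotone in width
  prev <- build_pvh_mask(vent, brain, 2)
  for (w in c(5, 10, 20)) {
    cur <- build_pvh_mask(vent, brain, w)
    expect_true(all(cur$values[prev$values]))
    prev <- cur
  }
  # phantom contract: truth PVH inside the mask, truth DWMH outside
  m10 <- build_pvh_mask(vent, brain, 10)
  expect_true(all(m10$values[ph$truth$pvh_mask$values]))
  expect_false(any(m10$values & ph$truth$dwmh_mask$values))
  # misaligned masks are rejected
  other <- vol_mask(array(TRUE, c(10, 10, 10)))
  expect_error(build_pvh_mask(vent, other, 5), "not aligned")
})

test_that("mask partition is an exact disjoint split of the WMC", {
  ph <- generate_phantom(small_phantom_spec())
  wmc <- ph$truth$wmc_mask
  pvh_mask <- build_pvh_mask(
    ph$truth$ventricle_mask, ph$truth$brain_mask, 10
  )
  parts <- partition_wmc(wmc, pvh_mask)
  expect_false(any(parts$pvh$values & parts$dwmh$values))
  expect_identical(parts$pvh$values | parts$dwmh$values, wmc$values)
  # wmc entirely inside the mask: dwmh empty
  inside <- partition_wmc(ph$truth$pvh_mask, pvh_mask)
  expect_false(any(inside$dwmh$values))
  # empty pvh mask: everything deep
  none <- vol_mask(array(FALSE, dim(wmc$values)), wmc$voxel_size)
  flipped <- partition_wmc(wmc, none)
  expect_false(any(flipped$pvh$values))
  expect_identical(flipped$dwmh$values, wmc$values)
})

test_that("zero-noise end-to-end pipeline recovers truth voxel-exactly", {
  ph <- generate_phantom(small_phantom_spec())
  res <- quantify_wmc(
    ph$image, ph$truth$brain_mask, ph$truth$ventricle_seeds,
    pvh_width_mm = 10, search_mask = ph$truth$wm_mask
  )
  expect_identical(res$masks$pvh$values, ph$truth$pvh_mask$values)
  expect_identical(res$masks$dwmh$values, ph$truth$dwmh_mask$values)
  expect_identical(
    res$masks$ventricles$values, ph$truth$ventricle_mask$values
  )
  expect_equal(res$volumes$pvh_ml, truth_ml(ph, "pvh"))
  expect_equal(res$volumes$dwmh_ml, truth_ml(ph, "dwmh"))
})

test_that("continuity rule classifies by lesion-ventricle contact", {
  ph <- generate_phantom(small_phantom_spec())
  vent <- ph$truth$ventricle_mask
  # a lesion touching the ventricle is fully periventricular
  touching <- ph$truth$pvh_mask
  parts <- continuity_partition(touching, vent)
  expect_identical(parts$pvh$values, touching$values)
  expect_false(any(parts$dwmh$values))
  # a separated lesion is fully deep
  deep <- ph$truth$dwmh_mask
  parts2 <- continuity_partition(deep, vent)
  expect_identical(parts2$dwmh$values, deep$values)
  expect_false(any(parts2$pvh$values))
})

test_that("confluent lesions split under the mask rule but not continuity", {
  ph <- generate_phantom(small_phantom_spec())
  vent <- ph$truth$ventricle_mask
  brain <- ph$truth$brain_mask
  # bridge the halo to the deep lesion with a thin connecting track
  wmc <- ph$truth$wmc_mask
  bridge <- wmc$values
  # walk a straight voxel line between the nearest points of the
  # two compartments
  a <- which(ph$truth$pvh_mask$values, arr.ind = TRUE)
  b <- which(ph$truth$dwmh_mask$values, arr.ind = TRUE)
  mid_a <- a[which.min(rowSums((a - matrix(colMeans(b), nrow(a), 3,
    byrow = TRUE
  ))^2)), ]
  mid_b <- b[which.min(rowSums((b - matrix(mid_a, nrow(b), 3,
    byrow = TRUE
  ))^2)), ]
  steps <- max(abs(mid_b - mid_a)) + 1
  line <- sapply(1:3, function(k) {
    round(seq(mid_a[k], mid_b[k], length.out = steps))
  })
  bridge[line] <- TRUE
  confluent <- vol_mask(bridge, wmc$voxel_size)
  cont <- continuity_partition(confluent, vent)
  expect_false(any(cont$dwmh$values)) # everything periventricular
  pvh_mask <- build_pvh_mask(vent, brain, 10)
  masked <- partition_wmc(confluent, pvh_mask)
  expect_gt(volume_ml(masked$dwmh), 0) # mask rule still splits
  # both rules conserve volume exactly
  expect_equal(
    volume_ml(cont$pvh) + volume_ml(cont$dwmh), volume_ml(confluent)
  )
  expect_equal(
    volume_ml(masked$pvh) + volume_ml(masked$dwmh), volume_ml(confluent)
  )
})

test_that("volumes are voxel counts times voxel volume", {
  m1 <- vol_mask(array(TRUE, c(10, 10, 10)), c(1, 1, 1))
  expect_equal(volume_ml(m1), 1)
  m0 <- vol_mask(array(FALSE, c(4, 4, 4)), c(1, 1, 1))
  expect_equal(volume_ml(m0), 0)
  m2 <- vol_mask(array(TRUE, c(20, 10, 10)), c(0.5, 0.5, 1))
  expect_equal(volume_ml(m2), 0.5)
  # doubling every voxel dimension scales all volumes by 8
  ph <- generate_phantom(small_phantom_spec())
  v1 <- ph$truth$volumes$ml
  doubled <- vol_mask(
    ph$truth$pvh_mask$values, ph$truth$pvh_mask$voxel_size * 2
  )
  expect_equal(volume_ml(doubled), 8 * truth_ml(ph, "pvh"))
})
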