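test_that("the cohort generator is seed-deterministic", {
  a <- generate_cohort(cohort_spec(n = 60, seed = 21))
  b <- generate_cohort(cohort_spec(n = 60, seed = 21))
  expect_identical(a, b)
  c <- generate_cohort(cohort_spec(n = 60, seed = 22))
  expect_false(identical(a, c))
  # the generator must not disturb the caller's RNG stream
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_cohort(cohort_spec(n = 10, seed = 1)))
  expect_identical(runif(1), before)
})

test_that("noise-free limit: constant intercept becomes a constant delta", {
  spec <- cohort_spec(
    n = 40, seed = 2,
    baseline_total_mean = 50, baseline_total_sd = 4,
    baseline_volume_coef = c(pvh = 0, dwmh = 0, ventricles = 0),
    domain_missing = c(gait = 0, balance = 0, continence = 0, cognitive = 0),
    extra_post_missing = 0,
    delta_model = list(
      intercept = 5, log2_pvh = 0, log2_dwmh = 0, log2_ventricles = 0,
      age = 0, sex_male = 0, waiting_time = 0, pre_total = 0,
      evans_index = 0, desh = 0, resid_sd = 0, domain_sd = 0
    )
  )
  sc <- score_cohort(generate_cohort(spec))
  expect_equal(sc$delta_total, rep(5, 40), tolerance = 1e-9)
})

test_that("non-finite model parameters are rejected", {
  expect_error(
    cohort_spec(delta_model = list(
      intercept = NaN, log2_pvh = -1.2, log2_dwmh = 0,
      log2_ventricles = 0, age = 0, sex_male = 0, waiting_time = 0,
      pre_total = 0, evans_index = 0, desh = 0, resid_sd = 15,
      domain_sd = 8
    )),
    "non-finite"
  )
  expect_error(cohort_spec(n = 0))
})

test_that("baseline totals converge to the specified moments", {
  n <- 10000
  sc <- score_cohort(generate_cohort(cohort_spec(n = n, seed = 17)))
  tol_mean <- 3 * 19 / sqrt(n)
  tol_sd <- 3 * 19 / sqrt(2 * n)
  expect_lt(abs(mean(sc$pre_total) - 49.8), tol_mean)
  expect_lt(abs(stats::sd(sc$pre_total) - 19.0), tol_sd)
  # generated scores respect the instrument bounds
  doms <- as.matrix(sc[c(
    "gait_pre", "balance_pre", "continence_pre", "cognitive_pre",
    "gait_post", "balance_post", "continence_post", "cognitive_post"
  )])
  expect_true(all(doms >= 0 & doms <= 100, na.rm = TRUE))
  expect_true(all(sc$evans_index > 0.2 & sc$evans_index < 0.5))
  expect_true(all(sc$waiting_time_months >= 0))
  expect_true(all(sc$pvh_ml > 0 & sc$dwmh_ml > 0 & sc$ventricles_ml > 0))
  expect_equal(sc$total_wmc_ml, sc$pvh_ml + sc$dwmh_ml)
})

test_that("volume distributions match their log-normal anchors", {
  co <- generate_cohort(cohort_spec(n = 10000, seed = 31))
  # medians within a few percent of the anchor medians
  expect_equal(median(co$pvh_ml), 2^3.878, tolerance = 0.06)
  expect_equal(median(co$dwmh_ml), 2^0.766, tolerance = 0.08)
  expect_equal(mean(co$ventricles_ml), 129.7, tolerance = 0.03)
  # strong PVH-DWMH rank correlation as designed
  r <- spearman_corr(co, pvh_ml, dwmh_ml)$r_s
  expect_gt(r, 0.7)
  expect_lt(r, 0.82)
})

test_that("a refit on the generated table recovers the volume effect", {
  sc <- score_cohort(generate_cohort(cohort_spec(n = 250, seed = 77)))
  fit <- fit_outcome_model(sc, "delta_total", "pvh_ml", adjusted = TRUE)
  expect_lt(fit$conf_int[1], -1.2)
  expect_gt(fit$conf_int[2], -1.2)
})
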