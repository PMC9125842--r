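test_that("log2 transform adds columns and flags non-positive volumes", {
  co <- tibble::tibble(pvh_ml = c(8, 1, 0), dwmh_ml = c(2, 4, 8))
  expect_warning(out <- log2_volumes(co), "non-positive")
  expect_equal(out$log2_pvh_ml, c(3, 0, NA))
  expect_equal(out$log2_dwmh_ml, c(1, 2, 3))
  expect_equal(out$pvh_ml, co$pvh_ml) # originals retained
})

test_that("a residual-free cohort is fitted exactly", {
  set.seed(10)
  n <- 60
  co <- tibble::tibble(
    pvh_ml = 2^rnorm(n, 4, 1.5),
    age = rnorm(n, 75, 6), sex = sample(c("male", "female"), n, TRUE),
    waiting_time_months = runif(n, 2, 10),
    pre_total = runif(n, 20, 80), evans_index = runif(n, 0.3, 0.4),
    desh = rbinom(n, 1, 0.5)
  )
  co$delta_total <- 12 - 1.7 * log2(co$pvh_ml) + 0.2 * co$age -
    0.1 * co$pre_total
  fit <- suppressWarnings(fit_outcome_model(co, "delta_total", "pvh_ml"))
  expect_equal(fit$B, -1.7, tolerance = 1e-9)
  expect_equal(fit$n, n)
  # OLS residuals are orthogonal to every design column
  mm <- stats::model.matrix(fit$fit)
  expect_lt(max(abs(crossprod(mm, stats::resid(fit$fit)))), 1e-8)
})

test_that("rank-deficient designs fail with the collinear column named", {
  set.seed(12)
  co <- tibble::tibble(
    pvh_ml = 2^runif(30, 1, 5), delta_total = rnorm(30),
    age = rnorm(30, 70, 5), sex = sample(c("male", "female"), 30, TRUE),
    waiting_time_months = runif(30, 2, 10), pre_total = rnorm(30, 50, 10),
    evans_index = rep(0.35, 30), desh = rbinom(30, 1, 0.5)
  )
  expect_error(
    fit_outcome_model(co, "delta_total", "pvh_ml"), "evans_index"
  )
  # an exact linear copy of another column is also rejected
  co$evans_index <- runif(30, 0.3, 0.4)
  co$desh <- co$age * 2
  expect_error(
    fit_outcome_model(co, "delta_total", "pvh_ml"), "collinear"
  )
})

test_that("adjustment moves the estimate in the direction of the confounding", {
  # build confounding through the baseline score: larger PVH -> worse
  # baseline -> (through the pre-score term) larger apparent change,
  # with no direct volume effect
  spec <- cohort_spec(
    n = 400, seed = 13,
    baseline_volume_coef = c(pvh = -6, dwmh = 0, ventricles = 0),
    delta_model = list(
      intercept = 20, log2_pvh = 0, log2_dwmh = 0, log2_ventricles = 0,
      age = 0, sex_male = 0, waiting_time = 0, pre_total = -0.3,
      evans_index = 0, desh = 0, resid_sd = 6, domain_sd = 4
    )
  )
  sc <- score_cohort(generate_cohort(spec))
  unadj <- fit_outcome_model(sc, "delta_total", "pvh_ml", adjusted = FALSE)
  adj <- fit_outcome_model(sc, "delta_total", "pvh_ml", adjusted = TRUE)
  # unadjusted estimate absorbs the positive indirect path (-0.3 x -6)
  expect_gt(unadj$B, adj$B + 0.5)
  expect_lt(abs(adj$B), abs(unadj$B))
})

test_that("Mann-Whitney agrees with label-assignment enumeration", {
  cmp <- compare_groups(
    data.frame(x = 1:6, g = rep(c("a", "b"), each = 3)), x, g
  )
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 0.1)
  set.seed(6)
  for (i in 1:25) {
    m <- sample(2:5, 1)
    n <- sample(2:5, 1)
    vals <- sample(1000, m + n) / 7 # distinct values, no ties
    df <- data.frame(
      x = vals, g = rep(c("a", "b"), c(m, n))
    )
    got <- compare_groups(df, x, g)
    oracle <- mw_enum(vals[seq_len(m)], vals[m + seq_len(n)])
    expect_equal(got$statistic, oracle$u)
    expect_equal(got$p_value, oracle$p, tolerance = 1e-12)
  }
  # identical groups through the approximation path
  big <- data.frame(
    x = rep(c(1, 2, 3), 20), g = rep(c("a", "b"), 30)
  )
  expect_equal(compare_groups(big, x, g)$p_value, 1)
  expect_error(
    compare_groups(data.frame(x = 1:3, g = "a"), x, g), "two levels"
  )
})

test_that("Wilcoxon signed-rank agrees with sign-pattern enumeration", {
  co <- tibble::tibble(mmse_pre = c(10, 10, 10), mmse_post = c(11, 12, 13))
  got <- paired_change_tests(co, "mmse")
  expect_equal(got$p_value, 0.25)
  set.seed(7)
  for (i in 1:20) {
    k <- sample(3:8, 1)
    d <- sample(setdiff(-40:40, 0), k) / 4 # non-zero, untied |d|
    while (anyDuplicated(abs(d)) > 0) d <- sample(setdiff(-40:40, 0), k) / 4
    co2 <- tibble::tibble(mmse_pre = rep(0, k), mmse_post = d)
    got2 <- paired_change_tests(co2, "mmse")
    oracle <- wsr_enum(d)
    expect_equal(got2$statistic, oracle$v)
    expect_equal(got2$p_value, oracle$p, tolerance = 1e-12)
  }
  # degenerate inputs
  flat <- tibble::tibble(mmse_pre = c(5, 5), mmse_post = c(5, 5))
  expect_error(paired_change_tests(flat, "mmse"), "zero")
  const <- tibble::tibble(
    gait_pre = c(10, 20, 30), gait_post = c(15, 25, 35),
    balance_pre = 1, balance_post = 1,
    continence_pre = 1, continence_post = 1,
    cognitive_pre = 1, cognitive_post = 1
  )
  expect_error(
    paired_change_tests(score_cohort(const), "total", test = "t"),
    "degenerate"
  )
})

test_that("paired t-test is used for the total score", {
  sc <- score_cohort(generate_cohort(cohort_spec(n = 80, seed = 3)))
  res <- paired_change_tests(sc, "total")
  expect_match(res$method, "t-test")
  ref <- stats::t.test(sc$post_total, sc$pre_total, paired = TRUE)
  expect_equal(res$p_value, ref$p.value)
  expect_equal(res$estimate, mean(sc$delta_total))
})

test_that("Spearman matches the rank-difference formula and permutations", {
  got <- spearman_corr(data.frame(x = 1:3, y = c(3, 1, 2)), x, y)
  expect_equal(got$r_s, -0.5)
  set.seed(8)
  for (i in 1:15) {
    n <- sample(4:8, 1)
    x <- sample(100, n)
    y <- sample(100, n)
    got <- spearman_corr(data.frame(x = x, y = y), x, y)
    expect_equal(got$r_s, spearman_formula(x, y), tolerance = 1e-12)
  }
  # monotone sequences and reversals
  expect_equal(
    spearman_corr(data.frame(x = 1:9, y = (1:9)^3), x, y)$r_s, 1
  )
  expect_equal(
    spearman_corr(data.frame(x = 1:9, y = 9:1), x, y)$r_s, -1
  )
  # exact permutation p at small n
  for (i in 1:5) {
    x <- sample(50, 5)
    y <- sample(50, 5)
    got <- spearman_corr(data.frame(x = x, y = y), x, y)
    expect_equal(got$p_value, spearman_perm_p(x, y), tolerance = 1e-9)
  }
  expect_error(
    spearman_corr(data.frame(x = c(1, 1, 1), y = 1:3), x, y), "constant"
  )
})
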