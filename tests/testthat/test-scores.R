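test_that("total score is the gait-double-weighted mean of available domains", {
  expect_equal(total_inph_score(40, 64, 60, NA), 51)
  expect_equal(total_inph_score(100, 100, 100, 100), 100)
  expect_equal(total_inph_score(30, NA, NA, NA), 30)
  expect_error(total_inph_score(NA, NA, NA, NA), "at least one")
  expect_error(total_inph_score(120, 50, 50, 50), "0, 100")
  # permuting the non-gait domains leaves the total unchanged
  set.seed(3)
  for (i in 1:20) {
    s <- runif(4, 0, 100)
    expect_equal(
      total_inph_score(s[1], s[2], s[3], s[4]),
      total_inph_score(s[1], s[4], s[2], s[3])
    )
    # bounded and monotone
    tot <- total_inph_score(s[1], s[2], s[3], s[4])
    expect_gte(tot, 0)
    expect_lte(tot, 100)
    bump <- pmin(s + c(5, 0, 0, 0), 100)
    expect_gte(total_inph_score(bump[1], s[2], s[3], s[4]), tot)
  }
})

test_that("responder classification is inclusive at 5 points", {
  expect_true(classify_responder(5))
  expect_false(classify_responder(4.99))
  expect_false(classify_responder(-10))
  expect_error(classify_responder(NA), "missing")
  # any achievable baseline x <= 95 improved by 5 responds
  for (x in c(0, 20, 51.3, 95)) {
    expect_true(classify_responder((x + 5) - x))
  }
})

test_that("MMSE change categories follow the sign of the change", {
  expect_equal(mmse_change_category(24, 27), "improved")
  expect_equal(mmse_change_category(25, 25), "unchanged")
  expect_equal(mmse_change_category(28, 26), "reduced")
  expect_true(is.na(mmse_change_category(NA, 26)))
})

test_that("scoring computes per-time-point totals and deltas", {
  cohort <- tibble::tibble(
    gait_pre = c(40, 50, 30), balance_pre = c(64, 50, NA),
    continence_pre = c(60, 50, 60), cognitive_pre = c(NA, 50, 70),
    gait_post = c(52, 50, 30), balance_post = c(76, 50, NA),
    continence_post = c(72, 50, 60), cognitive_post = c(NA, NA, 70),
    mmse_pre = c(24, 25, 28), mmse_post = c(27, 25, 26)
  )
  sc <- score_cohort(cohort)
  expect_equal(sc$pre_total, c(51, 50, (60 + 60 + 70) / 4))
  expect_equal(sc$delta_total[1], 12)
  # identical pre/post: all deltas zero
  expect_equal(sc$delta_total[3], 0)
  expect_equal(sc$delta_gait[3], 0)
  # post cognition missing while pre has it: per-domain delta missing,
  # totals still computed on each time point's available domains
  expect_true(is.na(sc$delta_cognitive[2]))
  expect_equal(sc$post_total[2], 50)
  expect_equal(sc$delta_total[2], 0)
  expect_equal(sc$mmse_category, c("improved", "unchanged", "reduced"))
  # strict mode uses the common domain set at both time points
  st <- score_cohort(cohort, strict = TRUE)
  expect_equal(st$pre_total[2], 50)
  expect_equal(st$responder[1], TRUE)
})

test_that("exclusion filtering is a pure filter with a complete report", {
  reg <- generate_cohort(cohort_spec(
    n = 262, seed = 5, n_exclude_event = 6, n_exclude_artifact = 3
  ))
  res <- apply_exclusions(reg)
  expect_equal(nrow(res$cohort), 253)
  expect_equal(res$report$n[res$report$reason == "non-shunt event"], 6)
  expect_equal(res$report$n[res$report$reason == "artifact"], 3)
  # retained records are untouched
  kept_ids <- res$cohort$id
  expect_identical(
    res$cohort, reg[reg$id %in% kept_ids, , drop = FALSE]
  )
  # no flags: identity
  clean <- generate_cohort(cohort_spec(n = 20, seed = 5))
  expect_identical(apply_exclusions(clean)$cohort, clean)
  # all flagged: empty cohort, complete report
  allbad <- clean
  allbad$exclusion_reason <- "artifact"
  res2 <- apply_exclusions(allbad)
  expect_equal(nrow(res2$cohort), 0)
  expect_equal(res2$report$n[res2$report$reason == "artifact"], 20)
})

test_that("cohort summary reports the conventional statistics", {
  co <- score_cohort(generate_cohort(cohort_spec(
    n = 120, seed = 8, gait_velocity_n = 11
  )))
  s <- cohort_summary(co)
  expect_true(all(c("variable", "statistic", "value", "formatted", "n") %in%
    names(s)))
  age_row <- s[s$variable == "age", ]
  expect_equal(age_row$n, 120)
  # gait-velocity subgroup: paired medians and their difference
  gv <- s[s$variable == "gait_velocity_deterioration", ]
  expect_equal(gv$n, 11)
  m0 <- s$value[s$variable == "gait_velocity_t0"]
  m1 <- s$value[s$variable == "gait_velocity_t1"]
  expect_equal(gv$value, m0 - m1)
  # n = 1 degenerate cohort: SD missing, IQR collapses to the value
  one <- co[1, ]
  s1 <- cohort_summary(one)
  expect_match(s1$formatted[s1$variable == "pre_total"], "NA")
  mm <- s1[s1$variable == "mmse_pre", ]
  expect_equal(mm$value, one$mmse_pre)
})
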