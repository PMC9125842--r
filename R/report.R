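p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

delta_dependents <- c(
  "delta_total", "delta_balance", "delta_continence", "delta_gait",
  "delta_cognitive", "delta_mmse"
)
baseline_dependents <- c(
  "pre_total", "balance_pre", "continence_pre", "gait_pre",
  "cognitive_pre", "mmse_pre"
)

fit_row <- function(cohort, dependent, volume, ...) {
  fit_a <- fit_outcome_model(cohort, dependent, volume,
    adjusted = TRUE, ...
  )
  fit_u <- fit_outcome_model(cohort, dependent, volume,
    adjusted = FALSE, ...
  )
  tibble::tibble(
    dependent = dependent, volume = volume,
    B_unadjusted = fit_u$B, p_unadjusted = fit_u$p_value,
    stars_unadjusted = p_stars(fit_u$p_value),
    B_adjusted = fit_a$B, p_adjusted = fit_a$p_value,
    stars_adjusted = p_stars(fit_a$p_value),
    n = fit_a$n
  )
}

#' Full statistical report of a scored cohort
#'
#' Runs the complete analysis battery and collects it into four report
#' tables:
#' * `volumes_by_response`: PVH, DWMH and lateral-ventricle volumes in
#'   shunt responders vs non-responders (medians/IQRs, Mann-Whitney U);
#' * `delta_models`: unadjusted and covariate-adjusted linear
#'   regressions of each change score on each log2 volume;
#' * `baseline_models`: adjusted regressions of each baseline score on
#'   each log2 volume;
#' * `biomarker_models`: adjusted regressions of each (log2) CSF
#'   biomarker on each log2 volume — empty with a notice when the
#'   cohort carries no biomarkers.
#'
#' Significance is flagged `*` (p < 0.05) and `**` (p < 0.01). No
#' multiple-testing correction is applied anywhere (the analyses are
#' treated as pre-defined), and the report says so in `notes`.
#'
#' @param cohort A cohort tibble; scored on the fly if needed.
#' @param biomarker_log2 Model biomarker outcomes on the log2 scale.
#' @return An object of class `wmc_report`: a list of the four tibbles
#'   plus `correlation` (Spearman r_s between PVH and DWMH), `paired`
#'   (pre/post change tests) and `notes`.
#' @export
build_report <- function(cohort, biomarker_log2 = TRUE) {
  if (!"delta_total" %in% names(cohort)) cohort <- score_cohort(cohort)
  cohort <- log2_volumes(cohort)

  vols <- volume_choices
  t2 <- purrr::map_dfr(vols, function(v) {
    dplyr::mutate(
      compare_groups(cohort, !!rlang::sym(v), .data$responder),
      volume = v, .before = 1
    )
  })

  deps_d <- intersect(delta_dependents, names(cohort))
  t3 <- purrr::map_dfr(
    deps_d,
    function(d) purrr::map_dfr(vols, ~ fit_row(cohort, d, .x))
  )

  deps_b <- intersect(baseline_dependents, names(cohort))
  t4 <- purrr::map_dfr(deps_b, function(d) {
    purrr::map_dfr(vols, function(v) {
      fit <- fit_outcome_model(cohort, d, v, adjusted = TRUE)
      tibble::tibble(
        dependent = d, volume = v, B = fit$B, p_value = fit$p_value,
        stars = p_stars(fit$p_value), n = fit$n
      )
    })
  })

  bms <- intersect(biomarker_choices, names(cohort))
  bms <- bms[vapply(bms, function(b) any(!is.na(cohort[[b]])), logical(1))]
  if (length(bms) == 0) {
    t5 <- tibble::tibble(
      dependent = character(), volume = character(), B = numeric(),
      p_value = numeric(), stars = character(), n = integer()
    )
    t5_notice <- "no CSF biomarkers present in this cohort"
  } else {
    t5 <- purrr::map_dfr(bms, function(b) {
      purrr::map_dfr(vols, function(v) {
        fit <- fit_outcome_model(cohort, b, v,
          adjusted = TRUE, biomarker_log2 = biomarker_log2
        )
        tibble::tibble(
          dependent = b, volume = v, B = fit$B, p_value = fit$p_value,
          stars = p_stars(fit$p_value), n = fit$n
        )
      })
    })
    t5_notice <- NULL
  }

  corr <- spearman_corr(cohort, .data$log2_pvh_ml, .data$log2_dwmh_ml)
  paired_vars <- c(
    "total",
    if ("mmse_pre" %in% names(cohort)) "mmse",
    "gait", "balance", "continence", "cognitive"
  )
  paired <- purrr::map_dfr(
    paired_vars, ~ paired_change_tests(cohort, .x)
  )

  structure(
    list(
      volumes_by_response = t2,
      delta_models = t3,
      baseline_models = t4,
      biomarker_models = t5,
      correlation = corr,
      paired = paired,
      notes = c(
        "Significance flags: * p < 0.05, ** p < 0.01.",
        "No correction for multiple analyses was performed (pre-defined analyses).",
        "Volumes and CSF biomarkers are log2-transformed in all models.",
        t5_notice
      )
    ),
    class = "wmc_report"
  )
}

#' @export
print.wmc_report <- function(x, ...) {
  cat("== Volumes by shunt response (Mann-Whitney U) ==\n")
  print(x$volumes_by_response, n = Inf)
  cat("\n== Change-score regressions (per log2 volume) ==\n")
  print(x$delta_models, n = Inf)
  cat("\n== Baseline-score regressions ==\n")
  print(x$baseline_models, n = Inf)
  cat("\n== CSF biomarker regressions ==\n")
  print(x$biomarker_models, n = Inf)
  cat("\n== PVH-DWMH correlation ==\n")
  print(x$correlation)
  cat("\n== Paired pre/post change tests ==\n")
  print(x$paired, n = Inf)
  cat("\n", paste(x$notes, collapse = "\n"), "\n", sep = "")
  invisible(x)
}
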