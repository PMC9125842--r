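#' Total iNPH-scale score
#'
#' The 0-100 total symptom score: a weighted mean of the available
#' domain scores in which gait counts double and balance, continence and
#' cognition count once; the denominator is the summed weight of the
#' domains actually assessed. Vectorised over patients; missing domains
#' are simply left out of both numerator and denominator.
#'
#' @param gait,balance,continence,cognitive Domain scores (0-100 or NA).
#' @return Numeric vector of total scores.
#' @examples
#' total_inph_score(40, 64, 60, NA) # (80 + 64 + 60) / 4 = 51
#' @export
total_inph_score <- function(gait, balance, continence, cognitive) {
  m <- cbind(gait, balance, continence, cognitive)
  if (any(m < 0 | m > 100, na.rm = TRUE)) {
    stop("domain scores must lie in [0, 100]", call. = FALSE)
  }
  if (any(rowSums(!is.na(m)) == 0)) {
    stop("at least one domain score must be present", call. = FALSE)
  }
  w <- c(2, 1, 1, 1)
  wm <- matrix(w, nrow(m), 4, byrow = TRUE)
  wm[is.na(m)] <- 0
  rowSums(m * wm, na.rm = TRUE) / rowSums(wm)
}

# as total_inph_score(), but rows with no assessed domain give NA
# (a registry may lack an entire follow-up assessment)
total_score_or_na <- function(m) {
  out <- rep(NA_real_, nrow(m))
  ok <- rowSums(!is.na(m)) > 0
  if (any(ok)) {
    out[ok] <- total_inph_score(
      m[ok, 1], m[ok, 2], m[ok, 3], m[ok, 4]
    )
  }
  out
}

#' Classify shunt responders
#'
#' A patient is a shunt responder when the change in the total
#' iNPH-scale score (follow-up minus baseline) is at least 5 points;
#' the comparison is inclusive (a change of exactly 5 responds).
#'
#' @param delta_total Change in total score (no missing values).
#' @return Logical vector.
#' @export
classify_responder <- function(delta_total) {
  if (anyNA(delta_total)) {
    stop("delta_total contains missing values", call. = FALSE)
  }
  delta_total >= 5
}

#' Categorise MMSE (or total-score) change
#'
#' `improved` when post > pre, `unchanged` when equal, `reduced` when
#' post < pre; missing where either assessment is missing.
#'
#' @param pre,post Scores at baseline and follow-up.
#' @return Character vector: "improved", "unchanged", "reduced" or NA.
#' @export
mmse_change_category <- function(pre, post) {
  dplyr::case_when(
    is.na(pre) | is.na(post) ~ NA_character_,
    post > pre ~ "improved",
    post < pre ~ "reduced",
    TRUE ~ "unchanged"
  )
}

#' Score a cohort: totals, deltas, responder status
#'
#' Adds to a cohort table the baseline and follow-up total iNPH-scale
#' scores, per-domain and total changes, the MMSE change, responder
#' status (change >= 5) and the improved/unchanged/reduced categories
#' for both instruments.
#'
#' Each time point's total uses its own available domains (the scale is
#' defined over the domains assessed at that visit); with
#' `strict = TRUE` both totals are restricted to the domains available
#' at *both* time points, as a sensitivity analysis. Per-domain deltas
#' are missing whenever either assessment is missing.
#'
#' @param cohort Tibble with columns `gait_pre`, `balance_pre`,
#'   `continence_pre`, `cognitive_pre`, the `_post` counterparts, and
#'   optionally `mmse_pre` / `mmse_post`.
#' @param strict Require identical domain sets at both time points for
#'   the totals.
#' @return The cohort with columns `pre_total`, `post_total`,
#'   `delta_total`, `delta_gait`, `delta_balance`, `delta_continence`,
#'   `delta_cognitive`, `delta_mmse`, `responder`, `inph_category`,
#'   `mmse_category` added.
#' @export
score_cohort <- function(cohort, strict = FALSE) {
  doms <- c("gait", "balance", "continence", "cognitive")
  pre <- as.matrix(cohort[paste0(doms, "_pre")])
  post <- as.matrix(cohort[paste0(doms, "_post")])
  colnames(pre) <- colnames(post) <- doms
  if (strict) {
    both <- !is.na(pre) & !is.na(post)
    pre[!both] <- NA
    post[!both] <- NA
  }
  pre_total <- total_score_or_na(pre)
  post_total <- total_score_or_na(post)
  delta_total <- post_total - pre_total
  out <- dplyr::mutate(
    cohort,
    pre_total = pre_total,
    post_total = post_total,
    delta_total = delta_total,
    delta_gait = post[, "gait"] - pre[, "gait"],
    delta_balance = post[, "balance"] - pre[, "balance"],
    delta_continence = post[, "continence"] - pre[, "continence"],
    delta_cognitive = post[, "cognitive"] - pre[, "cognitive"],
    responder = dplyr::if_else(
      is.na(delta_total), NA, delta_total >= 5
    ),
    inph_category = mmse_change_category(pre_total, post_total)
  )
  if (all(c("mmse_pre", "mmse_post") %in% names(cohort))) {
    out <- dplyr::mutate(
      out,
      delta_mmse = .data$mmse_post - .data$mmse_pre,
      mmse_category = mmse_change_category(.data$mmse_pre, .data$mmse_post)
    )
  }
  out
}

#' Change scores between baseline and follow-up
#'
#' Convenience accessor returning just the signed change scores
#' (follow-up minus baseline) computed by [score_cohort()]: the total
#' iNPH-scale change (totals computed per time point before
#' differencing), the per-domain changes and the MMSE change.
#'
#' @inheritParams score_cohort
#' @return A tibble of `delta_*` columns, one row per patient.
#' @export
delta_scores <- function(cohort, strict = FALSE) {
  scored <- score_cohort(cohort, strict = strict)
  dplyr::select(scored, dplyr::starts_with("delta_"))
}

#' Apply registry exclusions
#'
#' Removes registry rows flagged for exclusion (any
#' `exclusion_reason != "none"`), leaving retained records untouched,
#' and reports the counts per reason.
#'
#' @param registry Tibble with an `exclusion_reason` column.
#' @return A list: `cohort` (retained rows) and `report` (tibble of
#'   `reason`, `n`, including a `"retained"` row).
#' @export
apply_exclusions <- function(registry) {
  stopifnot(nrow(registry) >= 1, "exclusion_reason" %in% names(registry))
  excluded <- registry$exclusion_reason != "none"
  report <- registry |>
    dplyr::filter(excluded) |>
    dplyr::count(.data$exclusion_reason, name = "n") |>
    dplyr::rename(reason = "exclusion_reason")
  report <- dplyr::bind_rows(
    report,
    tibble::tibble(reason = "retained", n = sum(!excluded))
  )
  list(cohort = registry[!excluded, , drop = FALSE], report = report)
}

fmt_num <- function(x, digits = 1) {
  formatC(x, format = "f", digits = digits)
}

#' Descriptive cohort summary
#'
#' Per-variable descriptive statistics in the conventional layout of a
#' baseline table: mean (SD) or mean (range) for approximately
#' symmetric variables, median (IQR) for skewed ones, n (%) for flags,
#' plus responder and improvement proportions and — when a
#' gait-velocity subgroup is present — the paired medians before and
#' immediately prior to surgery and their difference.
#'
#' @param cohort A scored cohort (see [score_cohort()]); unscored
#'   cohorts are scored on the fly.
#' @return A tibble with columns `variable`, `statistic`, `value`
#'   (numeric primary estimate), `formatted` and `n`.
#' @export
cohort_summary <- function(cohort) {
  stopifnot(nrow(cohort) >= 1)
  if (!"delta_total" %in% names(cohort)) {
    cohort <- score_cohort(cohort)
  }
  rows <- list()
  add <- function(variable, statistic, value, formatted, n) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      variable = variable, statistic = statistic, value = value,
      formatted = formatted, n = n
    )
  }
  mean_sd <- function(var, digits = 1) {
    x <- cohort[[var]]
    x <- x[!is.na(x)]
    s <- if (length(x) > 1) fmt_num(stats::sd(x), digits) else "NA"
    add(
      var, "mean (SD)", mean(x),
      paste0(fmt_num(mean(x), digits), " (", s, ")"), length(x)
    )
  }
  median_iqr <- function(var, digits = 1) {
    x <- cohort[[var]]
    x <- x[!is.na(x)]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    add(
      var, "median (IQR)", q[2],
      paste0(
        fmt_num(q[2], digits), " (", fmt_num(q[1], digits), "-",
        fmt_num(q[3], digits), ")"
      ), length(x)
    )
  }
  n_pct <- function(var, value = TRUE) {
    x <- cohort[[var]]
    x <- x[!is.na(x)]
    k <- sum(x == value)
    pct <- round(100 * k / length(x))
    add(
      var, "n (%)", 100 * k / length(x),
      paste0(k, " (", pct, "%)"), length(x)
    )
  }

  if ("age" %in% names(cohort)) {
    x <- cohort$age[!is.na(cohort$age)]
    add(
      "age", "mean (range)", mean(x),
      paste0(
        fmt_num(mean(x), 0), " (", fmt_num(min(x), 0), "-",
        fmt_num(max(x), 0), ")"
      ), length(x)
    )
  }
  if ("sex" %in% names(cohort)) {
    x <- cohort$sex[!is.na(cohort$sex)]
    k <- sum(x == "male")
    add(
      "male", "n (%)", 100 * k / length(x),
      paste0(k, " (", round(100 * k / length(x)), "%)"), length(x)
    )
  }
  for (v in c(
    "diabetes", "hyperlipidemia", "hypertension", "previous_ami",
    "previous_stroke", "aspirin", "anticoagulant", "desh"
  )) {
    if (v %in% names(cohort)) n_pct(v)
  }
  if ("pre_total" %in% names(cohort)) mean_sd("pre_total")
  for (v in c("gait_pre", "balance_pre", "continence_pre", "cognitive_pre")) {
    if (v %in% names(cohort)) mean_sd(v)
  }
  if ("mmse_pre" %in% names(cohort)) median_iqr("mmse_pre")
  if ("waiting_time_months" %in% names(cohort)) {
    median_iqr("waiting_time_months", 0)
  }
  for (v in c("pvh_ml", "dwmh_ml", "total_wmc_ml")) {
    if (v %in% names(cohort)) median_iqr(v)
  }
  if ("ventricles_ml" %in% names(cohort)) mean_sd("ventricles_ml")
  for (v in c("t_tau", "p_tau", "abeta42", "nfl")) {
    if (v %in% names(cohort)) median_iqr(v, 0)
  }
  if ("responder" %in% names(cohort)) n_pct("responder")
  for (inst in c("inph_category", "mmse_category")) {
    if (!inst %in% names(cohort)) next
    x <- cohort[[inst]]
    x <- x[!is.na(x)]
    for (cat in c("improved", "unchanged", "reduced")) {
      k <- sum(x == cat)
      add(
        paste0(inst, ":", cat), "n (%)", 100 * k / length(x),
        paste0(k, " (", round(100 * k / length(x)), "%)"), length(x)
      )
    }
  }
  if (all(c("gait_velocity_t0", "gait_velocity_t1") %in% names(cohort))) {
    ok <- !is.na(cohort$gait_velocity_t0) & !is.na(cohort$gait_velocity_t1)
    if (any(ok)) {
      m0 <- stats::median(cohort$gait_velocity_t0[ok])
      m1 <- stats::median(cohort$gait_velocity_t1[ok])
      add(
        "gait_velocity_t0", "median", m0, fmt_num(m0, 2), sum(ok)
      )
      add(
        "gait_velocity_t1", "median", m1, fmt_num(m1, 2), sum(ok)
      )
      add(
        "gait_velocity_deterioration", "difference of medians", m0 - m1,
        fmt_num(m0 - m1, 2), sum(ok)
      )
    }
  }
  dplyr::bind_rows(rows)
}
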