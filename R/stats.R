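#' Add log2-transformed volume columns
#'
#' Radiological volumes enter every statistical analysis
#' log2-transformed (a doubling of a volume changes the outcome by the
#' regression coefficient B). Originals are retained; non-positive
#' volumes cannot be transformed, are set to NA in the log2 columns
#' with a warning, and thereby drop out of complete-case model fits.
#'
#' @param cohort Cohort tibble.
#' @param volumes Volume columns to transform.
#' @return The cohort with `log2_<volume>` columns added.
#' @export
log2_volumes <- function(cohort,
                         volumes = c(
                           "pvh_ml", "dwmh_ml", "ventricles_ml",
                           "total_wmc_ml"
                         )) {
  volumes <- intersect(volumes, names(cohort))
  for (v in volumes) {
    x <- cohort[[v]]
    bad <- !is.na(x) & x <= 0
    if (any(bad)) {
      warning(
        sum(bad), " non-positive value(s) in `", v,
        "` flagged and excluded from log2 transform"
      )
      x[bad] <- NA_real_
    }
    cohort[[paste0("log2_", v)]] <- log2(x)
  }
  cohort
}

volume_choices <- c("pvh_ml", "dwmh_ml", "ventricles_ml")
biomarker_choices <- c("t_tau", "p_tau", "abeta42", "nfl")

delta_covariates <- c(
  "age", "sex", "waiting_time_months", "pre_total", "evans_index", "desh"
)
baseline_covariates <- c("age", "sex", "evans_index", "desh")

covariates_for <- function(dependent) {
  if (startsWith(dependent, "delta_")) {
    delta_covariates
  } else {
    # baseline symptom scores and CSF biomarkers share the same set
    baseline_covariates
  }
}

#' Linear regression of an outcome on one log2 volume
#'
#' Fits one ordinary-least-squares model per (outcome, volume) pair:
#' the outcome on the log2-transformed volume plus the covariate set
#' belonging to the outcome family. Change ("delta") scores are
#' adjusted for age, sex, waiting time between preoperative evaluation
#' and surgery, preoperative total score, Evans' index and DESH;
#' baseline scores and CSF biomarkers for age, sex, Evans' index and
#' DESH. Fits use complete cases, so `n` varies by outcome. Each
#' volume is fitted separately because the three volumes are strongly
#' inter-correlated.
#'
#' @param cohort A scored cohort (see [score_cohort()]); log2 columns
#'   are added if absent.
#' @param dependent Outcome column: a `delta_*` score, a baseline score
#'   (e.g. `pre_total`, `gait_pre`, `mmse_pre`) or a biomarker
#'   (`t_tau`, `p_tau`, `abeta42`, `nfl`).
#' @param volume One of `"pvh_ml"`, `"dwmh_ml"`, `"ventricles_ml"`.
#' @param adjusted Include the covariate set (TRUE) or fit the volume
#'   alone (FALSE).
#' @param covariates Optional explicit covariate override.
#' @param biomarker_log2 Model biomarker outcomes on the log2 scale
#'   (default TRUE, matching the transform applied to volumes).
#' @return An object of class `outcome_fit`: the underlying `lm` plus
#'   the headline quantities `B` (unstandardised coefficient of the
#'   log2 volume), `p_value` and `n`.
#' @export
fit_outcome_model <- function(cohort, dependent, volume,
                              adjusted = TRUE, covariates = NULL,
                              biomarker_log2 = TRUE) {
  volume <- match.arg(volume, volume_choices)
  if (!dependent %in% names(cohort)) {
    stop("no column `", dependent, "` in the cohort", call. = FALSE)
  }
  cohort <- log2_volumes(cohort, volume)
  vterm <- paste0("log2_", volume)
  covs <- if (!adjusted) {
    character(0)
  } else if (!is.null(covariates)) {
    covariates
  } else {
    covariates_for(dependent)
  }
  missing_covs <- setdiff(covs, names(cohort))
  if (length(missing_covs) > 0) {
    stop("cohort lacks covariate column(s): ",
      paste(missing_covs, collapse = ", "),
      call. = FALSE
    )
  }
  df <- cohort[, c(dependent, vterm, covs)]
  if (dependent %in% biomarker_choices && biomarker_log2) {
    y <- df[[dependent]]
    y[!is.na(y) & y <= 0] <- NA_real_
    df[[dependent]] <- log2(y)
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  if (n < length(covs) + 3) {
    stop("too few complete cases (", n, ") to fit `", dependent,
      "` on ", vterm,
      call. = FALSE
    )
  }
  rhs <- c(vterm, covs)
  degenerate <- rhs[vapply(
    df[rhs], function(col) length(unique(col)) < 2, logical(1)
  )]
  if (length(degenerate) > 0) {
    stop(
      "rank-deficient design; constant or collinear column(s): ",
      paste(degenerate, collapse = ", "),
      call. = FALSE
    )
  }
  fml <- stats::reformulate(rhs, response = dependent)
  fit <- stats::lm(fml, data = df)
  if (anyNA(stats::coef(fit))) {
    stop(
      "rank-deficient design; constant or collinear column(s): ",
      paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
        collapse = ", "
      ),
      call. = FALSE
    )
  }
  cf <- summary(fit)$coefficients
  structure(
    list(
      fit = fit, dependent = dependent, volume = volume, term = vterm,
      B = cf[vterm, "Estimate"], p_value = cf[vterm, "Pr(>|t|)"],
      conf_int = stats::confint(fit)[vterm, ],
      n = n, adjusted = adjusted, covariates = covs
    ),
    class = "outcome_fit"
  )
}

#' @export
print.outcome_fit <- function(x, ...) {
  cat(
    x$dependent, " ~ log2(", x$volume, ")",
    if (x$adjusted) paste0(" + ", length(x$covariates), " covariates"),
    ": B = ", format(x$B, digits = 4), ", p = ",
    format(x$p_value, digits = 3), ", n = ", x$n, "\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy an outcome model fit
#'
#' @param x An `outcome_fit` from [fit_outcome_model()].
#' @param ... Unused.
#' @return `tidy()`: the full coefficient table; `glance()`: a one-row
#'   tibble with the headline volume coefficient, its p-value, n and
#'   the model R^2.
#' @export
tidy.outcome_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    std.error = cf[, "Std. Error"],
    statistic = cf[, "t value"],
    p.value = cf[, "Pr(>|t|)"]
  )
}

#' @rdname tidy.outcome_fit
#' @export
glance.outcome_fit <- function(x, ...) {
  tibble::tibble(
    dependent = x$dependent, volume = x$volume, adjusted = x$adjusted,
    B = x$B, p_value = x$p_value, n = x$n,
    r.squared = summary(x$fit)$r.squared
  )
}

#' Compare a variable between two groups (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney U test with group medians and IQRs. The
#' exact null distribution is used when the combined sample size is at
#' most 20 and there are no ties; otherwise the normal approximation
#' with tie correction and continuity correction.
#'
#' @param cohort Cohort tibble.
#' @param variable Column to compare (tidy-eval).
#' @param group Two-level grouping column (tidy-eval); logical or
#'   factor-like.
#' @return One-row tibble with per-group n, median and IQR, the U
#'   statistic, the p-value and the test name.
#' @export
compare_groups <- function(cohort, variable, group) {
  x <- rlang::eval_tidy(rlang::enquo(variable), cohort)
  g <- rlang::eval_tidy(rlang::enquo(group), cohort)
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]
  g <- g[ok]
  levels_ <- sort(unique(g), decreasing = is.logical(g))
  if (length(levels_) != 2) {
    stop("`group` must have exactly two levels, got ",
      length(levels_),
      call. = FALSE
    )
  }
  xa <- x[g == levels_[1]]
  xb <- x[g == levels_[2]]
  if (length(xa) == 0 || length(xb) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  has_ties <- anyDuplicated(x) > 0
  exact <- (length(x) <= 20) && !has_ties
  ht <- suppressWarnings(stats::wilcox.test(
    xa, xb,
    exact = exact, correct = !exact
  ))
  qa <- stats::quantile(xa, c(0.25, 0.5, 0.75), names = FALSE)
  qb <- stats::quantile(xb, c(0.25, 0.5, 0.75), names = FALSE)
  tibble::tibble(
    level_a = as.character(levels_[1]), n_a = length(xa),
    median_a = qa[2], iqr_low_a = qa[1], iqr_high_a = qa[3],
    level_b = as.character(levels_[2]), n_b = length(xb),
    median_b = qb[2], iqr_low_b = qb[1], iqr_high_b = qb[3],
    statistic = unname(ht$statistic), p_value = ht$p.value,
    method = if (exact) {
      "Mann-Whitney U (exact)"
    } else {
      "Mann-Whitney U (normal approximation)"
    }
  )
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties and a two-sided
#' p-value (exact for small untied samples, asymptotic otherwise, as in
#' [stats::cor.test()]).
#'
#' @param data Data frame.
#' @param x,y Columns to correlate (tidy-eval).
#' @return One-row tibble with `r_s`, `p_value`, `n`.
#' @export
spearman_corr <- function(data, x, y) {
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  ok <- !is.na(xv) & !is.na(yv)
  xv <- xv[ok]
  yv <- yv[ok]
  if (length(xv) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("constant input: rank correlation undefined", call. = FALSE)
  }
  ht <- suppressWarnings(
    stats::cor.test(xv, yv, method = "spearman", alternative = "two.sided")
  )
  tibble::tibble(
    r_s = unname(ht$estimate), p_value = ht$p.value, n = length(xv)
  )
}

# resolve pre/post column names for a change variable
pre_post_columns <- function(variable) {
  switch(variable,
    total = c("pre_total", "post_total"),
    mmse = c("mmse_pre", "mmse_post"),
    gait = ,
    balance = ,
    continence = ,
    cognitive = paste0(variable, c("_pre", "_post")),
    stop("unknown change variable `", variable, "`", call. = FALSE)
  )
}

#' Paired test of pre/post change
#'
#' Tests whether a score changed between baseline and the 12-month
#' follow-up: a two-sided paired t-test for the total iNPH-scale score,
#' and the Wilcoxon signed-rank test for MMSE and the separate domains
#' (zero differences dropped; exact distribution for at most 25
#' non-zero untied differences, otherwise normal approximation with
#' continuity correction).
#'
#' @param cohort A scored cohort.
#' @param variable One of `"total"`, `"gait"`, `"balance"`,
#'   `"continence"`, `"cognitive"`, `"mmse"`.
#' @param test `"auto"` (t-test for total, Wilcoxon otherwise), or
#'   force `"t"` / `"wilcoxon"`.
#' @return One-row tibble with the test name, statistic, p-value,
#'   number of pairs and mean/median change.
#' @export
paired_change_tests <- function(cohort,
                                variable = c(
                                  "total", "gait", "balance",
                                  "continence", "cognitive", "mmse"
                                ),
                                test = c("auto", "t", "wilcoxon")) {
  variable <- match.arg(variable)
  test <- match.arg(test)
  if (test == "auto") test <- if (variable == "total") "t" else "wilcoxon"
  cols <- pre_post_columns(variable)
  if (!all(cols %in% names(cohort))) {
    stop("cohort lacks columns ", paste(cols, collapse = ", "),
      call. = FALSE
    )
  }
  pre <- cohort[[cols[1]]]
  post <- cohort[[cols[2]]]
  ok <- !is.na(pre) & !is.na(post)
  d <- post[ok] - pre[ok]
  n_pairs <- length(d)
  if (test == "t") {
    if (n_pairs < 2) stop("need at least 2 complete pairs", call. = FALSE)
    if (stats::sd(d) == 0) {
      stop("all differences are identical: paired t-test is degenerate",
        call. = FALSE
      )
    }
    ht <- stats::t.test(d)
    tibble::tibble(
      variable = variable, method = "paired t-test",
      statistic = unname(ht$statistic), p_value = ht$p.value,
      n = n_pairs, estimate = mean(d)
    )
  } else {
    dz <- d[d != 0]
    if (length(dz) == 0) {
      stop("all differences are zero: signed-rank test undefined",
        call. = FALSE
      )
    }
    exact <- length(dz) <= 25 && anyDuplicated(abs(dz)) == 0
    ht <- suppressWarnings(stats::wilcox.test(
      dz,
      exact = exact, correct = !exact
    ))
    tibble::tibble(
      variable = variable, method = if (exact) {
        "Wilcoxon signed-rank (exact)"
      } else {
        "Wilcoxon signed-rank (normal approximation)"
      },
      statistic = unname(ht$statistic), p_value = ht$p.value,
      n = n_pairs, estimate = stats::median(d)
    )
  }
}
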