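#' Intraclass correlation between two measurement methods
#'
#' Single-rater intraclass correlation from the two-way ANOVA mean
#' squares of paired measurements, quantifying how well two volumetry
#' methods agree on the same subjects. The default form is ICC(A,1) —
#' two-way random effects, absolute agreement, single measurement —
#' which penalises a systematic offset between methods;
#' `type = "consistency"` gives ICC(C,1), which does not. The 95%
#' confidence interval uses the F-distribution method of McGraw & Wong.
#'
#' With subjects as rows and methods as columns, the mean squares are
#' MSR (rows), MSC (columns) and MSE (residual), and
#' \deqn{ICC(A,1) = \frac{MSR - MSE}{MSR + (k-1)MSE +
#'   \frac{k}{n}(MSC - MSE)}}{ICC(A,1) = (MSR-MSE) /
#'   (MSR + (k-1) MSE + (k/n)(MSC - MSE))}
#'
#' @param data Data frame of paired measurements.
#' @param value_a,value_b Columns holding the two methods' values
#'   (tidy-eval).
#' @param type `"agreement"` (ICC(A,1), default) or `"consistency"`
#'   (ICC(C,1)).
#' @param conf_level Confidence level for the interval.
#' @return An object of class `icc_fit`; see [tidy.icc_fit()].
#' @examples
#' d <- data.frame(a = c(1, 2, 3), b = c(2, 3, 4))
#' icc_agreement(d, a, b)$icc # 2/3
#' @export
icc_agreement <- function(data, value_a, value_b,
                          type = c("agreement", "consistency"),
                          conf_level = 0.95) {
  type <- match.arg(type)
  a <- rlang::eval_tidy(rlang::enquo(value_a), data)
  b <- rlang::eval_tidy(rlang::enquo(value_b), data)
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]
  b <- b[ok]
  n <- length(a)
  if (n < 2) stop("need at least 2 complete pairs", call. = FALSE)
  if (any(!is.finite(c(a, b)))) {
    stop("measurements must be finite", call. = FALSE)
  }
  x <- cbind(a, b)
  k <- 2L
  g <- mean(x)
  rm_ <- rowMeans(x)
  cm <- colMeans(x)
  msr <- k * sum((rm_ - g)^2) / (n - 1)
  msc <- n * sum((cm - g)^2) / (k - 1)
  mse <- sum((x - outer(rm_, rep(1, k)) -
    outer(rep(1, n), cm) + g)^2) / ((n - 1) * (k - 1))
  if (msr + msc + mse <= 0) {
    stop("ICC undefined: measurements have zero total variance",
      call. = FALSE
    )
  }
  if (type == "agreement") {
    icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
  }
  alpha <- 1 - conf_level
  ci <- c(NA_real_, NA_real_)
  if (type == "agreement") {
    denom <- n * (1 - icc)
    if (is.finite(icc) && abs(denom) > 1e-12 && mse > 0) {
      aa <- (k * icc) / denom
      bb <- 1 + (k * icc * (n - 1)) / denom
      v <- (aa * msc + bb * mse)^2 /
        ((aa * msc)^2 / (k - 1) + (bb * mse)^2 / ((n - 1) * (k - 1)))
      f_l <- stats::qf(1 - alpha / 2, n - 1, v)
      f_u <- stats::qf(1 - alpha / 2, v, n - 1)
      ci[1] <- n * (msr - f_l * mse) /
        (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
      ci[2] <- n * (f_u * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    }
  } else if (mse > 0) {
    fobs <- msr / mse
    f1 <- stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    f2 <- stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    ci[1] <- (fobs / f1 - 1) / (fobs / f1 + k - 1)
    ci[2] <- (fobs * f2 - 1) / (fobs * f2 + k - 1)
  }
  structure(
    list(
      icc = icc, ci_low = ci[1], ci_high = ci[2], type = type,
      n = n, k = k, msr = msr, msc = msc, mse = mse,
      conf_level = conf_level
    ),
    class = "icc_fit"
  )
}

#' @export
print.icc_fit <- function(x, ...) {
  label <- if (x$type == "agreement") "ICC(A,1)" else "ICC(C,1)"
  cat(
    label, " = ", format(x$icc, digits = 3), " (",
    round(100 * x$conf_level), "% CI ", format(x$ci_low, digits = 3),
    " to ", format(x$ci_high, digits = 3), "), n = ", x$n, " pairs\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy an ICC fit
#'
#' @param x An `icc_fit` from [icc_agreement()].
#' @param ... Unused.
#' @return One-row tibble with `icc`, `ci_low`, `ci_high`, `type`.
#' @export
tidy.icc_fit <- function(x, ...) {
  tibble::tibble(
    icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high, type = x$type
  )
}

#' @rdname tidy.icc_fit
#' @export
glance.icc_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, k = x$k, msr = x$msr, msc = x$msc, mse = x$mse,
    conf_level = x$conf_level
  )
}

#' Bland-Altman agreement analysis
#'
#' Mean difference and limits of agreement (mean +/- 1.96 SD of the
#' per-subject differences) between two measurement methods, plus the
#' per-subject (mean, difference) coordinates for plotting. One pair
#' per subject is assumed (no repeated-measures correction).
#'
#' @param data Data frame of paired measurements.
#' @param value_a,value_b Columns holding the two methods' values
#'   (tidy-eval); differences are `value_a - value_b`.
#' @param loa_multiplier Multiplier for the limits of agreement.
#' @return An object of class `bland_altman` with fields `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `n` and `points` (tibble of
#'   `mean`, `diff`).
#' @export
bland_altman <- function(data, value_a, value_b, loa_multiplier = 1.96) {
  a <- rlang::eval_tidy(rlang::enquo(value_a), data)
  b <- rlang::eval_tidy(rlang::enquo(value_b), data)
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]
  b <- b[ok]
  n <- length(a)
  if (n < 2) stop("need at least 2 complete pairs", call. = FALSE)
  d <- a - b
  md <- mean(d)
  sd_d <- stats::sd(d)
  structure(
    list(
      mean_diff = md, sd_diff = sd_d,
      loa_low = md - loa_multiplier * sd_d,
      loa_high = md + loa_multiplier * sd_d,
      loa_multiplier = loa_multiplier, n = n,
      points = tibble::tibble(mean = (a + b) / 2, diff = d)
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(
    "Bland-Altman: mean difference ", format(x$mean_diff, digits = 3),
    ", limits of agreement [", format(x$loa_low, digits = 3), ", ",
    format(x$loa_high, digits = 3), "], n = ", x$n, "\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a Bland-Altman analysis
#'
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @return One-row tibble with `mean_diff`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n`.
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(
    mean_diff = x$mean_diff, sd_diff = x$sd_diff,
    loa_low = x$loa_low, loa_high = x$loa_high, n = x$n
  )
}

#' Bland-Altman plot
#'
#' @param object A `bland_altman` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(
    object$points, ggplot2::aes(x = .data$mean, y = .data$diff)
  ) +
    ggplot2::geom_hline(yintercept = object$mean_diff, colour = "steelblue") +
    ggplot2::geom_hline(
      yintercept = c(object$loa_low, object$loa_high),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Mean of methods (ml)", y = "Difference between methods (ml)",
      title = "Bland-Altman agreement"
    ) +
    ggplot2::theme_minimal()
}
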