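#' Specification of a simulated iNPH shunt cohort
#'
#' Describes the joint distribution of a simulated patient registry:
#' demographics, comorbidity prevalences, correlated log-normal lesion
#' and ventricle volumes, baseline symptom-domain scores built around a
#' latent severity with a gait-double-weighted total of known mean and
#' SD, a configurable linear model for the postoperative change in the
#' total score (the quantity whose association with log2 volumes the
#' analysis estimates), CSF biomarkers with optional volume effects,
#' per-domain missingness, and registry exclusion flags.
#'
#' Default anchors reflect a typical large single-centre iNPH series:
#' baseline total score 49.8 (SD 19.0), median age 75, median waiting
#' time 6 months, PVH median ~15 ml, DWMH median ~2 ml, ventricles
#' ~129 ml, 64% hypertension, and strongly correlated PVH/DWMH volumes
#' (Spearman ~0.75). Volumes are drawn log-normal (strictly positive and
#' right-skewed, matching the median-far-below-mean pattern of such
#' data), with log2 parameters moment-matched from medians and IQRs.
#' Scores are truncated (clamped, not resampled) to 0-100 so that the
#' generating regression coefficient stays recoverable away from the
#' bounds.
#'
#' @param n Number of registry rows (including to-be-excluded ones).
#' @param seed Integer seed; the same spec is always reproduced exactly.
#' @param age_mean,age_sd,age_range Truncated-normal age distribution.
#' @param male_prop Proportion of male patients.
#' @param waiting_time_log2mu,waiting_time_log2sd Log2-normal waiting
#'   time (months).
#' @param volume_log2_mu,volume_log2_sd Named (pvh, dwmh, ventricles)
#'   log2-scale location and scale of the volume distributions (ml).
#' @param volume_corr 3x3 correlation matrix of the log2 volumes
#'   (order pvh, dwmh, ventricles).
#' @param evans_mean,evans_sd,evans_range Truncated-normal Evans' index.
#' @param desh_prevalence Probability of a positive DESH rating.
#' @param comorbidity_prevalences Named Bernoulli rates: diabetes,
#'   hyperlipidemia, hypertension, previous_ami, previous_stroke,
#'   aspirin, anticoagulant.
#' @param hypertension_volume_shift Named log2-shift (pvh, dwmh) applied
#'   (centred) to hypertensive patients' lesion volumes.
#' @param complication_prevalence Probability of a shunt-related
#'   complication flag.
#' @param baseline_total_mean,baseline_total_sd Mean and SD of the
#'   latent baseline total iNPH-scale score.
#' @param baseline_volume_coef Named coefficients (pvh, dwmh,
#'   ventricles) of centred log2 volumes on the latent baseline score.
#' @param domain_means,domain_sds Named (gait, balance, continence,
#'   cognitive) marginal means and SDs of the baseline domain scores.
#' @param domain_missing Named per-domain missingness rates (applied to
#'   both assessments).
#' @param extra_post_missing Additional follow-up missingness rate.
#' @param delta_model Linear model for the change in total score:
#'   a list with `intercept`, coefficients `log2_pvh`, `log2_dwmh`,
#'   `log2_ventricles`, `age`, `sex_male`, `waiting_time`, `pre_total`,
#'   `evans_index`, `desh`, plus `resid_sd` and `domain_sd` (extra
#'   per-domain scatter of the change, weighted-mean-zero).
#' @param mmse_mu,mmse_sd,mmse_missing Baseline MMSE distribution
#'   (0-30, integer) and missingness.
#' @param delta_mmse_mean,delta_mmse_sd Change in MMSE.
#' @param biomarker_log2_mu,biomarker_log2_sd Named (t_tau, p_tau,
#'   abeta42, nfl) log2-scale biomarker distributions (ng/L).
#' @param biomarker_vent_coef Named coefficients of the centred log2
#'   ventricular volume on each log2 biomarker.
#' @param biomarker_missing Named biomarker missingness rates.
#' @param n_exclude_event,n_exclude_artifact Number of rows flagged for
#'   exclusion (non-shunt-related event / radiological artifact).
#' @param gait_velocity_n Size of the gait-velocity subgroup assessed
#'   twice before surgery (0 disables).
#' @param gait_velocity_median,gait_velocity_decline Baseline median
#'   velocity (m/s) and mean pre-surgical decline.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n = 253,
                        seed = 1L,
                        age_mean = 75, age_sd = 7, age_range = c(50, 89),
                        male_prop = 0.557,
                        waiting_time_log2mu = log2(6),
                        waiting_time_log2sd = 0.742,
                        volume_log2_mu = c(
                          pvh = 3.878, dwmh = 0.766, ventricles = 6.947
                        ),
                        volume_log2_sd = c(
                          pvh = 1.710, dwmh = 1.658, ventricles = 0.459
                        ),
                        volume_corr = matrix(
                          c(
                            1, 0.767, 0.30,
                            0.767, 1, 0.25,
                            0.30, 0.25, 1
                          ),
                          nrow = 3
                        ),
                        evans_mean = 0.37, evans_sd = 0.04,
                        evans_range = c(0.2, 0.5),
                        desh_prevalence = 0.60,
                        comorbidity_prevalences = c(
                          diabetes = 0.25, hyperlipidemia = 0.38,
                          hypertension = 0.64, previous_ami = 0.15,
                          previous_stroke = 0.13, aspirin = 0.40,
                          anticoagulant = 0.07
                        ),
                        hypertension_volume_shift = c(pvh = 0.6, dwmh = 0.8),
                        complication_prevalence = 0.20,
                        baseline_total_mean = 49.8,
                        baseline_total_sd = 19.0,
                        baseline_volume_coef = c(
                          pvh = 0, dwmh = 0, ventricles = 0
                        ),
                        domain_means = c(
                          gait = 38.9, balance = 64.3,
                          continence = 59.5, cognitive = 48.9
                        ),
                        domain_sds = c(
                          gait = 24.1, balance = 20.9,
                          continence = 26.1, cognitive = 21.2
                        ),
                        domain_missing = c(
                          gait = 0, balance = 0.036,
                          continence = 0.028, cognitive = 0.613
                        ),
                        extra_post_missing = 0.012,
                        delta_model = list(
                          intercept = 19.2, log2_pvh = -1.2,
                          log2_dwmh = 0, log2_ventricles = 0,
                          age = 0, sex_male = 0, waiting_time = -0.3,
                          pre_total = -0.15, evans_index = 0, desh = 0,
                          resid_sd = 15, domain_sd = 8
                        ),
                        mmse_mu = 24.8, mmse_sd = 4, mmse_missing = 0.016,
                        delta_mmse_mean = 0.4, delta_mmse_sd = 3,
                        biomarker_log2_mu = c(
                          t_tau = 7.72, p_tau = 4.91,
                          abeta42 = 9.08, nfl = 10.23
                        ),
                        biomarker_log2_sd = c(
                          t_tau = 0.80, p_tau = 0.56,
                          abeta42 = 0.66, nfl = 0.84
                        ),
                        biomarker_vent_coef = c(
                          t_tau = -0.474, p_tau = 0, abeta42 = 0, nfl = 0
                        ),
                        biomarker_missing = c(
                          t_tau = 0.051, p_tau = 0.067,
                          abeta42 = 0.063, nfl = 0.70
                        ),
                        n_exclude_event = 0, n_exclude_artifact = 0,
                        gait_velocity_n = 0,
                        gait_velocity_median = 0.71,
                        gait_velocity_decline = 0.08) {
  spec <- as.list(environment())
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  stopifnot(
    spec$n >= 1,
    spec$n_exclude_event >= 0, spec$n_exclude_artifact >= 0,
    spec$n_exclude_event + spec$n_exclude_artifact <= spec$n,
    spec$gait_velocity_n <= spec$n
  )
  nums <- unlist(spec[vapply(spec, is.numeric, logical(1))])
  nums <- c(nums, unlist(spec$delta_model))
  if (any(!is.finite(nums))) {
    stop("cohort spec contains non-finite model parameters", call. = FALSE)
  }
  sds <- c(
    spec$delta_model$resid_sd, spec$delta_model$domain_sd,
    spec$volume_log2_sd, spec$domain_sds, spec$biomarker_log2_sd,
    spec$baseline_total_sd, spec$age_sd, spec$evans_sd
  )
  if (any(sds < 0)) stop("spread parameters must be >= 0", call. = FALSE)
  ev <- eigen(spec$volume_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("volume_corr is not positive semi-definite", call. = FALSE)
  }
  invisible(spec)
}

# mean and sd of a normal(mu, sigma) truncated to [lower, upper]
trunc_normal_moments <- function(mu, sigma, lower, upper) {
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / z
  v <- sigma^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  list(mean = m, sd = sqrt(max(v, 0)))
}

# pre-truncation (mu, sigma) whose truncated-to-[lower, upper] moments
# equal the requested mean and sd (simple fixed-point iteration)
trunc_normal_params <- function(mean, sd, lower, upper) {
  if (sd == 0) {
    return(list(mu = mean, sigma = 0))
  }
  mu <- mean
  sigma <- sd
  for (i in 1:100) {
    mo <- trunc_normal_moments(mu, sigma, lower, upper)
    if (abs(mo$mean - mean) < 1e-10 && abs(mo$sd - sd) < 1e-10) break
    mu <- mu + (mean - mo$mean)
    sigma <- sigma * sd / mo$sd
  }
  list(mu = mu, sigma = sigma)
}

# exact truncated-normal sampling by inverse CDF (deterministic draw count)
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  if (sd == 0) {
    return(rep(pmin(pmax(mean, lower), upper), n))
  }
  p <- stats::runif(
    n, stats::pnorm(lower, mean, sd), stats::pnorm(upper, mean, sd)
  )
  stats::qnorm(p, mean, sd)
}

clamp01 <- function(x, lo = 0, hi = 100) pmin(pmax(x, lo), hi)

# Build bounded domain scores whose gait-double-weighted mean equals the
# target total. Start from target + offset + residual, clamp to [0,100],
# then iteratively shift all domains by the remaining deficit and
# re-clamp; since the target itself lies in [0,100] the iteration
# converges (in the worst case every domain equals the target).
domains_matching_total <- function(target, offsets, e, w, iter = 30) {
  d <- clamp01(outer(target, offsets[names(w)], "+") + e)
  ww <- w / sum(w)
  for (k in seq_len(iter)) {
    deficit <- target - drop(d %*% ww)
    if (max(abs(deficit)) < 1e-10) break
    d <- clamp01(d + deficit)
  }
  colnames(d) <- names(w)
  d
}

# Draw per-domain residuals that (a) have weighted mean exactly zero for
# every patient, so the gait-double-weighted total equals the latent
# severity, and (b) hit prescribed marginal variances. The projection
# u_i = e_i - sum(w_j e_j)/W shrinks variances, so the raw variances v
# are solved from the linear map Var(u_i) = sum_j A_ij v_j with
# A_ii = (1 - w_i/W)^2, A_ij = (w_j/W)^2; negative solutions (targets
# unreachable under the projection) are clipped to zero.
domain_residuals <- function(n, w, target_var) {
  k <- length(w)
  ww <- w / sum(w)
  a <- outer(rep(1, k), ww^2)
  diag(a) <- (1 - ww)^2
  v <- tryCatch(solve(a, target_var), error = function(e) target_var)
  v <- pmax(v, 0)
  e <- vapply(
    seq_len(k), function(j) stats::rnorm(n, 0, sqrt(v[j])),
    numeric(n)
  )
  colnames(e) <- names(w)
  e - drop(e %*% w) / sum(w)
}

#' Generate a simulated iNPH shunt registry
#'
#' Draws one registry table from a [cohort_spec()]. Each row is one
#' simulated patient with demographics, comorbidity flags, compartment
#' volumes, pre/post symptom-domain scores and MMSE, CSF biomarkers,
#' an optional gait-velocity subgroup, and exclusion/complication
#' flags. The change in the total score is generated as
#' intercept + sum(coefficients x covariates) +
#' coefficient x log2(volume) + noise; responder status is *not* stored
#' — it is derived downstream by [score_cohort()] /
#' [classify_responder()].
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per simulated patient.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 50, seed = 7))
#' dplyr::glimpse(cohort)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  withr::with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n <- spec$n
  dm <- spec$delta_model

  age <- rnorm_trunc(
    n, spec$age_mean, spec$age_sd, spec$age_range[1], spec$age_range[2]
  )
  sex <- ifelse(stats::rbinom(n, 1, spec$male_prop) == 1, "male", "female")
  waiting <- 2^stats::rnorm(n, spec$waiting_time_log2mu,
    spec$waiting_time_log2sd
  )
  evans <- rnorm_trunc(
    n, spec$evans_mean, spec$evans_sd, spec$evans_range[1],
    spec$evans_range[2]
  )
  desh <- stats::rbinom(n, 1, spec$desh_prevalence)
  com <- purrr::map(
    spec$comorbidity_prevalences, ~ stats::rbinom(n, 1, .x) == 1
  )

  # correlated log2 volumes, with a centred hypertension shift on lesions
  sig <- diag(spec$volume_log2_sd) %*% spec$volume_corr %*%
    diag(spec$volume_log2_sd)
  lv <- MASS::mvrnorm(n, mu = spec$volume_log2_mu, Sigma = sig)
  colnames(lv) <- names(spec$volume_log2_mu)
  htn <- as.numeric(com$hypertension)
  prev_htn <- spec$comorbidity_prevalences[["hypertension"]]
  lv[, "pvh"] <- lv[, "pvh"] +
    spec$hypertension_volume_shift[["pvh"]] * (htn - prev_htn)
  lv[, "dwmh"] <- lv[, "dwmh"] +
    spec$hypertension_volume_shift[["dwmh"]] * (htn - prev_htn)
  pvh_ml <- 2^lv[, "pvh"]
  dwmh_ml <- 2^lv[, "dwmh"]
  ventricles_ml <- 2^lv[, "ventricles"]

  # latent baseline severity with a known-mean/SD weighted total;
  # truncated to the instrument range by inverse CDF (no point mass at
  # the bounds), with the pre-truncation parameters calibrated so the
  # post-truncation moments equal the requested mean and SD
  lv_c <- sweep(lv, 2, spec$volume_log2_mu)
  pars <- trunc_normal_params(
    spec$baseline_total_mean, spec$baseline_total_sd, 0, 100
  )
  s_latent <- rnorm_trunc(n, pars$mu, pars$sigma, 0, 100) +
    drop(lv_c %*% spec$baseline_volume_coef[colnames(lv)])
  s_latent <- clamp01(s_latent)

  w <- c(gait = 2, balance = 1, continence = 1, cognitive = 1)
  offsets <- spec$domain_means - sum(w * spec$domain_means) / sum(w)
  target_var <- pmax(spec$domain_sds^2 - spec$baseline_total_sd^2, 0)
  e <- domain_residuals(n, w, target_var)
  pre_dom <- domains_matching_total(s_latent, offsets, e, w)

  delta_total <- dm$intercept +
    dm$log2_pvh * lv[, "pvh"] + dm$log2_dwmh * lv[, "dwmh"] +
    dm$log2_ventricles * lv[, "ventricles"] +
    dm$age * age + dm$sex_male * (sex == "male") +
    dm$waiting_time * waiting + dm$pre_total * s_latent +
    dm$evans_index * evans + dm$desh * desh +
    stats::rnorm(n, 0, dm$resid_sd)
  f <- vapply(
    names(w), function(d) stats::rnorm(n, 0, dm$domain_sd),
    numeric(n)
  )
  f <- f - drop(f %*% w) / sum(w)
  post_dom <- domains_matching_total(
    clamp01(s_latent + delta_total), offsets, e + f, w
  )

  miss_pre <- vapply(
    names(w), function(d) stats::rbinom(n, 1, spec$domain_missing[[d]]) == 1,
    logical(n)
  )
  miss_post <- miss_pre |
    matrix(stats::rbinom(n * 4, 1, spec$extra_post_missing) == 1, n, 4)
  pre_dom[miss_pre] <- NA_real_
  post_dom[miss_post] <- NA_real_
  # the scale requires at least one assessed domain: gait is never dropped
  # by default, but guard against fully missing rows under custom rates
  all_gone <- rowSums(!miss_pre) == 0
  if (any(all_gone)) {
    pre_dom[all_gone, "gait"] <-
      clamp01(s_latent[all_gone] + offsets[["gait"]])
    post_dom[all_gone, "gait"] <-
      clamp01(pre_dom[all_gone, "gait"] + delta_total[all_gone])
  }

  mmse_pre <- round(clamp01(stats::rnorm(n, spec$mmse_mu, spec$mmse_sd),
    0, 30
  ))
  mmse_post <- round(clamp01(
    mmse_pre + stats::rnorm(n, spec$delta_mmse_mean, spec$delta_mmse_sd),
    0, 30
  ))
  mmse_gone <- stats::rbinom(n, 1, spec$mmse_missing) == 1
  mmse_pre[mmse_gone] <- NA_real_
  mmse_post[mmse_gone] <- NA_real_

  lv_vent_c <- lv[, "ventricles"] - spec$volume_log2_mu[["ventricles"]]
  bm <- purrr::imap(spec$biomarker_log2_mu, function(mu, b) {
    out <- 2^(mu + spec$biomarker_vent_coef[[b]] * lv_vent_c +
      stats::rnorm(n, 0, spec$biomarker_log2_sd[[b]]))
    out[stats::rbinom(n, 1, spec$biomarker_missing[[b]]) == 1] <- NA_real_
    out
  })

  exclusion_reason <- rep("none", n)
  n_flag <- spec$n_exclude_event + spec$n_exclude_artifact
  if (n_flag > 0) {
    flagged <- sample.int(n, n_flag)
    exclusion_reason[flagged[seq_len(spec$n_exclude_event)]] <-
      "non-shunt event"
    if (spec$n_exclude_artifact > 0) {
      exclusion_reason[flagged[spec$n_exclude_event + seq_len(
        spec$n_exclude_artifact
      )]] <- "artifact"
    }
  }

  gv0 <- gv1 <- rep(NA_real_, n)
  if (spec$gait_velocity_n > 0) {
    idx <- sample.int(n, spec$gait_velocity_n)
    v0 <- exp(stats::rnorm(
      spec$gait_velocity_n, log(spec$gait_velocity_median), 0.35
    ))
    v1 <- pmax(
      v0 - stats::rnorm(
        spec$gait_velocity_n, spec$gait_velocity_decline, 0.05
      ),
      0.05
    )
    gv0[idx] <- v0
    gv1[idx] <- v1
  }

  tibble::tibble(
    id = sprintf("P%04d", seq_len(n)),
    age = age, sex = sex, waiting_time_months = waiting,
    evans_index = evans, desh = desh,
    diabetes = com$diabetes, hyperlipidemia = com$hyperlipidemia,
    hypertension = com$hypertension, previous_ami = com$previous_ami,
    previous_stroke = com$previous_stroke, aspirin = com$aspirin,
    anticoagulant = com$anticoagulant,
    pvh_ml = pvh_ml, dwmh_ml = dwmh_ml,
    total_wmc_ml = pvh_ml + dwmh_ml, ventricles_ml = ventricles_ml,
    gait_pre = pre_dom[, "gait"], balance_pre = pre_dom[, "balance"],
    continence_pre = pre_dom[, "continence"],
    cognitive_pre = pre_dom[, "cognitive"],
    gait_post = post_dom[, "gait"], balance_post = post_dom[, "balance"],
    continence_post = post_dom[, "continence"],
    cognitive_post = post_dom[, "cognitive"],
    mmse_pre = mmse_pre, mmse_post = mmse_post,
    t_tau = bm$t_tau, p_tau = bm$p_tau, abeta42 = bm$abeta42,
    nfl = bm$nfl,
    gait_velocity_t0 = gv0, gait_velocity_t1 = gv1,
    shunt_complication =
      stats::rbinom(n, 1, spec$complication_prevalence) == 1,
    exclusion_reason = exclusion_reason
  )
}
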