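# derived per-stage seeds, kept below 2^31
substream <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k) %% 2147483629)
}

#' Run the full phantom-to-report pipeline
#'
#' One reproducible end-to-end run: generate FLAIR-like phantoms,
#' segment and partition them into PVH/DWMH/ventricle volumes (both
#' partition rules), generate and score a simulated cohort, run the
#' statistical battery, compute agreement between the two partition
#' rules across phantoms, and write every intermediate artifact
#' (NIfTI volumes, CSV tables, JSON results), a log and a manifest
#' with md5 hashes of all outputs. All randomness derives from the
#' single `seed`, via fixed per-stage substreams, so re-running the
#' same config reproduces identical outputs (and identical manifest
#' hashes).
#'
#' @param config A named list or the path of a JSON file with entries:
#'   `out_dir` (required), `seed` (default 1), `n_phantoms` (default
#'   2), `phantom` (named overrides for [phantom_spec()]), `cohort`
#'   (named overrides for [cohort_spec()]), `pvh_width_mm` (default
#'   10), `min_percent` (NULL for the automatic per-subject threshold,
#'   a scalar, or one value per phantom — an NA entry aborts naming
#'   the subject), `rim_max_thickness_mm` (default 3),
#'   `min_component_voxels` (default 5), `geometry_jitter` (default
#'   0.08; relative spread of per-phantom ventricle/halo scaling).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  if (is.null(config$out_dir)) {
    stop("config must name an `out_dir`", call. = FALSE)
  }
  cfg <- override_list(
    list(
      seed = 1L, n_phantoms = 2L, phantom = list(), cohort = list(),
      pvh_width_mm = 10, min_percent = NULL, rim_max_thickness_mm = 3,
      min_component_voxels = 10, geometry_jitter = 0.08
    ),
    config
  )
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  logf <- function(...) {
    line <- paste0(...)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    message(line)
  }
  unlink(log_path)
  outputs <- character(0)
  track <- function(path) {
    outputs <<- c(outputs, path)
    path
  }
  stage <- function(name, subject = NULL, expr) {
    tryCatch(expr, error = function(e) {
      stop(
        "stage `", name, "` failed",
        if (!is.null(subject)) paste0(" for subject ", subject),
        ": ", conditionMessage(e),
        call. = FALSE
      )
    })
  }

  n_ph <- cfg$n_phantoms
  minp <- cfg$min_percent
  if (!is.null(minp) && length(minp) == 1) minp <- rep(minp, n_ph)
  if (!is.null(minp) && length(minp) != n_ph) {
    stop("`min_percent` must be NULL, a scalar, or one value per phantom",
      call. = FALSE
    )
  }

  logf("pipeline seed ", cfg$seed, "; ", n_ph, " phantoms")
  phantom_dir <- file.path(out, "phantoms")
  dir.create(phantom_dir, showWarnings = FALSE)
  measured <- list()
  for (i in seq_len(n_ph)) {
    subj <- sprintf("phantom-%02d", i)
    if (!is.null(minp) && is.na(minp[i])) {
      stop("stage `segment` aborted: no minimum threshold for subject ",
        subj,
        call. = FALSE
      )
    }
    ph <- stage("simulate-phantom", subj, {
      sd_i <- substream(cfg$seed, i)
      spec <- do.call(
        jittered_phantom_spec,
        c(list(seed = sd_i, jitter = cfg$geometry_jitter), cfg$phantom)
      )
      generate_phantom(spec)
    })
    stage("write-phantom", subj, {
      track(write_volume(
        ph$image, file.path(phantom_dir, paste0(subj, ".nii"))
      ))
      for (m in c(
        "ventricle_mask", "pvh_mask", "dwmh_mask", "rim_mask", "brain_mask"
      )) {
        track(write_mask(
          ph$truth[[m]],
          file.path(phantom_dir, paste0(subj, "_", m, ".nii"))
        ))
      }
    })
    res <- stage("segment", subj, quantify_wmc(
      ph$image, ph$truth$brain_mask, ph$truth$ventricle_seeds,
      pvh_width_mm = cfg$pvh_width_mm,
      search_mask = ph$truth$wm_mask,
      min_percent = if (is.null(minp)) NULL else minp[i],
      rim_max_thickness_mm = cfg$rim_max_thickness_mm,
      min_component_voxels = cfg$min_component_voxels
    ))
    cont <- stage("partition", subj, continuity_partition(
      res$masks$wmc, res$masks$ventricles
    ))
    measured[[i]] <- dplyr::mutate(
      res$volumes,
      id = subj, min_percent = res$min_percent,
      pvh_ml_continuity = volume_ml(cont$pvh),
      dwmh_ml_continuity = volume_ml(cont$dwmh),
      true_pvh_ml = ph$truth$volumes$ml[ph$truth$volumes$compartment == "pvh"],
      true_dwmh_ml =
        ph$truth$volumes$ml[ph$truth$volumes$compartment == "dwmh"],
      true_ventricles_ml =
        ph$truth$volumes$ml[ph$truth$volumes$compartment == "ventricles"],
      .before = 1
    )
    logf(
      subj, ": total WMC ", fmt_num(res$volumes$total_wmc_ml, 2),
      " ml (threshold ", fmt_num(res$min_percent, 1), "%)"
    )
  }
  phantom_tbl <- dplyr::bind_rows(measured)
  readr::write_csv(
    phantom_tbl, track(file.path(out, "phantom_volumes.csv"))
  )

  cohort <- stage("simulate-cohort", NULL, {
    spec <- do.call(cohort_spec, override_list(
      list(seed = substream(cfg$seed, 1000)), cfg$cohort
    ))
    generate_cohort(spec)
  })
  readr::write_csv(cohort, track(file.path(out, "registry.csv")))

  scored <- stage("score", NULL, {
    excl <- apply_exclusions(cohort)
    jsonlite::write_json(
      excl$report, track(file.path(out, "exclusion_report.json")),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
    score_cohort(excl$cohort)
  })
  readr::write_csv(scored, track(file.path(out, "scored_cohort.csv")))
  logf(
    "cohort: ", nrow(cohort), " registered, ", nrow(scored), " retained, ",
    sum(scored$responder, na.rm = TRUE), " responders"
  )

  report <- stage("analyze", NULL, build_report(scored))
  for (tb in c(
    "volumes_by_response", "delta_models", "baseline_models",
    "biomarker_models", "paired"
  )) {
    readr::write_csv(
      report[[tb]], track(file.path(out, paste0(tb, ".csv")))
    )
  }
  jsonlite::write_json(
    list(correlation = report$correlation, notes = report$notes),
    track(file.path(out, "analysis_notes.json")),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )

  agreement <- stage("agree", NULL, {
    if (n_ph >= 2) {
      icc <- tryCatch(
        tidy.icc_fit(icc_agreement(
          phantom_tbl, .data$pvh_ml, .data$pvh_ml_continuity
        )),
        error = function(e) tibble::tibble(note = conditionMessage(e))
      )
      ba <- tidy.bland_altman(bland_altman(
        phantom_tbl, .data$pvh_ml, .data$pvh_ml_continuity
      ))
      list(icc = icc, bland_altman = ba)
    } else {
      list(note = "agreement skipped: fewer than 2 phantoms")
    }
  })
  jsonlite::write_json(
    agreement, track(file.path(out, "agreement.json")),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )

  track(log_path)
  manifest <- list(
    package = "wmcvol",
    version = as.character(utils::packageVersion("wmcvol")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), "out_dir")],
    files = {
      rel <- sub(paste0(out, "/"), "", outputs, fixed = TRUE)
      stats::setNames(
        as.list(unname(tools::md5sum(outputs))), rel
      )
    }
  )
  jsonlite::write_json(
    manifest, file.path(out, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  logf("pipeline complete: ", length(outputs) + 1, " artifacts in ", out)
  invisible(manifest)
}
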