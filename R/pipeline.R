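#' Pipeline configuration
#'
#' Collects the knobs of the end-to-end analysis: simulate (optional),
#' preprocess, cluster, back-fit, features, statistics.
#'
#' @param k Number of microstate classes (default 4).
#' @param epoch_window_s Analysis window taken from the start of each trial,
#'   seconds (default 2).
#' @param backfit_mode `"samplewise"` (default) or `"peaks"` (label GFP peaks
#'   and propagate to the midpoints between peaks).
#' @param template_level Which templates are back-fitted to each trial:
#'   `"condition"` (default; the condition-specific maps, aligned to the
#'   global template, are fitted to every trial of that condition),
#'   `"trial"` (each trial's own sorted maps) or `"global"`.
#' @param smoothing Optional label-smoothing window in samples (default 0,
#'   off).
#' @param min_peak_separation Minimum GFP-peak separation in samples, used
#'   both when collecting maps for clustering and in peaks-mode back-fitting
#'   (default 1, i.e. every strict local maximum). For amplitude-modulated
#'   data a value just below the carrier half-period suppresses spurious
#'   low-amplitude maxima.
#' @param bands Bands to analyse: `"none"` (default; use the epochs as they
#'   are, appropriate for band-limited synthetic data) or a subset of
#'   `c("theta", "alpha", "beta", "gamma")` to filter each epoch into bands.
#' @param gev_gate Minimum mean GEV for a band to enter the statistics stage
#'   (default 0.70).
#' @param reject_threshold_uv Amplitude-rejection threshold (default 100).
#' @param baseline Remove each channel's epoch mean after average referencing
#'   (default TRUE). Disable for amplitude-modulated synthetic data, whose
#'   nonnegative carrier stores topographic information in the per-channel
#'   mean; for band-passed real EEG (zero DC) the step is a harmless drift
#'   remover.
#' @param condition_from `"valence"` (default): derive the emotion condition
#'   of each trial from its valence rating via [categorize_valence()];
#'   `"label"`: use the condition tag carried by the epoch.
#' @param reference Reference condition for transition contrasts.
#' @param alpha Significance threshold for the statistics stage.
#' @param sim Optional [sim_config()] used when no study is supplied.
#' @param out_dir Optional output directory for CSV/YAML artifacts.
#' @param seed Master seed for the simulate stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(k = 4, epoch_window_s = 2,
                            backfit_mode = c("samplewise", "peaks"),
                            template_level = c("condition", "trial", "global"),
                            smoothing = 0, min_peak_separation = 1,
                            bands = "none", gev_gate = 0.70,
                            reject_threshold_uv = 100, baseline = TRUE,
                            condition_from = c("valence", "label"),
                            reference = "neutral", alpha = 0.05,
                            sim = NULL, out_dir = NULL, seed = 1) {
  backfit_mode <- match.arg(backfit_mode)
  template_level <- match.arg(template_level)
  condition_from <- match.arg(condition_from)
  if (k < 2) stop_invalid("`k` must be >= 2.")
  if (gev_gate < 0 || gev_gate > 1) stop_invalid("`gev_gate` must lie in [0, 1].")
  known <- c("none", "broadband", band_specs()$name)
  if (!all(bands %in% known)) stop_invalid("unknown band name in `bands`.")
  structure(
    list(
      k = k, epoch_window_s = epoch_window_s, backfit_mode = backfit_mode,
      template_level = template_level,
      smoothing = smoothing, min_peak_separation = min_peak_separation,
      bands = bands, gev_gate = gev_gate,
      reject_threshold_uv = reject_threshold_uv, baseline = baseline,
      condition_from = condition_from,
      reference = reference, alpha = alpha, sim = sim, out_dir = out_dir,
      seed = seed
    ),
    class = "pipeline_config"
  )
}

#' Extract microstate templates from one epoch
#'
#' GFP series, GFP-peak extraction, and AAHC clustering of the peak maps
#' (weighted by their GFP) into `k` template maps.
#'
#' @param epoch An [eeg_epoch()].
#' @param k Number of classes.
#' @param min_separation Minimum peak separation in samples.
#' @return A [template_set()] (level `"trial"`) with its GEV; attribute
#'   `"peaks"` holds the peak sample indices.
#' @export
extract_trial_templates <- function(epoch, k, min_separation = 1) {
  g <- gfp(epoch)
  pk <- gfp_peaks(g, min_separation)
  if (length(pk) < k) {
    stop_invalid(sprintf("only %d GFP peaks found; cannot fit %d classes.", length(pk), k))
  }
  maps <- epoch$data[, pk, drop = FALSE]
  set <- aahc(maps, k_target = k, gfp_weights = g[pk], band = epoch$band)
  set$level <- "trial"
  attr(set, "peaks") <- pk
  set
}

crop_window <- function(epoch, window_s) {
  w <- min(round(window_s * epoch$sfreq), n_samples(epoch))
  out <- epoch
  out$data <- epoch$data[, seq_len(w), drop = FALSE]
  out
}

## One band's worth of clustering, hierarchy, back-fitting and features.
pipeline_one_band <- function(tbl, config, band_name) {
  k <- config$k
  trial_sets <- purrr::map(tbl$epoch, extract_trial_templates,
    k = k, min_separation = config$min_peak_separation
  )

  conditions <- unique(tbl$condition)
  condition_sets <- purrr::map(conditions, function(cond) {
    average_template_sets(trial_sets[tbl$condition == cond])
  })
  names(condition_sets) <- conditions
  global_set <- average_template_sets(condition_sets, reference = condition_sets[[1]])
  global_set$level <- "global"
  condition_sets <- purrr::map(condition_sets, sort_templates, reference = global_set)
  trial_sets <- purrr::map2(
    trial_sets, tbl$condition,
    function(s, cond) sort_templates(s, condition_sets[[cond]])
  )

  labels <- purrr::map(seq_len(nrow(tbl)), function(i) {
    tpl <- switch(config$template_level,
      trial = trial_sets[[i]],
      condition = condition_sets[[tbl$condition[i]]],
      global = global_set
    )
    backfit(tbl$epoch[[i]], tpl,
      peaks_only = (config$backfit_mode == "peaks"),
      min_separation = config$min_peak_separation,
      smoothing = config$smoothing
    )
  })
  feats <- purrr::map_dfr(seq_len(nrow(tbl)), function(i) {
    f <- compute_features(labels[[i]])
    dplyr::bind_cols(
      tibble(
        subject = tbl$subject[i], condition = tbl$condition[i],
        trial = tbl$trial[i], valence = tbl$valence[i], band = band_name,
        gev = trial_sets[[i]]$gev
      ),
      f
    )
  })
  list(
    trial_sets = trial_sets, condition_sets = condition_sets,
    global_set = global_set, labels = labels, features = feats,
    mean_gev = mean(purrr::map_dbl(trial_sets, "gev"))
  )
}

#' Run the full microstate pipeline
#'
#' Orchestrates simulate (when no study is given), preprocess (windowing,
#' amplitude rejection, average reference, baseline removal, optional band
#' filtering), per-trial GFP-peak AAHC clustering, the trial / condition /
#' global template hierarchy with label alignment, back-fitting, the
#' 24-feature extraction, per-subject condition averaging with exclusion of
#' incomplete subjects, the GEV band gate, and the condition statistics.
#' Identical config and seed produce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param study Optional `ms_study` (from [generate_study()]) or a tibble
#'   with columns subject, condition, trial, valence and a list-column
#'   `epoch` of [eeg_epoch()] objects.
#' @return An `ms_run`: list with `bands` (per-band clustering results),
#'   `trial_features`, `subject_features`, `gate` (retained bands),
#'   `stats` (an `ms_stats_report` or NULL), and `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), study = NULL) {
  t_start <- Sys.time()
  timings <- list()
  stage <- function(name, code) {
    t0 <- Sys.time()
    out <- tryCatch(force(code), error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
        class = "microstates_stage_error", parent = e
      )
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    out
  }

  study <- stage("simulate", {
    study %||% generate_study(config$sim %||% sim_config(seed = config$seed))
  })
  tbl <- if (inherits(study, "ms_study")) study$epochs else study

  rejection <- NULL
  tbl <- stage("preprocess", {
    epochs <- purrr::map(tbl$epoch, crop_window, window_s = config$epoch_window_s)
    rej <- reject_amplitude(epochs, config$reject_threshold_uv)
    rejection <- rej$report
    keep <- setdiff(seq_len(nrow(tbl)), rej$report$epoch)
    tbl <- tbl[keep, ]
    tbl$epoch <- purrr::map(rej$kept, function(e) {
      e <- average_reference(e)
      if (config$baseline) e <- remove_baseline(e)
      e
    })
    if ("valence" %in% names(tbl) && config$condition_from == "valence") {
      tbl$condition <- as.character(categorize_valence(tbl$valence))
    }
    tbl
  })

  band_tables <- stage("bandsplit", {
    if (identical(config$bands, "none")) {
      list(none = tbl)
    } else {
      specs <- band_specs()
      out <- lapply(config$bands, function(bd) {
        t2 <- tbl
        if (bd == "broadband") {
          t2$epoch <- purrr::map(tbl$epoch, bandpass, low_hz = 3, high_hz = 80, band_tag = "broadband")
        } else {
          sp <- specs[specs$name == bd, ]
          t2$epoch <- purrr::map(tbl$epoch, bandpass,
            low_hz = sp$low_hz, high_hz = sp$high_hz, band_tag = bd
          )
        }
        t2
      })
      setNames(out, config$bands)
    }
  })

  band_results <- stage("cluster", {
    purrr::imap(band_tables, function(t2, bd) pipeline_one_band(t2, config, bd))
  })

  trial_features <- dplyr::bind_rows(purrr::map(band_results, "features"))

  subject_features <- stage("features", {
    average_by_condition(trial_features, exclude_incomplete = TRUE)
  })
  flagged <- attr(subject_features, "flagged_subjects")

  gate <- stage("gate", {
    gev_by_band <- purrr::map_dbl(band_results, "mean_gev")
    gate_bands(gev_by_band, config$gev_gate)
  })

  stats_report <- stage("stats", {
    sf <- subject_features[subject_features$band %in% gate, ]
    n_subj <- length(unique(sf$subject))
    n_cond <- length(unique(sf$condition))
    if (nrow(sf) && n_subj >= 3 && n_cond >= 2) {
      ref <- if (config$reference %in% sf$condition) config$reference else NULL
      analyze_features(sf, reference = ref, alpha = config$alpha)
    } else {
      NULL
    }
  })

  provenance <- list(
    seed = config$seed,
    config = config[setdiff(names(config), "sim")],
    n_epochs_in = length(band_tables[[1]]$epoch),
    n_epochs_rejected = nrow(rejection),
    rejected = if (nrow(rejection)) as.list(rejection$trial_id) else list(),
    excluded_subjects = as.list(flagged),
    exclusion_reason = if (length(flagged)) "missing condition" else NULL,
    stage_timings_s = timings,
    total_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )

  run <- structure(
    list(
      study = study, bands = band_results, trial_features = trial_features,
      subject_features = subject_features, rejection = rejection,
      gate = gate, stats = stats_report, provenance = provenance
    ),
    class = "ms_run"
  )
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' @export
print.ms_run <- function(x, ...) {
  cat(sprintf(
    "<ms_run> %d trials -> %d feature rows (%d bands: %s); %d epochs rejected, %d subjects excluded\n",
    nrow(x$trial_features), nrow(x$subject_features), length(x$bands),
    paste(names(x$bands), collapse = ", "), nrow(x$rejection),
    length(x$provenance$excluded_subjects)
  ))
  cat("  bands retained by GEV gate:", paste(x$gate, collapse = ", "), "\n")
  invisible(x)
}

#' Write pipeline outputs to disk
#'
#' Template sets (global and per condition) as delimited text, label
#' sequences, trial and subject feature tables, the rejection report, the
#' band-gate report and the statistics report as CSV, and a provenance log
#' (config snapshot, seed, timings, exclusions) as YAML.
#'
#' @param run An `ms_run` from [run_pipeline()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) file.create(file.path(dir, "FAILED")))
  for (bd in names(run$bands)) {
    br <- run$bands[[bd]]
    write_template_set(br$global_set, file.path(dir, sprintf("templates_global_%s.tsv", bd)))
    for (cond in names(br$condition_sets)) {
      write_template_set(
        br$condition_sets[[cond]],
        file.path(dir, sprintf("templates_%s_%s.tsv", cond, bd))
      )
    }
    lab <- purrr::map_dfr(seq_along(br$labels), function(i) {
      out <- tidy(br$labels[[i]])
      out$trial_id <- attr(br$labels[[i]], "trial_id")
      out$band <- bd
      out
    })
    utils::write.csv(lab, file.path(dir, sprintf("labels_%s.csv", bd)), row.names = FALSE)
  }
  utils::write.csv(run$trial_features, file.path(dir, "features_trial.csv"), row.names = FALSE)
  utils::write.csv(run$subject_features, file.path(dir, "features_subject.csv"), row.names = FALSE)
  utils::write.csv(run$rejection, file.path(dir, "rejection_report.csv"), row.names = FALSE)
  utils::write.csv(attr(run$gate, "report"), file.path(dir, "gev_gate.csv"), row.names = FALSE)
  if (!is.null(run$stats)) write_stats_report(run$stats, file.path(dir, "stats_report.csv"))
  yaml::write_yaml(run$provenance, file.path(dir, "provenance.yaml"))
  ok <- TRUE
  invisible(dir)
}
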