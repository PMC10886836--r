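#' Simulation configuration for synthetic microstate EEG
#'
#' Builds the validated configuration object used by [generate_study()] and
#' friends. The generator plants a known microstate structure: `n_states`
#' orthonormal average-referenced template maps alternate according to a
#' first-order Markov chain with geometric (memoryless) run lengths of mean
#' `dwell_ms`; each template is amplitude-modulated by a rectified sinusoid at
#' `carrier_hz` so that GFP maxima are dense and well defined, and spatially
#' smooth Gaussian noise is added at a controlled signal-to-noise ratio.
#'
#' Default condition parameters emulate a three-condition affect study:
#' `negative` trials have the longest mean dwell (140 ms) and raised A-D
#' coupling, `positive` trials the shortest dwell (110 ms) with weakened B-C
#' coupling, `neutral` trials uniform transitions at 125 ms dwell.
#'
#' @param n_channels Number of scalp channels (default 59, a 64-channel 10-20
#'   montage minus non-EEG electrodes).
#' @param sfreq Sampling rate, Hz. 250 by default; set 1000 to mirror typical
#'   lab recordings.
#' @param n_states Number of planted microstate classes (default 4).
#' @param dwell_ms Mean state dwell time in milliseconds (default 125; may be
#'   overridden per condition).
#' @param transition_matrix Row-stochastic `n_states` x `n_states` matrix with
#'   zero diagonal (default uniform off-diagonal).
#' @param carrier_hz Oscillation frequency of the amplitude carrier (default
#'   10, an alpha-band rhythm).
#' @param snr Ratio of state-signal RMS to noise RMS (default 4).
#' @param amplitude_uv Overall potential scale in microvolts (default 15).
#' @param n_subjects,n_trials_per_condition Study dimensions (defaults 10, 5).
#' @param epoch_s Epoch duration in seconds (default 2).
#' @param condition_params Named list of per-condition overrides; each entry
#'   may set `dwell_ms`, `transition_matrix` and `valence_range` (the integer
#'   1-9 ratings the condition produces).
#' @param rotation_deg Maximum angle (degrees) of the random orthogonal
#'   rotation applied to the templates of each subject (default 5).
#' @param noise `"smooth"` (default): spatially smoothed white noise, a
#'   moving average over a circular channel ring, mimicking volume
#'   conduction; `"iid"`: independent white noise.
#' @param smooth_width Half-width (channels) of the smoothing ring.
#' @param seed Master integer seed; every random draw is derived from it.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_subjects = 2, n_trials_per_condition = 2)
#' cfg$n_channels
#' @export
sim_config <- function(n_channels = 59, sfreq = 250, n_states = 4,
                       dwell_ms = 125, transition_matrix = NULL,
                       carrier_hz = 10, snr = 4, amplitude_uv = 15,
                       n_subjects = 10, n_trials_per_condition = 5,
                       epoch_s = 2, condition_params = NULL,
                       rotation_deg = 5, noise = c("smooth", "iid"),
                       smooth_width = 2, seed = 1) {
  noise <- match.arg(noise)
  transition_matrix <- transition_matrix %||% uniform_transitions(n_states)
  condition_params <- condition_params %||% default_condition_params()
  cfg <- list(
    n_channels = n_channels, sfreq = sfreq, n_states = n_states,
    dwell_ms = dwell_ms, transition_matrix = transition_matrix,
    carrier_hz = carrier_hz, snr = snr, amplitude_uv = amplitude_uv,
    n_subjects = n_subjects, n_trials_per_condition = n_trials_per_condition,
    epoch_s = epoch_s, condition_params = condition_params,
    rotation_deg = rotation_deg, noise = noise, smooth_width = smooth_width,
    seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

uniform_transitions <- function(k) {
  m <- matrix(1 / (k - 1), k, k)
  diag(m) <- 0
  m
}

default_condition_params <- function() {
  neg <- matrix(c(
    0, .25, .25, .50,
    1 / 3, 0, 1 / 3, 1 / 3,
    1 / 3, 1 / 3, 0, 1 / 3,
    .50, .25, .25, 0
  ), 4, 4, byrow = TRUE)
  pos <- matrix(c(
    0, 1 / 3, 1 / 3, 1 / 3,
    .45, 0, .10, .45,
    .45, .10, 0, .45,
    .30, .30, .40, 0
  ), 4, 4, byrow = TRUE)
  list(
    negative = list(dwell_ms = 140, transition_matrix = neg, valence_range = 1:3),
    neutral  = list(dwell_ms = 125, transition_matrix = NULL, valence_range = 4:5),
    positive = list(dwell_ms = 110, transition_matrix = pos, valence_range = 6:9)
  )
}

validate_transition_matrix <- function(m, k, what = "transition_matrix") {
  if (!is.matrix(m) || nrow(m) != k || ncol(m) != k) {
    stop_invalid(sprintf("`%s` must be a %d x %d matrix.", what, k, k))
  }
  if (any(diag(m) != 0)) stop_invalid(sprintf("`%s` must have an exactly zero diagonal.", what))
  if (any(m < 0)) stop_invalid(sprintf("`%s` must be nonnegative.", what))
  if (any(abs(rowSums(m) - 1) > 1e-12)) {
    stop_invalid(sprintf("rows of `%s` must sum to 1 within 1e-12.", what))
  }
  invisible(m)
}

validate_sim_config <- function(cfg) {
  counts <- c(
    n_channels = cfg$n_channels, n_states = cfg$n_states,
    n_subjects = cfg$n_subjects, n_trials_per_condition = cfg$n_trials_per_condition
  )
  if (any(counts < 1) || any(counts != round(counts))) {
    stop_invalid("all counts must be integers >= 1.")
  }
  if (cfg$dwell_ms <= 0) stop_invalid("`dwell_ms` must be > 0.")
  if (cfg$snr <= 0) stop_invalid("`snr` must be > 0.")
  if (cfg$sfreq <= 0) stop_invalid("`sfreq` must be > 0.")
  validate_transition_matrix(cfg$transition_matrix, cfg$n_states)
  for (nm in names(cfg$condition_params)) {
    p <- cfg$condition_params[[nm]]
    if (!is.null(p$transition_matrix)) {
      validate_transition_matrix(p$transition_matrix, cfg$n_states,
        what = paste0("condition_params$", nm, "$transition_matrix")
      )
    }
    if (!is.null(p$dwell_ms) && p$dwell_ms <= 0) {
      stop_invalid(sprintf("condition `%s` dwell_ms must be > 0.", nm))
    }
  }
  invisible(cfg)
}

## Resolve per-condition overrides against the config defaults.
condition_dynamics <- function(cfg, condition = NULL) {
  dwell <- cfg$dwell_ms
  trans <- cfg$transition_matrix
  if (!is.null(condition) && condition %in% names(cfg$condition_params)) {
    p <- cfg$condition_params[[condition]]
    dwell <- p$dwell_ms %||% dwell
    trans <- p$transition_matrix %||% trans
  }
  list(dwell_ms = dwell, transition_matrix = trans)
}

#' Generate orthonormal average-referenced template maps
#'
#' Draws `n_states` mutually orthogonal, unit-norm, zero-mean (i.e. average
#' referenced) topographies by QR-orthonormalising centred Gaussian vectors.
#' The zero-mean subspace of an `n_channels`-dimensional space has dimension
#' `n_channels - 1`, so at most that many orthogonal templates exist.
#'
#' @param n_channels Number of channels.
#' @param n_states Number of templates.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A [template_set()] with level `"planted"`.
#' @examples
#' ts <- make_templates(59, 4, seed = 1)
#' round(crossprod(ts$maps), 10)  # identity: orthonormal maps
#' @export
make_templates <- function(n_channels, n_states, seed = 1) {
  if (n_states > n_channels - 1) {
    stop_invalid(sprintf(
      "cannot build %d orthogonal zero-mean maps over %d channels (the average-referenced subspace has dimension %d).",
      n_states, n_channels, n_channels - 1
    ))
  }
  maps <- with_seed(seed, {
    x <- matrix(rnorm(n_channels * n_states), n_channels, n_states)
    x <- sweep(x, 2, colMeans(x))        # project into the zero-mean subspace
    q <- qr.Q(qr(x))[, seq_len(n_states), drop = FALSE]
    ## qr.Q columns are combinations of the centred columns, hence zero-mean;
    ## canonicalise signs so the largest-magnitude channel is positive
    for (j in seq_len(n_states)) {
      i <- which.max(abs(q[, j]))
      if (q[i, j] < 0) q[, j] <- -q[, j]
    }
    q
  })
  template_set(maps, level = "planted")
}

#' Sample a planted microstate state sequence
#'
#' Run lengths are geometric with mean `dwell_ms` (converted to samples); the
#' successor of each run is drawn from the transition-matrix row of the current
#' state. The zero diagonal guarantees no two adjacent runs share a state.
#'
#' @param cfg A [sim_config()].
#' @param duration_s Sequence duration in seconds.
#' @param condition Optional condition name whose overrides apply.
#' @param seed Optional seed; by default the current RNG stream is used.
#' @return Integer vector of per-sample states in `1:n_states`.
#' @export
sample_state_sequence <- function(cfg, duration_s, condition = NULL, seed = NULL) {
  if (duration_s <= 0) stop_invalid("`duration_s` must be > 0.")
  if (!is.null(seed)) return(with_seed(seed, sample_state_sequence(cfg, duration_s, condition)))
  dyn <- condition_dynamics(cfg, condition)
  k <- cfg$n_states
  n <- round(duration_s * cfg$sfreq)
  dwell_samples <- dyn$dwell_ms * cfg$sfreq / 1000
  if (dwell_samples < 1) stop_invalid("`dwell_ms` must be at least one sample at this sampling rate.")
  p <- 1 / dwell_samples
  cum <- t(apply(dyn$transition_matrix, 1, cumsum))

  states <- integer(0)
  lengths <- integer(0)
  current <- sample.int(k, 1)
  total <- 0L
  while (total < n) {
    m <- max(32L, ceiling((n - total) / dwell_samples * 1.5))
    len <- 1L + rgeom(m, p)
    u <- runif(m)
    st <- integer(m)
    for (i in seq_len(m)) {
      st[i] <- current
      current <- 1L + sum(cum[current, ] < u[i]) # next state from the Markov row
      if (current > k) current <- k
    }
    states <- c(states, st)
    lengths <- c(lengths, len)
    total <- total + sum(len)
  }
  rep(states, lengths)[seq_len(n)]
}

#' Synthesize one EEG epoch from a planted state sequence
#'
#' The clean signal is `template[state(t)] * |sin(2 pi carrier_hz t)| *
#' amplitude`; noise (spatially smoothed by default) is scaled so that
#' RMS(signal)/RMS(noise) equals `cfg$snr`, and the result is average
#' referenced. At carrier-amplitude maxima the sample topography equals the
#' active template up to positive scale (exactly so in the noise-free limit
#' `snr = Inf`).
#'
#' @param templates A [template_set()] (or channels x states matrix) of
#'   planted maps.
#' @param state_sequence Integer vector of per-sample states.
#' @param cfg A [sim_config()].
#' @param condition,subject_id,trial_id Metadata tags for the epoch.
#' @param seed Optional seed for the noise draw.
#' @return A list with `epoch` (an [eeg_epoch()]) and `truth` (the planted
#'   state sequence and templates).
#' @export
synthesize_epoch <- function(templates, state_sequence, cfg, condition = NA_character_,
                             subject_id = NA_character_, trial_id = NA_character_,
                             seed = NULL) {
  if (!is.null(seed)) {
    return(with_seed(seed, synthesize_epoch(templates, state_sequence, cfg,
      condition = condition, subject_id = subject_id, trial_id = trial_id
    )))
  }
  maps <- as_template_matrix(templates)
  if (nrow(maps) != cfg$n_channels) {
    stop_dimension("template channel count does not match `cfg$n_channels`.")
  }
  if (any(state_sequence < 1 | state_sequence > ncol(maps))) {
    stop_input("`state_sequence` values must index the templates.")
  }
  n <- length(state_sequence)
  tt <- (seq_len(n) - 1) / cfg$sfreq
  amp <- abs(sin(2 * pi * cfg$carrier_hz * tt))
  clean <- maps[, state_sequence, drop = FALSE] *
    rep(amp * cfg$amplitude_uv, each = cfg$n_channels)

  if (is.finite(cfg$snr)) {
    noise <- matrix(rnorm(cfg$n_channels * n), cfg$n_channels, n)
    if (cfg$noise == "smooth") noise <- smooth_channels(noise, cfg$smooth_width)
    rms_clean <- sqrt(mean(clean^2))
    rms_noise <- sqrt(mean(noise^2))
    noise <- noise * rms_clean / (cfg$snr * rms_noise)
    data <- clean + noise
  } else {
    data <- clean
  }
  data <- sweep(data, 2, colMeans(data)) # average reference
  epoch <- eeg_epoch(data,
    sfreq = cfg$sfreq, band = "broadband",
    subject_id = subject_id, trial_id = trial_id, condition = condition
  )
  list(epoch = epoch, truth = list(states = state_sequence, templates = maps))
}

## Circular moving average over the channel index, a crude stand-in for the
## spatial smearing of volume conduction.
smooth_channels <- function(x, half_width) {
  if (half_width < 1) return(x)
  nch <- nrow(x)
  out <- x
  for (s in seq_len(half_width)) {
    up <- c((s + 1):nch, 1:s)
    dn <- c((nch - s + 1):nch, 1:(nch - s))
    out <- out + x[up, , drop = FALSE] + x[dn, , drop = FALSE]
  }
  out / (2 * half_width + 1)
}

## Random orthogonal rotation with maximum rotation angle `angle_deg`,
## restricted to the zero-mean subspace (it fixes the constant vector), so
## rotated templates stay average referenced and orthonormal.
rotation_matrix <- function(n, angle_deg) {
  if (angle_deg == 0) return(diag(n))
  m <- matrix(rnorm(n * n), n, n)
  s <- m - t(m)
  c_mat <- diag(n) - 1 / n
  a <- c_mat %*% s %*% c_mat
  a <- a * (angle_deg * pi / 180) / norm(a, "2")
  as.matrix(Matrix::expm(a))
}

#' Generate a full synthetic study with ground truth
#'
#' Produces `n_subjects` x conditions x `n_trials_per_condition` epochs. Each
#' subject receives a small random orthogonal rotation of the planted template
#' maps (inter-subject topographic variability); each condition uses its own
#' planted dwell time and transition matrix; simulated valence ratings are
#' drawn from the condition's `valence_range`. Fully reproducible from
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `ms_study` with elements `epochs` (a tibble with
#'   columns subject, condition, trial, valence and list-columns `epoch`,
#'   `states`), `templates` (the planted [template_set()]),
#'   `subject_templates`, `planted` (per-condition dwell and transition
#'   matrices) and `config`.
#' @examples
#' study <- generate_study(sim_config(
#'   n_channels = 12, n_subjects = 2,
#'   n_trials_per_condition = 1, epoch_s = 0.5
#' ))
#' study$epochs
#' @export
generate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  base <- make_templates(cfg$n_channels, cfg$n_states, seed = child_seed(cfg$seed, 1))
  conditions <- names(cfg$condition_params)
  with_seed(child_seed(cfg$seed, 2), {
    subject_templates <- lapply(seq_len(cfg$n_subjects), function(s) {
      q <- rotation_matrix(cfg$n_channels, cfg$rotation_deg)
      template_set(q %*% base$maps, level = "planted")
    })
    rows <- list()
    for (s in seq_len(cfg$n_subjects)) {
      subj <- sprintf("S%02d", s)
      for (cond in conditions) {
        vr <- cfg$condition_params[[cond]]$valence_range %||% 1:9
        for (tr in seq_len(cfg$n_trials_per_condition)) {
          states <- sample_state_sequence(cfg, cfg$epoch_s, cond)
          syn <- synthesize_epoch(subject_templates[[s]], states, cfg,
            condition = cond, subject_id = subj,
            trial_id = sprintf("%s_%s_t%02d", subj, cond, tr)
          )
          rows[[length(rows) + 1L]] <- tibble(
            subject = subj, condition = cond, trial = tr,
            valence = as.integer(sample(as.character(vr), 1)),
            epoch = list(syn$epoch), states = list(states)
          )
        }
      }
    }
    planted <- purrr::map_dfr(conditions, function(cond) {
      dyn <- condition_dynamics(cfg, cond)
      tibble(
        condition = cond, dwell_ms = dyn$dwell_ms,
        transition_matrix = list(dyn$transition_matrix)
      )
    })
    structure(
      list(
        epochs = dplyr::bind_rows(rows), templates = base,
        subject_templates = subject_templates, planted = planted, config = cfg
      ),
      class = "ms_study"
    )
  })
}

#' @export
print.ms_study <- function(x, ...) {
  cat(sprintf(
    "<ms_study> %d epochs: %d subjects x %d conditions x %d trials, %d channels @ %g Hz\n",
    nrow(x$epochs), x$config$n_subjects, length(x$config$condition_params),
    x$config$n_trials_per_condition, x$config$n_channels, x$config$sfreq
  ))
  invisible(x)
}

#' Write a synthetic study to plain-text files
#'
#' Writes one tab-separated matrix per trial, a `manifest.csv` linking
#' subjects, trials, conditions, valence ratings and files, a
#' `ground_truth.csv` of per-sample planted labels, a
#' `planted_parameters.csv` of per-condition dwell times and transition
#' probabilities, and the configuration as `config.yaml`.
#'
#' @param study An `ms_study` from [generate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ep <- study$epochs
  files <- character(nrow(ep))
  for (i in seq_len(nrow(ep))) {
    files[i] <- paste0(ep$epoch[[i]]$trial_id, ".tsv")
    write_eeg_matrix(ep$epoch[[i]], file.path(dir, files[i]))
  }
  manifest <- dplyr::mutate(
    dplyr::select(ep, "subject", "condition", "trial", "valence"),
    file = files, start_sample = 1L
  )
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  truth <- purrr::map_dfr(seq_len(nrow(ep)), function(i) {
    tibble(file = files[i], sample = seq_along(ep$states[[i]]), state = ep$states[[i]])
  })
  utils::write.csv(truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  planted <- purrr::map_dfr(seq_len(nrow(study$planted)), function(i) {
    m <- study$planted$transition_matrix[[i]]
    k <- nrow(m)
    tibble(
      condition = study$planted$condition[i],
      dwell_ms = study$planted$dwell_ms[i],
      from = rep(LETTERS[1:k], each = k), to = rep(LETTERS[1:k], k),
      probability = as.vector(t(m))
    )
  })
  utils::write.csv(planted, file.path(dir, "planted_parameters.csv"), row.names = FALSE)
  cfg <- study$config
  cfg_out <- cfg[c(
    "n_channels", "sfreq", "n_states", "dwell_ms", "carrier_hz", "snr",
    "amplitude_uv", "n_subjects", "n_trials_per_condition", "epoch_s",
    "rotation_deg", "noise", "smooth_width", "seed"
  )]
  yaml::write_yaml(cfg_out, file.path(dir, "config.yaml"))
  invisible(dir)
}
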