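#' Frequency-band definitions
#'
#' The four analysis bands: theta (4-8 Hz), alpha (8-13 Hz), beta (13-30 Hz)
#' and gamma (30-49 Hz).
#'
#' @return A tibble with columns `name`, `low_hz`, `high_hz`.
#' @export
band_specs <- function() {
  tibble(
    name = c("theta", "alpha", "beta", "gamma"),
    low_hz = c(4, 8, 13, 30),
    high_hz = c(8, 13, 30, 49)
  )
}

## Design a linear-phase (odd length, type I) Hamming-window FIR band-pass.
## The length follows the transition width (approximately 3.3 / delta_f for a
## Hamming window) rather than any fixed tap count, so the dB contract holds
## at every sampling rate; it is capped so the reflection padding fits the
## signal.
design_fir <- function(low_hz, high_hz, sfreq, n_samples) {
  nyq <- sfreq / 2
  if (high_hz >= nyq) stop_invalid("`high_hz` must be below the Nyquist frequency.")
  if (low_hz <= 0 || low_hz >= high_hz) stop_invalid("need 0 < low_hz < high_hz.")
  trans <- max(min(low_hz * 0.5, 6), 1)
  order <- ceiling(3.3 * sfreq / trans)
  order <- min(order, 2L * floor((n_samples - 2L) / 2L))
  if (order %% 2 == 1) order <- order + 1
  if (order < 8) stop_invalid("epoch too short for the requested filter.")
  signal::fir1(order, c(low_hz, high_hz) / nyq, type = "pass")
}

## Zero-phase filtering: centred convolution with the symmetric FIR after
## reflection padding (a linear-phase FIR applied centred has exactly zero
## phase, so one pass suffices).
apply_fir <- function(x, h) {
  p <- (length(h) - 1) / 2
  n <- length(x)
  left <- x[(p + 1):2]
  right <- x[(n - 1):(n - p)]
  xp <- c(left, x, right)
  stats::convolve(xp, rev(h), type = "filter")
}

#' Zero-phase FIR band-pass filter
#'
#' Filters every channel with a Hamming-window linear-phase FIR applied with
#' zero phase (reflection-padded centred convolution). Out-of-band sinusoids
#' are attenuated by at least 20 dB and in-band components pass within 1 dB
#' (outside the transition bands). Filtering is linear.
#'
#' @param epoch An [eeg_epoch()].
#' @param low_hz,high_hz Band edges in Hz; `high_hz` must be below Nyquist.
#' @param band_tag Optional band name recorded on the output.
#' @return The filtered [eeg_epoch()].
#' @export
bandpass <- function(epoch, low_hz, high_hz, band_tag = NULL) {
  h <- design_fir(low_hz, high_hz, epoch$sfreq, n_samples(epoch))
  out <- epoch
  out$data <- t(apply(epoch$data, 1, apply_fir, h = h))
  if (!is.null(band_tag)) out$band <- band_tag
  out
}

#' Optional 50 Hz notch filter
#'
#' Removes power-line interference with a zero-phase FIR band-stop. Synthetic
#' data carry no line noise, so this is off the main path and provided for
#' real recordings.
#'
#' @param epoch An [eeg_epoch()].
#' @param centre_hz Line frequency (default 50).
#' @param half_width_hz Stop-band half width (default 2).
#' @return The filtered [eeg_epoch()].
#' @export
notch <- function(epoch, centre_hz = 50, half_width_hz = 2) {
  nyq <- epoch$sfreq / 2
  if (centre_hz + half_width_hz >= nyq) stop_invalid("notch band must lie below Nyquist.")
  n <- n_samples(epoch)
  order <- min(ceiling(3.3 * epoch$sfreq / 1), 2L * floor((n - 2L) / 2L))
  if (order %% 2 == 1) order <- order + 1
  h <- signal::fir1(order, c(centre_hz - half_width_hz, centre_hz + half_width_hz) / nyq,
    type = "stop"
  )
  out <- epoch
  out$data <- t(apply(epoch$data, 1, apply_fir, h = h))
  out
}

#' Split a broadband epoch into the four analysis bands
#'
#' @param epoch A broadband [eeg_epoch()].
#' @return A named list of four band-tagged epochs (theta, alpha, beta,
#'   gamma) of the same duration and channels.
#' @export
split_bands <- function(epoch) {
  if (!identical(epoch$band, "broadband")) {
    abort("`split_bands()` expects a broadband epoch.", class = "microstates_invalid_state")
  }
  specs <- band_specs()
  out <- purrr::pmap(specs, function(name, low_hz, high_hz) {
    bandpass(epoch, low_hz, high_hz, band_tag = name)
  })
  setNames(out, specs$name)
}

#' Cut a recording into consecutive analysis epochs
#'
#' Non-overlapping consecutive windows of `window_s` seconds; sample indices
#' are half-open `[start, start + W)` and a trailing remainder shorter than
#' one window is dropped.
#'
#' @param recording An [eeg_epoch()] holding the continuous data.
#' @param window_s Window length in seconds.
#' @return A list of [eeg_epoch()] windows (empty, with a warning, when the
#'   recording is shorter than one window).
#' @export
segment_epochs <- function(recording, window_s) {
  w <- round(window_s * recording$sfreq)
  n <- n_samples(recording)
  k <- n %/% w
  if (k == 0) {
    warn("recording shorter than one window; returning no epochs.")
    return(list())
  }
  lapply(seq_len(k), function(i) {
    out <- recording
    out$data <- recording$data[, ((i - 1) * w + 1):(i * w), drop = FALSE]
    out$trial_id <- if (is.na(recording$trial_id)) {
      sprintf("seg%03d", i)
    } else {
      sprintf("%s_seg%03d", recording$trial_id, i)
    }
    out
  })
}

#' Amplitude-based artifact rejection
#'
#' An epoch is removed if and only if any sample on any channel exceeds the
#' threshold in absolute value (strictly greater than; an epoch touching
#' exactly the threshold is kept). Kept epochs pass through bit-identical.
#'
#' @param epochs List of [eeg_epoch()] objects sharing a channel set.
#' @param threshold_uv Rejection threshold in microvolts (default 100).
#' @return A list with `kept` (the surviving epochs) and `report`, a tibble
#'   with one row per rejected epoch giving the first violating channel and
#'   sample.
#' @export
reject_amplitude <- function(epochs, threshold_uv = 100) {
  rows <- list()
  keep <- logical(length(epochs))
  for (i in seq_along(epochs)) {
    e <- epochs[[i]]
    bad <- which(abs(e$data) > threshold_uv)
    if (length(bad) == 0) {
      keep[i] <- TRUE
    } else {
      first <- bad[1]
      ch <- ((first - 1) %% nrow(e$data)) + 1
      sm <- ((first - 1) %/% nrow(e$data)) + 1
      rows[[length(rows) + 1L]] <- tibble(
        epoch = i,
        trial_id = e$trial_id,
        channel = e$channel_labels[ch],
        sample = sm,
        value = e$data[ch, sm]
      )
    }
  }
  report <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble(
      epoch = integer(), trial_id = character(), channel = character(),
      sample = integer(), value = numeric()
    )
  }
  list(kept = epochs[keep], report = report)
}

#' Average reference and baseline removal
#'
#' `average_reference()` subtracts the instantaneous mean over channels from
#' every sample; `remove_baseline()` subtracts each channel's own epoch mean.
#' (For continuous viewing data there is no pre-stimulus window, so the
#' epoch mean serves as the baseline.) Both are idempotent and commute within
#' numerical tolerance.
#'
#' @param epoch An [eeg_epoch()] with at least two channels.
#' @return The re-referenced [eeg_epoch()].
#' @export
average_reference <- function(epoch) {
  if (n_channels(epoch) < 2) stop_invalid("average reference needs >= 2 channels.")
  out <- epoch
  out$data <- sweep(epoch$data, 2, colMeans(epoch$data))
  out
}

#' @rdname average_reference
#' @export
remove_baseline <- function(epoch) {
  if (n_channels(epoch) < 2) stop_invalid("baseline removal needs >= 2 channels.")
  out <- epoch
  out$data <- sweep(epoch$data, 1, rowMeans(epoch$data))
  out
}

#' Artifact-cleaning hook
#'
#' ICA/PCA-based ocular and muscle artifact removal needs real montage
#' geometry and is out of scope for synthetic data; this hook lets users of
#' real recordings insert their own cleaning step into [run_pipeline()]. The
#' default is a no-op.
#'
#' @param epoch An [eeg_epoch()].
#' @param fun Optional function `eeg_epoch -> eeg_epoch`.
#' @return The (possibly cleaned) epoch.
#' @export
clean_artifacts <- function(epoch, fun = NULL) {
  if (is.null(fun)) epoch else fun(epoch)
}
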