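#' EEG epoch objects
#'
#' An `eeg_epoch` holds one channels-by-samples matrix of scalp potentials
#' (microvolts) together with its sampling rate, channel labels, frequency-band
#' tag and subject/trial/condition metadata. The same container is used for
#' continuous recordings (a long epoch) and for analysis windows cut from them.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param sfreq Sampling frequency in Hz.
#' @param channel_labels Character vector of channel names, one per row of
#'   `data`. Defaults to `ch01, ch02, ...`.
#' @param band Frequency-band tag, one of `"broadband"`, `"theta"`, `"alpha"`,
#'   `"beta"`, `"gamma"` (or `"none"` for unfiltered synthetic data).
#' @param subject_id,trial_id,condition Optional metadata labels.
#'
#' @return An object of class `eeg_epoch`.
#' @examples
#' e <- eeg_epoch(matrix(rnorm(20), 4, 5), sfreq = 250)
#' n_channels(e)
#' n_samples(e)
#' @export
eeg_epoch <- function(data, sfreq, channel_labels = NULL, band = "broadband",
                      subject_id = NA_character_, trial_id = NA_character_,
                      condition = NA_character_) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop_input("`data` must be a numeric channels x samples matrix.")
  }
  if (!all(is.finite(data))) stop_input("`data` must contain only finite values.")
  if (!is.numeric(sfreq) || length(sfreq) != 1L || sfreq <= 0) {
    stop_invalid("`sfreq` must be a single positive number (Hz).")
  }
  dimnames(data) <- NULL
  channel_labels <- channel_labels %||% sprintf("ch%02d", seq_len(nrow(data)))
  if (length(channel_labels) != nrow(data)) {
    stop_dimension("`channel_labels` length must equal the number of channels.")
  }
  structure(
    list(
      data = data, sfreq = sfreq, channel_labels = as.character(channel_labels),
      band = band, subject_id = subject_id, trial_id = trial_id,
      condition = condition
    ),
    class = "eeg_epoch"
  )
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf(
    "<eeg_epoch> %d channels x %d samples @ %g Hz (%.3g s), band = %s\n",
    n_channels(x), n_samples(x), x$sfreq, n_samples(x) / x$sfreq, x$band
  ))
  meta <- c(subject = x$subject_id, trial = x$trial_id, condition = x$condition)
  meta <- meta[!is.na(meta)]
  if (length(meta)) cat("  ", paste(names(meta), meta, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' @rdname eeg_epoch
#' @param x An `eeg_epoch`.
#' @export
n_channels <- function(x) nrow(x$data)

#' @rdname eeg_epoch
#' @export
n_samples <- function(x) ncol(x$data)

#' @export
as_tibble.eeg_epoch <- function(x, ...) {
  tibble(
    channel = rep(x$channel_labels, times = n_samples(x)),
    sample = rep(seq_len(n_samples(x)), each = n_channels(x)),
    time_s = rep((seq_len(n_samples(x)) - 1) / x$sfreq, each = n_channels(x)),
    value = as.vector(x$data)
  )
}

#' Read and write delimited EEG matrices
#'
#' Recordings are exchanged as plain tab-separated text: one column per
#' channel with a header row of channel labels, one row per sample. The
#' on-disk layout is samples x channels (the natural orientation for a
#' delimited file); `read_eeg_matrix()` returns the channels x samples
#' [eeg_epoch()] used throughout the package.
#'
#' @param path File path.
#' @param sfreq Sampling frequency of the stored recording, Hz.
#' @param ... Passed on to [eeg_epoch()] (band and metadata tags).
#' @return `read_eeg_matrix()` returns an [eeg_epoch()]; `write_eeg_matrix()`
#'   returns `path` invisibly.
#' @export
read_eeg_matrix <- function(path, sfreq, ...) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- t(as.matrix(df))
  dimnames(m) <- NULL
  eeg_epoch(m, sfreq = sfreq, channel_labels = colnames(df), ...)
}

#' @rdname read_eeg_matrix
#' @param epoch An [eeg_epoch()].
#' @export
write_eeg_matrix <- function(epoch, path) {
  df <- as.data.frame(t(epoch$data))
  names(df) <- epoch$channel_labels
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
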