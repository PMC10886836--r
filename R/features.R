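#' Maximal runs of a microstate label sequence
#'
#' Run-length encodes a label sequence into maximal runs of identical class.
#' Unassigned samples (`NA`) are excluded and split runs: a gap both breaks a
#' run in two and breaks transition adjacency. Start indices are 1-based.
#'
#' @param labels An `ms_labels` object from [backfit()], or an integer vector
#'   (NA = unassigned).
#' @return A tibble with columns `state` (integer class), `class` (label),
#'   `start` (1-based sample), `length` (samples), and `adjacent_next`
#'   (TRUE when the following run starts immediately after this one, i.e. no
#'   gap breaks the transition).
#' @examples
#' run_segments(c(1, 1, 1, 2, 2))
#' run_segments(c(1, NA, 1)) # the gap splits the two runs
#' @export
run_segments <- function(labels) {
  v <- as.integer(unclass(labels))
  if (length(v) == 0) stop_input("empty label sequence.")
  class_labels <- attr(labels, "class_labels") %||% LETTERS[seq_len(max(v, 1L, na.rm = TRUE))]
  sentinel <- 0L
  v2 <- ifelse(is.na(v), sentinel, v)
  r <- rle(v2)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  keep <- r$values != sentinel
  ends <- starts + r$lengths - 1L
  adjacent <- c(ends[-length(ends)] + 1L == starts[-1] & keep[-1], FALSE)
  tibble(
    state = r$values[keep],
    class = class_labels[r$values[keep]],
    start = starts[keep],
    length = r$lengths[keep],
    adjacent_next = adjacent[keep]
  )
}

#' Microstate dynamics features of one label sequence
#'
#' Computes, per microstate class k:
#' * duration: mean run length in ms (`mean run samples * 1000 / sfreq`);
#' * occurrence: runs per second of labelled time;
#' * coverage: percentage of labelled samples spent in k;
#' and the conditional transition probabilities `P(i -> j)` = (runs of i
#' immediately followed by a run of j) / (runs of i followed by any run).
#' Terminal runs (and runs followed by an unassigned gap) have no successor
#' and are excluded from transition denominators. Runs truncated by the epoch
#' edges are included in duration/occurrence/coverage unless
#' `drop_boundary_runs`. Classes that never occur get duration, occurrence
#' and coverage 0 and `NA` transition probabilities; transitions from a class
#' with no observed successor are likewise `NA`.
#'
#' For K = 4 this yields the classical 24-feature vector: 4 durations,
#' 4 occurrences, 4 coverages and 12 transition probabilities.
#'
#' @param labels An `ms_labels` object, or an integer vector plus `sfreq`/`k`.
#' @param sfreq Sampling rate (taken from `labels` when available).
#' @param k Number of classes (taken from `labels` when available).
#' @param conditional Row-normalize transition counts (default TRUE, the
#'   conditional "likelihood of shifting" convention); FALSE gives joint
#'   frequencies over all observed transitions.
#' @param drop_boundary_runs Exclude the first and last run (truncated by the
#'   epoch edges) from duration/occurrence/coverage (default FALSE).
#' @return A one-row tibble: `<class>_dur` (ms), `<class>_occ` (per s),
#'   `<class>_cov` (percent), and `p_<i><j>` for all ordered pairs.
#' @export
compute_features <- function(labels, sfreq = NULL, k = NULL,
                             conditional = TRUE, drop_boundary_runs = FALSE) {
  sfreq <- sfreq %||% attr(labels, "sfreq")
  k <- k %||% attr(labels, "k")
  if (is.null(sfreq) || is.na(sfreq)) stop_input("`sfreq` must be known.")
  if (is.null(k)) stop_input("`k` (number of classes) must be known.")
  class_labels <- attr(labels, "class_labels") %||% LETTERS[seq_len(k)]
  v <- as.integer(unclass(labels))
  if (all(is.na(v))) stop_undefined("all samples unassigned; features are undefined.")
  runs <- run_segments(labels)
  labelled_samples <- sum(!is.na(v))
  labelled_s <- labelled_samples / sfreq

  feat_runs <- runs
  if (drop_boundary_runs && nrow(runs) > 2) feat_runs <- runs[-c(1, nrow(runs)), ]

  dur <- occ <- cov <- numeric(k)
  for (s in seq_len(k)) {
    rs <- feat_runs[feat_runs$state == s, ]
    if (nrow(rs)) {
      dur[s] <- mean(rs$length) * 1000 / sfreq
      occ[s] <- nrow(rs) / labelled_s
    }
    cov[s] <- 100 * sum(v == s, na.rm = TRUE) / labelled_samples
  }

  counts <- matrix(0, k, k)
  if (nrow(runs) > 1) {
    from <- runs$state[-nrow(runs)]
    to <- runs$state[-1]
    ok <- runs$adjacent_next[-nrow(runs)]
    counts <- unclass(table(
      factor(from[ok], levels = seq_len(k)),
      factor(to[ok], levels = seq_len(k))
    ))
    dimnames(counts) <- NULL
    counts <- matrix(as.numeric(counts), k, k)
  }
  trans <- matrix(NA_real_, k, k)
  if (conditional) {
    out_totals <- rowSums(counts)
    for (s in seq_len(k)) if (out_totals[s] > 0) trans[s, ] <- counts[s, ] / out_totals[s]
  } else if (sum(counts) > 0) {
    trans[] <- counts / sum(counts)
  }

  vals <- c(dur, occ, cov)
  names(vals) <- c(
    paste0(class_labels, "_dur"),
    paste0(class_labels, "_occ"),
    paste0(class_labels, "_cov")
  )
  off <- which(row(trans) != col(trans))
  tp <- trans[off]
  names(tp) <- paste0("p_", class_labels[row(trans)[off]], class_labels[col(trans)[off]])
  ## order transition features row-wise: p_AB, p_AC, p_AD, p_BA, ...
  ord <- order(row(trans)[off], col(trans)[off])
  as_tibble(as.list(c(vals, tp[ord])))
}

#' Map valence ratings to emotion categories
#'
#' Integer ratings on the 1-9 self-assessment scale are binned as:
#' 1-3 negative, 4-5 neutral, 6-9 positive.
#'
#' @param rating Integer vector with values in 1..9.
#' @return A factor with levels negative, neutral, positive.
#' @examples
#' categorize_valence(c(3, 5, 9))
#' @export
categorize_valence <- function(rating) {
  if (any(is.na(rating)) || any(rating != round(rating)) ||
    any(rating < 1) || any(rating > 9)) {
    stop_input("valence ratings must be integers in 1..9.")
  }
  cut(rating,
    breaks = c(0.5, 3.5, 5.5, 9.5),
    labels = c("negative", "neutral", "positive")
  )
}

#' Average per-trial features within participant and condition
#'
#' Arithmetic mean of every feature column over each subject's trials of each
#' condition (and band, when present). Subjects lacking any of the required
#' conditions are flagged — such participants cannot enter a within-subject
#' comparison — and optionally excluded.
#'
#' @param trial_features Tibble of per-trial features with columns `subject`,
#'   `condition`, optionally `band`, plus feature columns.
#' @param required_conditions Conditions every subject must have; defaults to
#'   all conditions present in the data.
#' @param exclude_incomplete Drop flagged subjects (default FALSE; they are
#'   flagged either way).
#' @return A tibble of per-subject x condition means, with the flagged
#'   subjects in attribute `"flagged_subjects"`.
#' @export
average_by_condition <- function(trial_features, required_conditions = NULL,
                                 exclude_incomplete = FALSE) {
  stopifnot(all(c("subject", "condition") %in% names(trial_features)))
  required_conditions <- required_conditions %||% unique(trial_features$condition)
  have <- dplyr::summarise(
    dplyr::group_by(trial_features, .data$subject),
    complete = all(required_conditions %in% .data$condition),
    .groups = "drop"
  )
  flagged <- have$subject[!have$complete]
  group_cols <- intersect(c("subject", "condition", "band"), names(trial_features))
  numeric_cols <- names(trial_features)[vapply(trial_features, is.numeric, logical(1))]
  numeric_cols <- setdiff(numeric_cols, c("trial", "valence"))
  out <- dplyr::summarise(
    dplyr::group_by(trial_features, dplyr::across(dplyr::all_of(group_cols))),
    dplyr::across(dplyr::all_of(numeric_cols), ~ mean(.x, na.rm = TRUE)),
    .groups = "drop"
  )
  if (exclude_incomplete) out <- out[!(out$subject %in% flagged), ]
  attr(out, "flagged_subjects") <- flagged
  out
}
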