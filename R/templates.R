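#' Microstate template sets
#'
#' A `template_set` holds K labelled topographic maps (channels x K matrix),
#' the global explained variance they achieve on the data they were fitted to,
#' a frequency-band tag and a hierarchy level (`"trial"`, `"condition"`,
#' `"global"` or `"planted"`). Maps are stored normalized: zero channel mean
#' and unit L2 norm. A topography and its sign-flipped version denote the same
#' microstate (polarity invariance), so all comparisons between maps use
#' absolute spatial correlation.
#'
#' @param maps Channels x K numeric matrix of topographies.
#' @param labels Map labels; defaults to `A`, `B`, `C`, ... in column order.
#' @param gev Global explained variance in `[0, 1]` (NA when unknown, e.g.
#'   for planted or averaged sets).
#' @param band Frequency-band tag.
#' @param level Hierarchy level tag.
#' @return An object of class `template_set`.
#' @export
template_set <- function(maps, labels = NULL, gev = NA_real_,
                         band = NA_character_, level = "trial") {
  if (!is.matrix(maps) || !is.numeric(maps)) stop_input("`maps` must be a numeric matrix.")
  k <- ncol(maps)
  if (k < 1) stop_invalid("a template set needs at least one map.")
  labels <- labels %||% LETTERS[seq_len(k)]
  if (length(labels) != k || anyDuplicated(labels)) {
    stop_invalid("`labels` must be unique and match the number of maps.")
  }
  if (!is.na(gev) && (gev < 0 || gev > 1)) stop_invalid("`gev` must lie in [0, 1].")
  maps <- normalize_maps(maps)
  colnames(maps) <- labels
  structure(
    list(maps = maps, labels = labels, gev = gev, band = band, level = level),
    class = "template_set"
  )
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf(
    "<template_set> %d maps (%s) over %d channels, level = %s%s%s\n",
    ncol(x$maps), paste(x$labels, collapse = ""), nrow(x$maps), x$level,
    if (is.na(x$band)) "" else paste0(", band = ", x$band),
    if (is.na(x$gev)) "" else sprintf(", GEV = %.3f", x$gev)
  ))
  invisible(x)
}

as_template_matrix <- function(x) {
  if (inherits(x, "template_set")) x$maps else as.matrix(x)
}

#' Normalize topographic maps
#'
#' Centres each column (average reference) and scales it to unit L2 norm.
#' All-constant maps are rejected: a flat map is not a topography.
#'
#' @param maps Channels x K numeric matrix.
#' @return The normalized matrix.
#' @export
normalize_maps <- function(maps) {
  maps <- sweep(maps, 2, colMeans(maps))
  nrm <- sqrt(colSums(maps^2))
  if (any(nrm == 0)) stop_invalid("cannot normalize an all-constant map.")
  sweep(maps, 2, nrm, "/")
}

#' Spatial correlation between topographies
#'
#' Pearson correlation across channels of two maps, computed after removing
#' each map's channel mean (equivalently, the cosine of the average-referenced
#' maps). By default the absolute value is returned, because microstate
#' topographies are polarity invariant.
#'
#' @param a,b Numeric vectors (single maps) or channels x K matrices.
#' @param absolute Take the absolute value (default TRUE).
#' @return A correlation matrix (columns of `a` vs columns of `b`), or a
#'   scalar when both inputs are vectors.
#' @export
spatial_correlation <- function(a, b, absolute = TRUE) {
  va <- is.null(dim(a))
  vb <- is.null(dim(b))
  a <- normalize_maps(as.matrix(a))
  b <- normalize_maps(as.matrix(b))
  r <- crossprod(a, b)
  if (absolute) r <- abs(r)
  if (va && vb) r[1, 1] else r
}

#' Align a template set to a reference by optimal assignment
#'
#' Finds the one-to-one matching between the set's maps and the reference
#' maps that maximizes the total absolute spatial correlation (exhaustive
#' search over permutations; exact for the K <= 6 used in practice). The maps
#' are reordered accordingly, sign-aligned to the reference, and inherit the
#' reference labels.
#'
#' @param set,reference [template_set()] objects with equal K and channels.
#' @return The aligned `template_set`; the permutation applied is stored in
#'   attribute `"permutation"` (index into the input set for each reference
#'   slot).
#' @export
sort_templates <- function(set, reference) {
  a <- as_template_matrix(set)
  b <- as_template_matrix(reference)
  k <- ncol(a)
  if (ncol(b) != k) stop_invalid("`set` and `reference` must share K.")
  if (nrow(b) != nrow(a)) stop_dimension("`set` and `reference` must share channels.")
  if (k > 8) stop_invalid("exhaustive assignment supports K <= 8.")
  cmat <- spatial_correlation(a, b) # K_set x K_ref
  perms <- all_permutations(k)
  scores <- vapply(perms, function(p) sum(cmat[cbind(p, seq_len(k))]), numeric(1))
  best <- perms[[which.max(scores)]]
  out <- a[, best, drop = FALSE]
  signed <- spatial_correlation(out, b, absolute = FALSE)
  for (j in seq_len(k)) if (signed[j, j] < 0) out[, j] <- -out[, j]
  labels <- if (inherits(reference, "template_set")) reference$labels else LETTERS[seq_len(k)]
  res <- template_set(out,
    labels = labels, gev = if (inherits(set, "template_set")) set$gev else NA_real_,
    band = if (inherits(set, "template_set")) set$band else NA_character_,
    level = if (inherits(set, "template_set")) set$level else "trial"
  )
  attr(res, "permutation") <- best
  res
}

#' Average template sets across a hierarchy level
#'
#' Aligns every set to a common reference (the first set by default) with
#' [sort_templates()], averages corresponding maps (already sign-aligned by
#' the sorting step), renormalizes, and promotes the level tag
#' (trial to condition, condition to global). Averaging is polarity invariant
#' and idempotent for identical inputs. The `gev` of the result is the mean of
#' the members' GEV values, recorded as a summary of the level below.
#'
#' @param sets List of [template_set()] objects sharing K and channel count.
#' @param reference Optional [template_set()] used for label alignment; by
#'   default the member with the highest GEV (the best-explaining set) is the
#'   reference, falling back to the first set.
#' @param refine Number of re-alignment passes: after averaging, every set is
#'   re-sorted against the provisional mean and averaged again (default 1).
#' @return A [template_set()].
#' @export
average_template_sets <- function(sets, reference = NULL, refine = 1) {
  stopifnot(length(sets) >= 1)
  k <- ncol(as_template_matrix(sets[[1]]))
  member_gevs <- vapply(
    sets,
    function(s) if (inherits(s, "template_set")) s$gev else NA_real_, numeric(1)
  )
  ref <- reference %||%
    if (all(is.na(member_gevs))) sets[[1]] else sets[[which.max(member_gevs)]]
  if (ncol(as_template_matrix(ref)) != k) stop_invalid("mismatched K between sets and reference.")
  mean_of <- function(reference_set) {
    aligned <- lapply(sets, sort_templates, reference = reference_set)
    acc <- Reduce(`+`, lapply(aligned, function(s) s$maps))
    normalize_maps(acc / length(aligned))
  }
  maps <- mean_of(ref)
  for (i in seq_len(refine)) {
    ref <- template_set(maps,
      labels = if (inherits(ref, "template_set")) ref$labels else LETTERS[seq_len(k)]
    )
    maps <- mean_of(ref)
  }
  levels_in <- vapply(sets, function(s) if (inherits(s, "template_set")) s$level else "trial", character(1))
  level_out <- if (all(levels_in == "trial")) "condition" else if (all(levels_in == "condition")) "global" else "global"
  gevs <- vapply(sets, function(s) if (inherits(s, "template_set")) s$gev else NA_real_, numeric(1))
  template_set(maps,
    labels = if (inherits(ref, "template_set")) ref$labels else LETTERS[seq_len(k)],
    gev = if (all(is.na(gevs))) NA_real_ else mean(gevs, na.rm = TRUE),
    band = if (inherits(sets[[1]], "template_set")) sets[[1]]$band else NA_character_,
    level = level_out
  )
}

#' Back-fit template maps to an epoch
#'
#' Labels every sample with the template of highest absolute spatial
#' correlation. Samples with zero GFP carry no topography and are left
#' unassigned (`NA`). In `peaks_only` mode only GFP-peak samples are labelled
#' directly; each remaining sample inherits the label of its nearest peak
#' (boundaries at the midpoint between adjacent peaks), reflecting the view
#' that topographies are only reliable at GFP maxima.
#'
#' @param epoch An [eeg_epoch()] (or channels x samples matrix with an
#'   `sfreq` attribute).
#' @param templates A [template_set()].
#' @param peaks_only Label only GFP peaks and propagate (default FALSE:
#'   every sample labelled independently).
#' @param min_separation Minimum GFP-peak separation in samples (peaks mode
#'   only); peaks closer than this to a larger peak are treated as noise.
#' @param smoothing Optional odd window length (samples) for majority-vote
#'   smoothing of the label sequence; 0 (default) disables it.
#' @return An `ms_labels` object: an integer vector of class indices
#'   (NA = unassigned) with attributes `sfreq`, `k`, `class_labels` and the
#'   epoch metadata. Use [tidy()] for a tibble view.
#' @export
backfit <- function(epoch, templates, peaks_only = FALSE, min_separation = 1,
                    smoothing = 0) {
  u <- if (inherits(epoch, "eeg_epoch")) epoch$data else as.matrix(epoch)
  maps <- as_template_matrix(templates)
  if (nrow(u) != nrow(maps)) stop_dimension("epoch and templates have different channel counts.")
  maps <- normalize_maps(maps)
  sfreq <- if (inherits(epoch, "eeg_epoch")) epoch$sfreq else attr(epoch, "sfreq") %||% NA_real_
  n <- ncol(u)
  uc <- sweep(u, 2, colMeans(u))
  nrm <- sqrt(colSums(uc^2))
  ok <- nrm > 0
  labels <- rep(NA_integer_, n)
  corr <- abs(crossprod(maps, uc[, ok, drop = FALSE])) # K x n_ok; maps are unit norm
  if (any(ok)) labels[ok] <- apply(corr, 2, which.max)

  if (peaks_only) {
    g <- gfp(u)
    pk <- gfp_peaks(g, min_separation)
    out <- rep(NA_integer_, n)
    if (length(pk)) {
      ## nearest-peak propagation: cut at midpoints between adjacent peaks
      cuts <- if (length(pk) > 1) (pk[-length(pk)] + pk[-1]) / 2 else numeric(0)
      idx <- findInterval(seq_len(n), cuts + 0.5) + 1L
      out <- labels[pk][idx]
      out[!ok] <- NA_integer_
    }
    labels <- out
  }
  if (smoothing > 1) labels <- smooth_labels(labels, smoothing)

  structure(
    labels,
    sfreq = sfreq,
    k = ncol(maps),
    class_labels = if (inherits(templates, "template_set")) templates$labels else LETTERS[seq_len(ncol(maps))],
    subject_id = if (inherits(epoch, "eeg_epoch")) epoch$subject_id else NA_character_,
    trial_id = if (inherits(epoch, "eeg_epoch")) epoch$trial_id else NA_character_,
    condition = if (inherits(epoch, "eeg_epoch")) epoch$condition else NA_character_,
    class = "ms_labels"
  )
}

## Sliding-window majority vote; NA samples stay NA and do not vote.
smooth_labels <- function(labels, window) {
  h <- floor(window / 2)
  n <- length(labels)
  out <- labels
  for (i in seq_len(n)) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    w <- labels[lo:hi]
    w <- w[!is.na(w)]
    if (length(w)) {
      tab <- tabulate(w)
      out[i] <- if (is.na(labels[i])) labels[i] else which.max(tab)
    }
  }
  out
}

#' @export
print.ms_labels <- function(x, ...) {
  cat(sprintf(
    "<ms_labels> %d samples @ %g Hz, %d classes (%s), %d unassigned\n",
    length(x), attr(x, "sfreq"), attr(x, "k"),
    paste(attr(x, "class_labels"), collapse = ""), sum(is.na(unclass(x)))
  ))
  invisible(x)
}

#' @export
tidy.ms_labels <- function(x, ...) {
  v <- unclass(x)
  attributes(v) <- NULL
  tibble(
    sample = seq_along(v),
    time_s = (seq_along(v) - 1) / attr(x, "sfreq"),
    state = v,
    class = ifelse(is.na(v), NA_character_, attr(x, "class_labels")[v])
  )
}

#' Serialize template sets as delimited text
#'
#' Template maps are written as a tab-separated channels x K table with the
#' map labels as header.
#'
#' @param set A [template_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_template_set <- function(set, path) {
  df <- as.data.frame(set$maps)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_template_set
#' @param level,band Tags for the read set.
#' @export
read_template_set <- function(path, level = "trial", band = NA_character_) {
  df <- utils::read.delim(path, check.names = FALSE)
  template_set(as.matrix(df), labels = colnames(df), level = level, band = band)
}
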