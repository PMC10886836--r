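#' Global field power
#'
#' GFP at sample t is the root mean square deviation of the potentials from
#' their instantaneous channel mean: `sqrt(mean((U_n(t) - mean(U(t)))^2))`
#' over the N electrodes, i.e. the uncorrected (population) standard deviation
#' across channels. It is nonnegative and invariant to adding a common offset
#' to all channels of a sample.
#'
#' @param epoch An [eeg_epoch()] or a channels x samples numeric matrix.
#' @return Numeric vector of per-sample GFP values.
#' @examples
#' gfp(matrix(c(3, 1, -1, -3), ncol = 1)) # sqrt(5)
#' @export
gfp <- function(epoch) {
  u <- if (inherits(epoch, "eeg_epoch")) epoch$data else epoch
  if (!is.matrix(u)) u <- as.matrix(u)
  if (nrow(u) < 2) stop_invalid("GFP needs at least 2 channels.")
  mu <- colMeans(u)
  sqrt(colMeans(u^2) - mu^2)
}

#' Locate GFP peaks
#'
#' Finds strict local maxima of a GFP series: samples greater than both
#' neighbours. A flat plateau that is higher than its surroundings counts as
#' one peak at the plateau's first sample. Endpoints are never peaks. With
#' `min_separation > 1`, peaks are greedily retained in decreasing height
#' order subject to the separation constraint.
#'
#' @param gfp_series Numeric vector (typically from [gfp()]).
#' @param min_separation Minimum distance between retained peaks, in samples.
#' @return Integer vector of peak sample indices (1-based); empty if the
#'   series is shorter than 3 samples.
#' @examples
#' gfp_peaks(c(0, 1, 0, 2, 0)) # 2 and 4
#' @export
gfp_peaks <- function(gfp_series, min_separation = 1) {
  n <- length(gfp_series)
  if (n < 3) return(integer(0))
  r <- rle(gfp_series)
  nr <- length(r$values)
  if (nr < 3) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-nr]))
  interior <- 2:(nr - 1)
  is_peak <- r$values[interior] > r$values[interior - 1] &
    r$values[interior] > r$values[interior + 1]
  peaks <- starts[interior][is_peak]
  if (min_separation > 1 && length(peaks) > 1) {
    ord <- peaks[order(gfp_series[peaks], decreasing = TRUE)]
    kept <- integer(0)
    for (p in ord) {
      if (!length(kept) || all(abs(kept - p) >= min_separation)) kept <- c(kept, p)
    }
    peaks <- sort(kept)
  }
  peaks
}
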