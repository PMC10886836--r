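#' Tidy a microstate test result
#'
#' One row per test with the statistic, degrees of freedom (possibly
#' fractional after a sphericity correction), p value, effect size and the
#' correction applied.
#'
#' @param x An `ms_stat` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.ms_stat <- function(x, ...) {
  df <- unlist(x$df)
  tibble(
    test = x$test,
    statistic = x$statistic,
    df1 = unname(df[1]),
    df2 = if (length(df) > 1) unname(df[2]) else NA_real_,
    p_value = x$p_value,
    effect_size = x$effect_size %||% NA_real_,
    effect_type = x$effect_type %||% NA_character_,
    correction = x$correction %||% "none"
  )
}

#' @rdname tidy.ms_stat
#' @export
glance.ms_stat <- function(x, ...) {
  out <- tidy(x)
  if (!is.null(x$mauchly_p)) {
    out$mauchly_w <- x$mauchly_w
    out$mauchly_p <- x$mauchly_p
    out$gg_epsilon <- x$gg_epsilon
    out$hf_epsilon <- x$hf_epsilon
  }
  if (!is.null(x$n)) out$n <- x$n
  out
}

#' Tidy a template set
#'
#' Long tibble of map values: one row per channel x class.
#'
#' @param x A [template_set()].
#' @param ... Unused.
#' @return A tibble with columns `channel`, `class`, `value`.
#' @export
tidy.template_set <- function(x, ...) {
  tibble(
    channel = rep(seq_len(nrow(x$maps)), times = ncol(x$maps)),
    class = rep(x$labels, each = nrow(x$maps)),
    value = as.vector(x$maps)
  )
}

#' @rdname tidy.template_set
#' @export
glance.template_set <- function(x, ...) {
  tibble(
    k = ncol(x$maps), n_channels = nrow(x$maps),
    gev = x$gev, band = x$band, level = x$level
  )
}
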