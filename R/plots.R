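#' Plot a template set as a channel-by-class heat map
#'
#' Without electrode coordinates a topography is shown as the vector of
#' channel weights per microstate class; sign structure and the relative
#' weighting across channels are what distinguish the classes.
#'
#' @param object A [template_set()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.template_set <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$channel, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(
      x = "microstate class", y = "channel", fill = "weight",
      title = sprintf("%s-level template maps", object$level)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a microstate label sequence
#'
#' Timeline of back-fitted labels, one coloured band per microstate run;
#' unassigned samples are blank.
#'
#' @param object An `ms_labels` object from [backfit()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ms_labels <- function(object, ...) {
  runs <- run_segments(object)
  sfreq <- attr(object, "sfreq")
  runs$start_s <- (runs$start - 1) / sfreq
  runs$end_s <- (runs$start - 1 + runs$length) / sfreq
  ggplot2::ggplot(runs) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start_s, xmax = .data$end_s,
      ymin = 0, ymax = 1, fill = .data$class
    )) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "time (s)", y = NULL, fill = "class", title = "Microstate sequence") +
    ggplot2::theme_minimal()
}

#' Plot per-condition microstate features
#'
#' Box plots of duration, occurrence or coverage per class and condition from
#' a per-subject feature table.
#'
#' @param features Tibble from [average_by_condition()].
#' @param measure One of `"dur"`, `"occ"`, `"cov"`.
#' @return A ggplot object.
#' @export
plot_features <- function(features, measure = c("dur", "occ", "cov")) {
  measure <- match.arg(measure)
  cols <- grep(paste0("_", measure, "$"), names(features), value = TRUE)
  long <- tidyr::pivot_longer(
    features[, c("subject", "condition", cols)],
    dplyr::all_of(cols),
    names_to = "class", values_to = "value"
  )
  long$class <- sub(paste0("_", measure, "$"), "", long$class)
  ylab <- c(dur = "duration (ms)", occ = "occurrence (1/s)", cov = "coverage (%)")[measure]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$value, fill = .data$condition)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "microstate class", y = ylab, fill = "condition") +
    ggplot2::theme_minimal()
}

#' Plot a transition-probability matrix
#'
#' Heat map of mean conditional transition probabilities per condition,
#' computed from a feature table's `p_<i><j>` columns.
#'
#' @param features Tibble with `condition` and `p_*` columns.
#' @return A ggplot object.
#' @export
plot_transitions <- function(features) {
  cols <- grep("^p_", names(features), value = TRUE)
  long <- tidyr::pivot_longer(
    features[, c("condition", cols)],
    dplyr::all_of(cols),
    names_to = "pair", values_to = "probability"
  )
  long$from <- substr(long$pair, 3, 3)
  long$to <- substr(long$pair, 4, 4)
  agg <- dplyr::summarise(
    dplyr::group_by(long, .data$condition, .data$from, .data$to),
    probability = mean(.data$probability, na.rm = TRUE), .groups = "drop"
  )
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$to, y = .data$from, fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$probability)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b") +
    ggplot2::facet_wrap(~condition) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "to", y = "from", fill = "P") +
    ggplot2::theme_minimal()
}
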