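#' Compare microstate features across conditions
#'
#' The full statistical stage over a per-subject x condition feature table:
#'
#' * duration / occurrence / coverage features: a Shapiro-Wilk gate per
#'   condition decides between the one-way repeated-measures ANOVA (with the
#'   Mauchly / GG / HF sphericity rule, [rm_anova_oneway()]) and the Friedman
#'   test ([friedman_rm()]); significant omnibus tests are followed by
#'   Bonferroni-corrected pairwise post hocs.
#' * transition probabilities: two-sided paired comparisons of each
#'   non-reference condition against the reference (normality-gated t /
#'   Wilcoxon, [paired_test()]). No multiplicity adjustment is applied across
#'   the transition features by default (per-test p values are reported);
#'   `transition_adjust = "holm"` adds a Holm adjustment within each
#'   condition contrast.
#'
#' Subjects with missing conditions must be excluded beforehand (see
#' [average_by_condition()]).
#'
#' @param features Tibble with columns `subject`, `condition`, optionally
#'   `band`, and feature columns (`*_dur`, `*_occ`, `*_cov`, `p_*`).
#' @param reference Reference condition for transition contrasts (default
#'   `"neutral"` when present, else the first condition).
#' @param alpha Significance threshold (default 0.05).
#' @param transition_adjust `"none"` (default) or `"holm"`.
#' @return An `ms_stats_report`: a list of tibbles `omnibus`, `posthoc` and
#'   `transitions`; [tidy()] binds them into one long table.
#' @export
analyze_features <- function(features, reference = NULL, alpha = 0.05,
                             transition_adjust = c("none", "holm")) {
  transition_adjust <- match.arg(transition_adjust)
  stopifnot(all(c("subject", "condition") %in% names(features)))
  conditions <- unique(features$condition)
  if (length(conditions) < 2) stop_input("need at least 2 conditions.")
  reference <- reference %||% if ("neutral" %in% conditions) "neutral" else conditions[1]
  if (!reference %in% conditions) stop_input("`reference` is not a condition in the data.")
  bands <- if ("band" %in% names(features)) unique(features$band) else NA_character_

  feat_cols <- setdiff(
    names(features)[vapply(features, is.numeric, logical(1))],
    c("trial", "valence")
  )
  dyn_cols <- grep("_(dur|occ|cov)$", feat_cols, value = TRUE)
  trans_cols <- grep("^p_", feat_cols, value = TRUE)

  omnibus <- list()
  posthoc <- list()
  transitions <- list()

  for (bd in bands) {
    sub <- if (is.na(bd)) features else features[features$band == bd, ]
    wide_of <- function(col) {
      w <- tidyr::pivot_wider(
        sub[, c("subject", "condition", col)],
        names_from = "condition", values_from = dplyr::all_of(col)
      )
      as.matrix(w[, conditions])
    }

    for (col in dyn_cols) {
      x <- wide_of(col)
      if (anyNA(x)) next # a class absent for some subject/condition
      normal <- all(apply(x, 2, function(v) {
        stats::sd(v) > 0 && stats::shapiro.test(v)$p.value >= alpha
      }))
      st <- if (normal) rm_anova_oneway(x) else friedman_rm(x)
      row <- tidy(st)
      row$feature <- col
      row$band <- bd
      omnibus[[length(omnibus) + 1L]] <- row
      if (st$p_value < alpha) {
        ph <- bonferroni_posthoc(x, mode = if (normal) "t" else "wilcoxon")
        ph$feature <- col
        ph$band <- bd
        posthoc[[length(posthoc) + 1L]] <- ph
      }
    }

    for (cond in setdiff(conditions, reference)) {
      rows <- purrr::map_dfr(trans_cols, function(col) {
        x <- wide_of(col)
        a <- x[, cond]
        b <- x[, reference]
        keep <- !is.na(a) & !is.na(b)
        if (sum(keep) < 3) return(tibble())
        st <- tryCatch(paired_test(a[keep], b[keep]), error = function(e) NULL)
        if (is.null(st)) return(tibble())
        tibble(
          feature = col, band = bd, condition = cond, reference = reference,
          test = st$test, statistic = st$statistic, df = unname(st$df[1]),
          p_value = st$p_value, effect_size = st$effect_size,
          effect_type = st$effect_type, n = st$n
        )
      })
      if (nrow(rows) && transition_adjust == "holm") {
        rows$p_adjusted <- stats::p.adjust(rows$p_value, method = "holm")
      }
      transitions[[length(transitions) + 1L]] <- rows
    }
  }

  structure(
    list(
      omnibus = dplyr::bind_rows(omnibus),
      posthoc = dplyr::bind_rows(posthoc),
      transitions = dplyr::bind_rows(transitions),
      alpha = alpha, reference = reference
    ),
    class = "ms_stats_report"
  )
}

#' @export
print.ms_stats_report <- function(x, ...) {
  cat(sprintf(
    "<ms_stats_report> %d omnibus tests, %d post hoc rows, %d transition contrasts (alpha = %g, reference = %s)\n",
    nrow(x$omnibus), nrow(x$posthoc), nrow(x$transitions), x$alpha, x$reference
  ))
  sig <- x$omnibus[x$omnibus$p_value < x$alpha, , drop = FALSE]
  if (nrow(sig)) {
    cat("  significant omnibus:", paste(sig$feature, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.ms_stats_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$omnibus, stage = "omnibus"),
    dplyr::mutate(x$posthoc, stage = "posthoc"),
    dplyr::mutate(x$transitions, stage = "transition")
  )
}

#' Write a statistics report as CSV
#'
#' One row per test (omnibus, post hoc and transition contrasts combined).
#'
#' @param report An `ms_stats_report` from [analyze_features()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stats_report <- function(report, path) {
  utils::write.csv(tidy(report), path, row.names = FALSE)
  invisible(path)
}
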