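## Statistical stage: normality-gated repeated-measures comparisons with the
## Mauchly / Greenhouse-Geisser / Huynh-Feldt sphericity rule, Friedman and
## Wilcoxon alternatives, Bonferroni post hocs, and noncentral-distribution
## power / sample-size calculators.

new_ms_stat <- function(...) structure(list(...), class = "ms_stat")

#' @export
print.ms_stat <- function(x, ...) {
  df_txt <- paste(signif(unlist(x$df), 4), collapse = ", ")
  cat(sprintf(
    "<%s> statistic = %.4g, df = (%s), p = %.4g%s\n",
    x$test, x$statistic, df_txt, x$p_value,
    if (!is.null(x$effect_size) && !is.na(x$effect_size)) {
      sprintf(", %s = %.3f", x$effect_type, x$effect_size)
    } else {
      ""
    }
  ))
  if (!is.null(x$correction) && x$correction != "none") {
    cat("  correction:", x$correction, "\n")
  }
  invisible(x)
}

as_wide_matrix <- function(data) {
  if (is.matrix(data)) {
    m <- data
  } else if (is.data.frame(data)) {
    m <- as.matrix(data[vapply(data, is.numeric, logical(1))])
  } else {
    stop_input("`data` must be a subjects x conditions matrix or data frame.")
  }
  if (anyNA(m)) stop_input("missing cells: repeated-measures tests need complete cases.")
  m
}

## Orthonormal contrasts spanning the space orthogonal to the grand mean.
orthonormal_contrasts <- function(m) {
  h <- stats::contr.helmert(m) # m x (m-1), columns orthogonal
  sweep(h, 2, sqrt(colSums(h^2)), "/")
}

#' One-way repeated-measures ANOVA with the sphericity rule
#'
#' Within-subject sum-of-squares decomposition for one factor with `m` levels
#' measured on every subject, with Mauchly's sphericity test and both
#' epsilon corrections. The correction rule follows common practice for
#' within-subject designs: when Mauchly's test is significant (p < 0.05) the
#' degrees of freedom are multiplied by Huynh-Feldt epsilon if
#' Greenhouse-Geisser epsilon exceeds 0.75, and by Greenhouse-Geisser epsilon
#' otherwise; with `sphericity = "always"` the correction is applied
#' regardless of Mauchly's p, with `"never"` it is not applied.
#'
#' @param data Subjects x conditions numeric matrix or data frame (complete
#'   cases).
#' @param sphericity `"auto"` (default, gate on Mauchly), `"always"` or
#'   `"never"`.
#' @return An `ms_stat` with the F statistic, (possibly fractional,
#'   corrected) degrees of freedom, p value, partial eta squared, Mauchly W
#'   and p, both epsilons and the correction applied. Supports [tidy()] and
#'   [glance()].
#' @examples
#' x <- matrix(rnorm(18), 6, 3)
#' rm_anova_oneway(x)
#' @export
rm_anova_oneway <- function(data, sphericity = c("auto", "always", "never")) {
  sphericity <- match.arg(sphericity)
  x <- as_wide_matrix(data)
  n <- nrow(x)
  m <- ncol(x)
  if (m < 2) stop_input("need at least 2 conditions.")
  if (n < 3) stop_input("need at least 3 subjects.")

  grand <- mean(x)
  col_m <- colMeans(x)
  row_m <- rowMeans(x)
  ss_cond <- n * sum((col_m - grand)^2)
  ss_subj <- m * sum((row_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- m - 1
  df2 <- (n - 1) * (m - 1)
  f_stat <- if (ss_err <= .Machine$double.eps * ss_tot) {
    ## no residual variance: F is 0 when conditions do not differ, else infinite
    if (ss_cond <= .Machine$double.eps * max(ss_tot, 1)) 0 else Inf
  } else {
    (ss_cond / df1) / (ss_err / df2)
  }

  ## Mauchly's W on the covariance of orthonormal contrasts
  cm <- orthonormal_contrasts(m)
  s_c <- crossprod(cm, stats::cov(x)) %*% cm
  p_dim <- m - 1
  ev <- eigen(s_c, symmetric = TRUE, only.values = TRUE)$values
  singular <- n - 1 < p_dim || any(ev <= .Machine$double.eps * max(ev))
  if (!singular) {
    w <- det(s_c) / (sum(diag(s_c)) / p_dim)^p_dim
    chi <- -(n - 1 - (2 * p_dim^2 + p_dim + 2) / (6 * p_dim)) * log(w)
    df_w <- p_dim * (p_dim + 1) / 2 - 1
    mauchly_p <- if (df_w > 0) stats::pchisq(chi, df_w, lower.tail = FALSE) else 1
  } else {
    w <- NA_real_
    mauchly_p <- NA_real_
  }
  gg <- sum(diag(s_c))^2 / (p_dim * sum(s_c^2))
  if (!is.finite(gg)) gg <- NA_real_
  hf <- (n * p_dim * gg - 2) / (p_dim * (n - 1 - p_dim * gg))
  hf <- if (is.na(gg)) NA_real_ else min(1, max(hf, gg))

  apply_corr <- switch(sphericity,
    always = TRUE,
    never = FALSE,
    auto = !is.na(mauchly_p) && mauchly_p < 0.05
  )
  if (is.na(gg)) apply_corr <- FALSE
  if (apply_corr) {
    eps <- if (gg > 0.75) hf else gg
    correction <- if (gg > 0.75) "HF" else "GG"
  } else {
    eps <- 1
    correction <- "none"
  }
  p_value <- stats::pf(f_stat, df1 * eps, df2 * eps, lower.tail = FALSE)

  new_ms_stat(
    test = "rm_anova_oneway", statistic = f_stat,
    df = c(df1 = df1 * eps, df2 = df2 * eps),
    df_uncorrected = c(df1 = df1, df2 = df2),
    p_value = p_value,
    effect_size = ss_cond / (ss_cond + ss_err), effect_type = "partial_eta_sq",
    mauchly_w = w, mauchly_p = mauchly_p, gg_epsilon = gg, hf_epsilon = hf,
    epsilon = eps, correction = correction,
    n = n, m = m, ss = c(condition = ss_cond, subject = ss_subj, error = ss_err),
    groups = colnames(x) %||% paste0("cond", seq_len(m))
  )
}

#' Friedman rank test for repeated measures
#'
#' Rank-based chi-squared omnibus test over `m` conditions within subjects
#' (mid-ranks for ties), the nonparametric alternative used when normality
#' fails. With `exact = TRUE` (tie-free data, `(m!)^n` small) the p value is
#' computed from the exact permutation null distribution over all rank
#' configurations; otherwise from the chi-squared approximation with
#' `df = m - 1`.
#'
#' @param data Subjects x conditions matrix or data frame.
#' @param exact Compute the exact enumeration p value (default FALSE).
#' @return An `ms_stat` with the chi-squared statistic, df, p value, and
#'   Kendall's W as effect size.
#' @export
friedman_rm <- function(data, exact = FALSE) {
  x <- as_wide_matrix(data)
  n <- nrow(x)
  m <- ncol(x)
  if (m < 2) stop_input("need at least 2 conditions.")
  ft <- stats::friedman.test(x)
  stat <- unname(ft$statistic)
  p_value <- ft$p.value
  if (!is.finite(stat)) {
    ## every row fully tied: mid-ranks carry no information
    stat <- 0
    p_value <- 1
  }
  method <- "asymptotic"
  if (exact) {
    ranks <- t(apply(x, 1, rank))
    if (any(apply(ranks, 1, anyDuplicated) > 0)) {
      stop_input("exact enumeration requires tie-free rows.")
    }
    if (factorial(m)^n > 2e6) stop_invalid("exact enumeration too large; use exact = FALSE.")
    p_value <- friedman_exact_p(ranks)
    method <- "exact"
  }
  new_ms_stat(
    test = "friedman", statistic = stat, df = c(df = m - 1), p_value = p_value,
    effect_size = stat / (n * (m - 1)), effect_type = "kendall_w",
    correction = "none", n = n, m = m, method = method,
    groups = colnames(x) %||% paste0("cond", seq_len(m))
  )
}

## Exact Friedman null: dynamic programme over subjects on the distribution
## of column rank-sum vectors; all (m!)^n rank configurations equally likely.
friedman_exact_p <- function(ranks) {
  n <- nrow(ranks)
  m <- ncol(ranks)
  stat_of <- function(colsums) {
    12 / (n * m * (m + 1)) * sum(colsums^2) - 3 * n * (m + 1)
  }
  observed <- stat_of(colSums(ranks))
  perms <- all_permutations(m)
  dist <- new.env(parent = emptyenv())
  assign(paste(rep(0L, m), collapse = ","), 1, envir = dist)
  for (s in seq_len(n)) {
    nxt <- new.env(parent = emptyenv())
    for (key in ls(dist)) {
      base <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
      cnt <- get(key, envir = dist)
      for (p in perms) {
        k2 <- paste(base + p, collapse = ",")
        prev <- if (exists(k2, envir = nxt, inherits = FALSE)) get(k2, envir = nxt) else 0
        assign(k2, prev + cnt, envir = nxt)
      }
    }
    dist <- nxt
  }
  total <- 0
  hits <- 0
  for (key in ls(dist)) {
    cs <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
    cnt <- get(key, envir = dist)
    total <- total + cnt
    if (stat_of(cs) >= observed - 1e-9) hits <- hits + cnt
  }
  hits / total
}

#' Paired comparison with normality gating
#'
#' Two-sided paired comparison of two repeated measurements. In `"auto"` mode
#' a Shapiro-Wilk test on the paired differences (alpha 0.05) dispatches to
#' the paired t-test (normal) or the Wilcoxon signed-rank test (non-normal).
#' The t branch reports Cohen's d_z = mean(diff)/sd(diff); the Wilcoxon
#' branch drops zero differences (Wilcoxon's convention), uses the exact
#' distribution for n <= 25 without ties and the normal approximation
#' otherwise, reports V (the sum of positive signed ranks) and the matched
#' pairs rank-biserial correlation.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param mode `"auto"` (default), `"t"` or `"wilcoxon"`.
#' @param alpha_normality Level of the Shapiro-Wilk gate (default 0.05).
#' @return An `ms_stat`.
#' @examples
#' paired_test(c(2, 4, 6), c(1, 2, 3), mode = "t") # t = 2 * sqrt(3)
#' @export
paired_test <- function(x, y, mode = c("auto", "t", "wilcoxon"),
                        alpha_normality = 0.05) {
  mode <- match.arg(mode)
  if (length(x) != length(y)) stop_input("`x` and `y` must have equal length.")
  if (length(x) < 3) stop_input("need at least 3 pairs.")
  d <- x - y
  if (mode == "auto") {
    sw_p <- if (stats::sd(d) == 0) 0 else stats::shapiro.test(d)$p.value
    mode <- if (sw_p < alpha_normality) "wilcoxon" else "t"
  }
  n <- length(d)
  if (mode == "t") {
    sd_d <- stats::sd(d)
    if (sd_d == 0) stop_undefined("zero-variance differences: paired t is undefined.")
    t_stat <- mean(d) / (sd_d / sqrt(n))
    new_ms_stat(
      test = "paired_t", statistic = t_stat, df = c(df = n - 1),
      p_value = 2 * stats::pt(-abs(t_stat), n - 1),
      effect_size = mean(d) / sd_d, effect_type = "cohen_dz",
      correction = "none", n = n, groups = c("x", "y")
    )
  } else {
    dnz <- d[d != 0]
    if (!length(dnz)) stop_undefined("all differences are zero: Wilcoxon has no data after dropping zeros.")
    nn <- length(dnz)
    ties <- anyDuplicated(abs(dnz)) > 0
    wt <- suppressWarnings(stats::wilcox.test(dnz, exact = (nn <= 25 && !ties)))
    v <- unname(wt$statistic)
    s_total <- nn * (nn + 1) / 2
    new_ms_stat(
      test = "wilcoxon_signed_rank", statistic = v, df = c(df = NA_real_),
      p_value = wt$p.value,
      effect_size = 2 * v / s_total - 1, effect_type = "rank_biserial",
      correction = "none", n = nn, n_dropped_zeros = n - nn,
      exact = (nn <= 25 && !ties), groups = c("x", "y")
    )
  }
}

#' Bonferroni-corrected pairwise post hocs
#'
#' Pairwise paired comparisons between all condition pairs of a
#' within-subject design, with each p value multiplied by the number of pairs
#' and clipped at 1.
#'
#' @param data Subjects x conditions matrix or data frame.
#' @param mode Dispatch mode passed to [paired_test()].
#' @return A tibble with one row per pair: groups, test, statistic, df, raw
#'   and Bonferroni-adjusted p, effect size.
#' @export
bonferroni_posthoc <- function(data, mode = "auto") {
  x <- as_wide_matrix(data)
  m <- ncol(x)
  labs <- colnames(x) %||% paste0("cond", seq_len(m))
  pairs <- utils::combn(m, 2)
  n_pairs <- ncol(pairs)
  purrr::map_dfr(seq_len(n_pairs), function(i) {
    a <- pairs[1, i]
    b <- pairs[2, i]
    st <- paired_test(x[, a], x[, b], mode = mode)
    tibble(
      group1 = labs[a], group2 = labs[b], test = st$test,
      statistic = st$statistic, df = unname(st$df[1]),
      p_value = st$p_value,
      p_adjusted = min(1, st$p_value * n_pairs),
      effect_size = st$effect_size, effect_type = st$effect_type,
      correction = "Bonferroni", n_comparisons = n_pairs
    )
  })
}

#' Power of a two-sided paired t-test
#'
#' Computed from the noncentral t distribution with `df = n - 1` and
#' noncentrality `d * sqrt(n)` (the standard convention for an effect size
#' d on paired differences).
#'
#' @param n Number of pairs.
#' @param d Effect size (mean difference / SD of differences).
#' @param alpha Significance level (default 0.05).
#' @param two_sided Two-sided test (default TRUE).
#' @return Power in `[0, 1]` (vectorized over `n`).
#' @export
power_paired_t <- function(n, d, alpha = 0.05, two_sided = TRUE) {
  df <- n - 1
  ncp <- d * sqrt(n)
  if (two_sided) {
    tc <- qt(1 - alpha / 2, df)
    pt(tc, df, ncp, lower.tail = FALSE) + pt(-tc, df, ncp)
  } else {
    tc <- qt(1 - alpha, df)
    pt(tc, df, ncp, lower.tail = FALSE)
  }
}

#' Required sample size for a paired t-test
#'
#' Smallest integer `n` whose [power_paired_t()] reaches the target power.
#'
#' @param d Effect size (> 0).
#' @param alpha Significance level.
#' @param power Target power in (0, 1).
#' @param two_sided Two-sided test (default TRUE).
#' @return Integer sample size.
#' @examples
#' required_n_paired_t(d = 0.5) # 34
#' @export
required_n_paired_t <- function(d, alpha = 0.05, power = 0.8, two_sided = TRUE) {
  if (d <= 0) stop_invalid("`d` must be > 0.")
  for (n in 2:1e6) {
    if (power_paired_t(n, d, alpha, two_sided) >= power) return(n)
  }
  abort("required n exceeds 1e6; effect size too small.", class = "microstates_divergence")
}

#' Power of a one-group within-factor repeated-measures ANOVA
#'
#' Noncentral-F power under the G*Power convention for a within factor with
#' `m` repeated measurements, correlation `rho` among them and nonsphericity
#' correction `eps`: `lambda = f^2 * N * m * eps / (1 - rho)`,
#' `df1 = (m - 1) * eps`, `df2 = (N - 1) * (m - 1) * eps`.
#'
#' @param n Number of subjects.
#' @param f Effect size f.
#' @param m Number of repeated measurements.
#' @param alpha Significance level.
#' @param rho Correlation among repeated measures.
#' @param eps Nonsphericity correction in `[1/(m-1), 1]`.
#' @return Power in `[0, 1]` (vectorized over `n`).
#' @export
power_rm_anova <- function(n, f, m, alpha = 0.05, rho = 0.5, eps = 1) {
  lambda <- f^2 * n * m * eps / (1 - rho)
  df1 <- (m - 1) * eps
  df2 <- (n - 1) * (m - 1) * eps
  pf(qf(1 - alpha, df1, df2), df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Required sample size for a within-factor repeated-measures ANOVA
#'
#' Smallest integer `N` whose [power_rm_anova()] reaches the target power.
#'
#' @inheritParams power_rm_anova
#' @param power Target power.
#' @return Integer sample size.
#' @examples
#' required_n_rm_anova(f = 0.25, m = 3) # 28
#' @export
required_n_rm_anova <- function(f, alpha = 0.05, power = 0.8, m = 3,
                                rho = 0.5, eps = 1) {
  if (f <= 0) stop_invalid("`f` must be > 0.")
  if (m < 2) stop_invalid("`m` must be >= 2.")
  if (rho < 0 || rho >= 1) stop_invalid("`rho` must lie in [0, 1).")
  if (eps < 1 / (m - 1) || eps > 1) stop_invalid("`eps` must lie in [1/(m-1), 1].")
  for (n in 2:1e6) {
    if (power_rm_anova(n, f, m, alpha, rho, eps) >= power) return(n)
  }
  abort("required n exceeds 1e6; effect size too small.", class = "microstates_divergence")
}

#' Gate frequency bands on mean global explained variance
#'
#' Bands whose mean GEV falls below the threshold are excluded from further
#' analysis (the conventional 70% GEV criterion); a band exactly at the
#' threshold is retained.
#'
#' @param gev_by_band Named numeric vector of mean GEV fractions in `[0, 1]`.
#' @param threshold Inclusion threshold (default 0.70).
#' @return Character vector of retained band names, with a per-band report
#'   tibble in attribute `"report"`.
#' @examples
#' gate_bands(c(theta = 0.77, alpha = 0.76, beta = 0.62, gamma = 0.55))
#' @export
gate_bands <- function(gev_by_band, threshold = 0.70) {
  if (any(gev_by_band < 0 | gev_by_band > 1)) stop_input("GEV fractions must lie in [0, 1].")
  included <- gev_by_band >= threshold
  out <- names(gev_by_band)[included]
  attr(out, "report") <- tibble(
    band = names(gev_by_band), mean_gev = unname(gev_by_band),
    threshold = threshold, included = unname(included)
  )
  out
}
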