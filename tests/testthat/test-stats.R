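# Parse the GG / HF epsilons that anova.mlm prints in its heading — an
# independent implementation of the sphericity corrections in base R.
mlm_epsilons <- function(x) {
  fit <- stats::lm(x ~ 1)
  a <- stats::anova(fit, X = ~1, test = "Spherical")
  head_txt <- attr(a, "heading")
  gg <- as.numeric(sub(".*Greenhouse-Geisser epsilon:\\s+([0-9.]+).*", "\\1",
    paste(head_txt, collapse = " ")
  ))
  hf <- as.numeric(sub(".*Huynh-Feldt epsilon:\\s+([0-9.]+).*", "\\1",
    paste(head_txt, collapse = " ")
  ))
  list(gg = gg, hf = hf)
}

test_that("RM-ANOVA matches the aov() decomposition on random data", {
  set.seed(101)
  for (rep in 1:10) {
    n <- sample(5:9, 1)
    m <- sample(3:4, 1)
    x <- matrix(rnorm(n * m, mean = rep(rnorm(m, sd = 0.5), each = n)), n, m)
    st <- rm_anova_oneway(x, sphericity = "never")
    long <- data.frame(
      y = as.vector(x),
      cond = factor(rep(seq_len(m), each = n)),
      subj = factor(rep(seq_len(n), m))
    )
    sm <- summary(stats::aov(y ~ cond + Error(subj), data = long))
    tab <- sm[["Error: Within"]][[1]]
    expect_equal(st$statistic, tab["cond", "F value"], tolerance = 1e-8)
    expect_equal(st$p_value, tab["cond", "Pr(>F)"], tolerance = 1e-8)
    expect_equal(unname(st$df_uncorrected), c(m - 1, (n - 1) * (m - 1)))
    # partial eta squared from the same table
    expect_equal(
      st$effect_size,
      tab["cond", "Sum Sq"] / (tab["cond", "Sum Sq"] + tab["Residuals", "Sum Sq"]),
      tolerance = 1e-10
    )
  }
})

test_that("epsilons agree with anova.mlm and respect their bounds", {
  set.seed(102)
  for (rep in 1:8) {
    n <- sample(6:10, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    x[, 1] <- x[, 1] * sample(c(1, 3), 1) # provoke nonsphericity sometimes
    st <- rm_anova_oneway(x)
    eps <- mlm_epsilons(x)
    expect_equal(st$gg_epsilon, eps$gg, tolerance = 1e-3)
    expect_equal(min(st$hf_epsilon, 1), min(eps$hf, 1), tolerance = 1e-3)
    # bounds: 1/(m-1) <= GG eps <= 1 for m = 3
    expect_gte(st$gg_epsilon, 0.5 - 1e-12)
    expect_lte(st$gg_epsilon, 1 + 1e-12)
    # Mauchly's W agrees with base mauchly.test
    mt <- stats::mauchly.test(stats::lm(x ~ 1), X = ~1)
    expect_equal(unname(st$mauchly_w), unname(mt$statistic), tolerance = 1e-8)
    expect_equal(st$mauchly_p, mt$p.value, tolerance = 1e-6)
  }
})

test_that("the sphericity rule picks HF above GG eps 0.75 and GG below", {
  set.seed(103)
  found <- c(GG = FALSE, HF = FALSE)
  for (rep in 1:200) {
    n <- 6
    x <- matrix(rnorm(n * 3), n, 3)
    x[, 1] <- x[, 1] * 4
    x[, 2] <- x[, 2] * 0.25
    st <- rm_anova_oneway(x)
    if (!is.na(st$mauchly_p) && st$mauchly_p < 0.05) {
      expected <- if (st$gg_epsilon > 0.75) "HF" else "GG"
      expect_equal(st$correction, expected)
      eps_used <- if (expected == "HF") st$hf_epsilon else st$gg_epsilon
      expect_equal(unname(st$df["df1"]), 2 * eps_used)
      found[expected] <- TRUE
    } else {
      expect_equal(st$correction, "none")
    }
    if (all(found)) break
  }
  expect_true(any(found)) # the rule was exercised at least once
})

test_that("degenerate inputs: identical conditions give F = 0, p = 1", {
  x <- matrix(rep(rnorm(5), 3), 5, 3) # each subject constant across conditions
  st <- rm_anova_oneway(x)
  expect_equal(st$statistic, 0)
  expect_equal(st$p_value, 1)
  expect_error(rm_anova_oneway(matrix(c(1, NA, 2, 3, 4, 5), 2)), class = "microstates_invalid_input")
})

test_that("for m = 2 the RM-ANOVA F equals the squared paired t", {
  set.seed(104)
  for (rep in 1:10) {
    x <- matrix(rnorm(16), 8, 2)
    st_f <- rm_anova_oneway(x, sphericity = "never")
    st_t <- paired_test(x[, 1], x[, 2], mode = "t")
    expect_equal(st_f$statistic, st_t$statistic^2, tolerance = 1e-8)
    expect_equal(st_f$p_value, st_t$p_value, tolerance = 1e-8)
  }
})

test_that("Friedman: perfect concordance and degenerate cases", {
  # all subjects rank the three conditions identically: chi^2 = 2n
  for (n in c(5, 12, 30)) {
    x <- matrix(rep(c(1, 2, 3), each = n), n, 3) + rep(rnorm(n, sd = 0.01), 3)
    st <- friedman_rm(x)
    expect_equal(st$statistic, 2 * n, tolerance = 1e-10)
    expect_equal(unname(st$df), 2)
    # Kendall's W = 1 under perfect agreement
    expect_equal(st$effect_size, 1, tolerance = 1e-10)
  }
  # equal values within every subject: chi^2 = 0 (mid-ranks)
  x0 <- matrix(5, 4, 3) + rep(rnorm(4), 3)
  expect_equal(friedman_rm(x0)$statistic, 0)
})

test_that("Friedman exact p matches brute-force enumeration at n = 5, m = 3", {
  set.seed(105)
  x <- matrix(rnorm(15), 5, 3)
  st <- friedman_rm(x, exact = TRUE)
  ranks <- t(apply(x, 1, rank))
  obs <- 12 / (5 * 3 * 4) * sum(colSums(ranks)^2) - 3 * 5 * 4
  # brute force over all (3!)^5 rank configurations
  perms <- matrix(c(1, 2, 3, 1, 3, 2, 2, 1, 3, 2, 3, 1, 3, 1, 2, 3, 2, 1), 6, 3, byrow = TRUE)
  grid <- expand.grid(rep(list(1:6), 5))
  stats_null <- apply(grid, 1, function(idx) {
    cs <- colSums(perms[idx, , drop = FALSE])
    12 / (5 * 3 * 4) * sum(cs^2) - 3 * 5 * 4
  })
  p_exact <- mean(stats_null >= obs - 1e-9)
  expect_equal(st$p_value, p_exact, tolerance = 1e-12)
  # and the asymptotic branch matches base R
  expect_equal(
    friedman_rm(x)$p_value,
    stats::friedman.test(x)$p.value,
    tolerance = 1e-12
  )
})

test_that("paired test: hand-computed t branch values", {
  st <- paired_test(c(2, 4, 6), c(1, 2, 3), mode = "t") # diffs 1, 2, 3
  expect_equal(st$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(unname(st$df), 2)
  expect_equal(st$effect_size, 2.0)
  expect_equal(st$effect_type, "cohen_dz")
  # agrees with t.test
  tt <- stats::t.test(c(2, 4, 6), c(1, 2, 3), paired = TRUE)
  expect_equal(st$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(st$p_value, tt$p.value, tolerance = 1e-12)
  # zero mean difference: t = 0, p = 1
  st0 <- paired_test(c(1, 2, 3), c(3, 2, 1), mode = "t")
  expect_equal(st0$statistic, 0)
  expect_equal(st0$p_value, 1)
  # zero-variance differences are undefined for t
  expect_error(paired_test(c(1, 2, 3), c(0, 1, 2), mode = "t"),
    class = "microstates_undefined_result"
  )
})

test_that("Wilcoxon branch: exact p for all-positive ranks and zero handling", {
  x <- c(1.2, 2.3, 0.8, 1.9, 1.1, 2.8)
  st <- paired_test(x, rep(0, 6), mode = "wilcoxon")
  expect_equal(st$p_value, 2 / 2^6) # 0.03125, exact two-sided
  expect_equal(st$statistic, 21) # sum of all positive ranks, n = 6
  expect_equal(st$effect_size, 1) # rank-biserial: all positive
  expect_true(st$exact)
  # all-zero differences leave no data after dropping zeros
  expect_error(paired_test(1:5, 1:5, mode = "wilcoxon"),
    class = "microstates_undefined_result"
  )
  # zeros are dropped, remaining pairs analysed
  st2 <- paired_test(c(1, 2, 3, 4), c(1, 2, 0, 0), mode = "wilcoxon")
  expect_equal(st2$n, 2)
  expect_equal(st2$n_dropped_zeros, 2)
})

test_that("auto mode dispatches on Shapiro-Wilk normality of differences", {
  set.seed(106)
  d_norm <- rnorm(20)
  st1 <- paired_test(d_norm + 1:20, as.numeric(1:20))
  expect_equal(st1$test, "paired_t")
  d_skew <- c(rep(0.01, 15), 40, 55, 60, 70, 90) # grossly non-normal
  st2 <- paired_test(d_skew + 1:20, as.numeric(1:20))
  expect_equal(st2$test, "wilcoxon_signed_rank")
})

test_that("Bonferroni post hocs multiply p by the number of pairs and clip", {
  set.seed(107)
  x <- matrix(rnorm(24), 8, 3)
  colnames(x) <- c("negative", "neutral", "positive")
  ph <- bonferroni_posthoc(x, mode = "t")
  expect_equal(nrow(ph), 3)
  expect_equal(unique(ph$n_comparisons), 3)
  expect_equal(ph$p_adjusted, pmin(1, ph$p_value * 3))
  expect_true(all(ph$p_adjusted <= 1))
  big <- ph$p_value > 1 / 3
  expect_true(all(ph$p_adjusted[big] == pmin(1, ph$p_value[big] * 3)))
})

test_that("sample sizes reproduce the noncentral-distribution values", {
  expect_identical(required_n_paired_t(d = 0.5, alpha = 0.05, power = 0.8), 34L)
  expect_identical(
    required_n_rm_anova(f = 0.25, alpha = 0.05, power = 0.8, m = 3, rho = 0.5, eps = 1),
    28L
  )
})

test_that("required n inverts the power function exactly and is monotone", {
  for (d in c(0.3, 0.5, 0.8)) {
    n <- required_n_paired_t(d = d)
    expect_gte(power_paired_t(n, d), 0.8)
    expect_lt(power_paired_t(n - 1, d), 0.8)
  }
  ns <- vapply(c(0.2, 0.35, 0.5, 0.8), function(d) required_n_paired_t(d = d), integer(1))
  expect_true(all(diff(ns) <= 0))
  # required N non-increasing in the repeated-measures correlation
  Ns <- vapply(c(0.2, 0.5, 0.8), function(r) required_n_rm_anova(f = 0.25, rho = r), integer(1))
  expect_true(all(diff(Ns) <= 0))
  n_rm <- required_n_rm_anova(f = 0.25)
  expect_gte(power_rm_anova(n_rm, 0.25, 3), 0.8)
  expect_lt(power_rm_anova(n_rm - 1, 0.25, 3), 0.8)
})

test_that("Monte-Carlo power at the returned n matches the noncentral formula", {
  # paired t, d = 0.5, n = 34: simulate rejection rate
  set.seed(108)
  n <- 34
  reps <- 20000
  x <- matrix(rnorm(n * reps, mean = 0.5, sd = 1), n, reps)
  tstat <- colMeans(x) / (apply(x, 2, sd) / sqrt(n))
  rej <- mean(abs(tstat) > qt(0.975, n - 1))
  expect_equal(rej, power_paired_t(n, 0.5), tolerance = 0.02)

  # within-factor ANOVA, f = 0.25, N = 28, compound symmetry rho = 0.5
  N <- 28
  m <- 3
  reps2 <- 4000
  sd_between <- sqrt(0.5)
  sd_within <- sqrt(0.5)
  mu <- c(-1, 0, 1)
  mu <- mu / sqrt(mean((mu - mean(mu))^2)) * 0.25 # effect size f on sd = 1 scale
  rej2 <- mean(vapply(seq_len(reps2), function(i) {
    subj <- rnorm(N, sd = sd_between)
    x <- outer(subj, rep(1, m)) + matrix(rnorm(N * m, sd = sd_within), N, m) +
      outer(rep(1, N), mu)
    rm_anova_oneway(x, sphericity = "never")$p_value < 0.05
  }, logical(1)))
  expect_equal(rej2, power_rm_anova(N, 0.25, 3, rho = 0.5), tolerance = 0.04)
})

test_that("band gating keeps bands at or above the GEV threshold", {
  got <- gate_bands(c(theta = 0.77, alpha = 0.76, beta = 0.62, gamma = 0.55))
  expect_equal(as.character(got), c("theta", "alpha"))
  rep_tbl <- attr(got, "report")
  expect_equal(rep_tbl$included, c(TRUE, TRUE, FALSE, FALSE))
  all_in <- gate_bands(c(theta = 0.9, alpha = 0.8))
  expect_length(all_in, 2)
  # boundary: exactly at threshold is retained
  expect_equal(as.character(gate_bands(c(a = 0.70, b = 0.699))), "a")
  expect_error(gate_bands(c(a = 1.2)), class = "microstates_invalid_input")
})
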