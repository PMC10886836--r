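test_that("sorting finds the optimal permutation, not the greedy one", {
  tpl <- make_templates(20, 4, seed = 2)
  # already aligned -> identity
  s1 <- sort_templates(tpl, tpl)
  expect_equal(attr(s1, "permutation"), 1:4)
  # reversed order -> reversing permutation
  rev_set <- template_set(tpl$maps[, 4:1])
  s2 <- sort_templates(rev_set, tpl)
  expect_equal(attr(s2, "permutation"), 4:1)
  expect_equal(unname(abs(diag(spatial_correlation(s2$maps, tpl$maps)))), rep(1, 4))

  # instance where greedy matching fails: maps are mixtures whose pairwise
  # correlations reward a non-greedy assignment
  b <- make_templates(12, 3, seed = 9)$maps
  mix <- cbind(
    0.9 * b[, 1] + sqrt(1 - 0.81) * b[, 2], # close to template 1
    0.95 * b[, 1] + sqrt(1 - 0.9025) * b[, 3], # even closer to template 1
    b[, 2]
  )
  set <- template_set(normalize_maps(mix))
  ref <- template_set(b)
  got <- sort_templates(set, ref)
  # brute force over all 6 permutations
  cmat <- spatial_correlation(set$maps, ref$maps)
  perms <- list(
    c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
    c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)
  )
  scores <- vapply(perms, function(p) sum(cmat[cbind(p, 1:3)]), numeric(1))
  expect_equal(attr(got, "permutation"), perms[[which.max(scores)]])
  # greedy (pick the best match for reference slot 1 first) would take map 2
  greedy_first <- which.max(cmat[, 1])
  expect_false(identical(attr(got, "permutation")[1], greedy_first))
})

test_that("sorting composed with its inverse is the identity", {
  tpl <- make_templates(16, 4, seed = 4)
  perm <- c(3, 1, 4, 2)
  shuffled <- template_set(tpl$maps[, perm] * rep(c(-1, 1, -1, 1), each = 16))
  sorted <- sort_templates(shuffled, tpl)
  expect_equal(unname(abs(diag(spatial_correlation(sorted$maps, tpl$maps)))),
    rep(1, 4),
    tolerance = 1e-12
  )
  expect_equal(attr(sorted, "permutation")[perm], 1:4)
})

test_that("averaging template sets is idempotent and polarity invariant", {
  tpl <- make_templates(24, 4, seed = 6)
  avg <- average_template_sets(list(tpl, tpl))
  expect_equal(unname(abs(diag(spatial_correlation(avg$maps, tpl$maps)))),
    rep(1, 4),
    tolerance = 1e-12
  )
  flipped <- template_set(tpl$maps * rep(c(-1, 1, 1, -1), each = 24))
  avg2 <- average_template_sets(list(tpl, flipped))
  expect_equal(avg2$maps, avg$maps, tolerance = 1e-12)
  expect_error(
    average_template_sets(list(tpl, template_set(tpl$maps[, 1:2]))),
    class = "microstates_invalid_configuration"
  )
})

test_that("averaging noisy sets beats the median single set", {
  set.seed(51)
  truth <- make_templates(30, 4, seed = 12)
  noisy <- lapply(1:20, function(i) {
    m <- truth$maps + matrix(rnorm(30 * 4, sd = 0.15), 30, 4)
    template_set(normalize_maps(m))
  })
  avg <- average_template_sets(noisy, reference = truth)
  avg_corr <- mean(diag(spatial_correlation(sort_templates(avg, truth)$maps, truth$maps)))
  single_corrs <- vapply(noisy, function(s) {
    mean(diag(spatial_correlation(sort_templates(s, truth)$maps, truth$maps)))
  }, numeric(1))
  expect_gt(avg_corr, stats::median(single_corrs))
})

test_that("level tags promote along the hierarchy", {
  tpl <- make_templates(10, 2, seed = 3)
  trialish <- template_set(tpl$maps, level = "trial")
  cond <- average_template_sets(list(trialish, trialish))
  expect_equal(cond$level, "condition")
  glob <- average_template_sets(list(cond, cond))
  expect_equal(glob$level, "global")
})

test_that("backfit labels by absolute correlation and flags zero-GFP samples", {
  tpl <- make_templates(15, 4, seed = 7)
  # every sample is template B at arbitrary nonzero scales and signs
  scales <- c(-3, 0.5, 2, -0.1, 7)
  e <- eeg_epoch(tpl$maps[, 2, drop = FALSE] %*% t(scales), sfreq = 100)
  lab <- backfit(e, tpl)
  expect_equal(unclass(lab), rep(2L, 5), ignore_attr = TRUE)
  # all-zero epoch -> all unassigned
  z <- eeg_epoch(matrix(0, 15, 5), sfreq = 100)
  expect_true(all(is.na(unclass(backfit(z, tpl)))))
  # channel mismatch
  e2 <- eeg_epoch(matrix(rnorm(20), 10, 2), sfreq = 100)
  expect_error(backfit(e2, tpl), class = "microstates_dimension_error")
})

test_that("backfit is invariant to global sign and positive scaling of the epoch", {
  cfg <- sim_config(n_channels = 20, snr = 8)
  tpl <- make_templates(20, 4, seed = 8)
  s <- sample_state_sequence(cfg, 1, seed = 13)
  e <- synthesize_epoch(tpl, s, cfg, seed = 14)$epoch
  base <- unclass(backfit(e, tpl))
  for (fac in c(-1, 0.25, 40)) {
    e2 <- e
    e2$data <- e$data * fac
    expect_identical(unclass(backfit(e2, tpl)), base)
  }
})

test_that("peak-propagation backfit matches planted labels at peaks and fills between", {
  cfg <- sim_config(n_channels = 30, snr = 16)
  tpl <- make_templates(30, 4, seed = 9)
  s <- sample_state_sequence(cfg, 2, seed = 15)
  e <- synthesize_epoch(tpl, s, cfg, seed = 16)$epoch
  lab <- backfit(e, tpl, peaks_only = TRUE)
  v <- unclass(lab)
  pk <- gfp_peaks(gfp(e))
  expect_true(all(!is.na(v[pk])))
  samplewise <- unclass(backfit(e, tpl))
  expect_equal(v[pk], samplewise[pk])
  # between peaks the label is constant until the midpoint to the next peak
  mid <- floor((pk[1] + pk[2]) / 2)
  expect_true(all(v[pk[1]:mid] == v[pk[1]]))
  # agreement with planted sequence at peaks is high at this snr
  expect_gt(mean(v[pk] == s[pk]), 0.9)
})

test_that("hierarchy round trip reproduces planted labels on separable data", {
  cfg <- sim_config(
    n_channels = 30, snr = 8, n_subjects = 3,
    n_trials_per_condition = 2, seed = 17
  )
  study <- generate_study(cfg)
  # baseline removal is off: the nonnegative synthetic carrier stores
  # topography in the per-channel mean (see the methods vignette)
  run <- run_pipeline(pipeline_config(seed = 17, baseline = FALSE), study = study)
  br <- run$bands[[1]]
  # global templates recover the planted ones
  aligned <- sort_templates(br$global_set, study$templates)
  expect_gt(min(diag(spatial_correlation(aligned$maps, study$templates$maps))), 0.98)
  # trial label sequences agree with planted states at GFP peaks
  agree <- vapply(seq_len(nrow(study$epochs)), function(i) {
    e <- study$epochs$epoch[[i]]
    s <- study$epochs$states[[i]]
    pk <- gfp_peaks(gfp(e))
    lab <- unclass(br$labels[[i]])
    # map estimated classes onto planted classes through the global alignment
    cond_set <- br$condition_sets[[study$epochs$condition[i]]]
    perm <- attr(sort_templates(cond_set, study$subject_templates[[
      match(study$epochs$subject[i], unique(study$epochs$subject))
    ]]), "permutation")
    to_planted <- match(seq_along(perm), perm)
    mean(to_planted[lab[pk]] == s[pk], na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean(agree > 0.9), 0.99)
})
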