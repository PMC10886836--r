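test_that("planted templates are orthonormal, zero-mean, and deterministic", {
  ts <- make_templates(59, 4, seed = 1)
  expect_equal(dim(ts$maps), c(59, 4))
  expect_lt(max(abs(colMeans(ts$maps))), 1e-10)
  gram <- crossprod(ts$maps)
  expect_lt(max(abs(gram - diag(4))), 1e-10)
  ts2 <- make_templates(59, 4, seed = 1)
  expect_identical(ts$maps, ts2$maps)
  expect_false(identical(ts$maps, make_templates(59, 4, seed = 2)$maps))
})

test_that("more orthogonal zero-mean maps than the subspace admits is rejected", {
  # the average-referenced subspace of R^4 is 3-dimensional
  expect_error(make_templates(4, 4), class = "microstates_invalid_configuration")
  expect_silent(make_templates(5, 4))
})

test_that("config invariants are enforced", {
  bad <- matrix(c(0, 0.5, 0.5, 0.3, 0, 0.7, 0.2, 0.2, 0.59), 3, 3, byrow = TRUE)
  expect_error(
    sim_config(n_states = 3, transition_matrix = bad),
    class = "microstates_invalid_configuration"
  )
  with_diag <- matrix(1 / 3, 3, 3)
  expect_error(
    sim_config(n_states = 3, transition_matrix = with_diag),
    class = "microstates_invalid_configuration"
  )
  expect_error(sim_config(snr = 0), class = "microstates_invalid_configuration")
  expect_error(sim_config(dwell_ms = -5), class = "microstates_invalid_configuration")
  expect_error(sim_config(n_subjects = 0), class = "microstates_invalid_configuration")
})

test_that("a deterministic cycle chain produces exactly periodic state order", {
  cyc <- matrix(0, 4, 4)
  cyc[cbind(1:4, c(2, 3, 4, 1))] <- 1
  cfg <- sim_config(transition_matrix = cyc, dwell_ms = 100, condition_params = list())
  s <- sample_state_sequence(cfg, 2, seed = 11)
  runs <- rle(s)$values
  expected_next <- c(2L, 3L, 4L, 1L)
  expect_true(all(runs[-1] == expected_next[runs[-length(runs)]]))
  expect_true(all(rle(s)$lengths >= 1))
})

test_that("empirical transition frequencies and dwell converge to planted values", {
  cfg <- sim_config(dwell_ms = 100, condition_params = list())
  s <- sample_state_sequence(cfg, 10000, seed = 42)
  r <- rle(s)
  # mean dwell within 5 percent of 100 ms (25 samples at 250 Hz)
  expect_lt(abs(mean(r$lengths) / 25 - 1), 0.05)
  # successor frequencies within 0.02 of the uniform 1/3
  from <- r$values[-length(r$values)]
  to <- r$values[-1]
  for (i in 1:4) {
    emp <- table(factor(to[from == i], levels = 1:4)) / sum(from == i)
    expect_lt(max(abs(emp[-i] - 1 / 3)), 0.02)
  }
  # no self-transitions ever
  expect_true(all(from != to))
})

test_that("noise-free epochs reproduce the active template exactly at carrier peaks", {
  cfg <- sim_config(n_channels = 20, snr = Inf)
  ts <- make_templates(20, 4, seed = 5)
  s <- sample_state_sequence(cfg, 2, seed = 6)
  syn <- synthesize_epoch(ts, s, cfg, seed = 7)
  # average reference holds at every sample
  expect_lt(max(abs(colMeans(syn$epoch$data))), 1e-10)
  g <- gfp(syn$epoch)
  pk <- gfp_peaks(g)
  expect_gt(length(pk), 30)
  for (p in pk) {
    r <- spatial_correlation(syn$epoch$data[, p], ts$maps[, s[p]])
    expect_equal(r, 1.0, tolerance = 1e-8)
  }
})

test_that("back-fitting true templates recovers peak-sample labels at snr 4", {
  cfg <- sim_config(n_channels = 59, snr = 4)
  ts <- make_templates(59, 4, seed = 8)
  hits <- 0
  total <- 0
  for (i in 1:20) {
    s <- sample_state_sequence(cfg, 2, seed = 100 + i)
    syn <- synthesize_epoch(ts, s, cfg, seed = 200 + i)
    pk <- gfp_peaks(gfp(syn$epoch))
    lab <- unclass(backfit(syn$epoch, ts))
    hits <- hits + sum(lab[pk] == s[pk], na.rm = TRUE)
    total <- total + length(pk)
  }
  expect_gt(hits / total, 0.95)
})

test_that("epoch synthesis validates dimensions and state values", {
  cfg <- sim_config(n_channels = 10)
  ts <- make_templates(12, 4, seed = 1)
  s <- rep(1L, 100)
  expect_error(synthesize_epoch(ts, s, cfg), class = "microstates_dimension_error")
  cfg2 <- sim_config(n_channels = 12)
  expect_error(
    synthesize_epoch(ts, rep(9L, 10), cfg2),
    class = "microstates_invalid_input"
  )
})

test_that("generate_study books every cell and is reproducible from the seed", {
  cfg <- sim_config(
    n_channels = 16, n_subjects = 3, n_trials_per_condition = 2,
    epoch_s = 0.5, seed = 9
  )
  study <- generate_study(cfg)
  expect_equal(nrow(study$epochs), 3 * 3 * 2)
  expect_setequal(unique(study$epochs$condition), c("negative", "neutral", "positive"))
  # valence ratings consistent with the condition bins
  expect_true(all(
    as.character(categorize_valence(study$epochs$valence)) == study$epochs$condition
  ))
  # ground-truth labels match epoch lengths
  expect_true(all(
    vapply(seq_len(nrow(study$epochs)), function(i) {
      length(study$epochs$states[[i]]) == n_samples(study$epochs$epoch[[i]])
    }, logical(1))
  ))
  study2 <- generate_study(cfg)
  expect_identical(study$epochs$valence, study2$epochs$valence)
  expect_identical(study$epochs$epoch[[7]]$data, study2$epochs$epoch[[7]]$data)
  # subject rotation keeps templates orthonormal but distinct across subjects
  t1 <- study$subject_templates[[1]]$maps
  expect_lt(max(abs(crossprod(t1) - diag(4))), 1e-8)
  expect_false(identical(t1, study$subject_templates[[2]]$maps))
  # rotation angle is small: subject maps stay close to the base maps
  expect_gt(min(diag(spatial_correlation(t1, study$templates$maps))), 0.99)
})

test_that("study round-trips through plain-text files", {
  cfg <- sim_config(
    n_channels = 6, n_subjects = 1, n_trials_per_condition = 1,
    epoch_s = 0.4, seed = 3
  )
  study <- generate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(study, dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 3)
  e <- read_eeg_matrix(file.path(dir, man$file[1]), sfreq = cfg$sfreq)
  expect_equal(e$data, study$epochs$epoch[[1]]$data, tolerance = 1e-6)
  expect_true(file.exists(file.path(dir, "config.yaml")))
  truth <- read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(
    truth$state[truth$file == man$file[1]],
    study$epochs$states[[1]]
  )
})
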