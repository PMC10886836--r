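# Shared fixtures and independent oracles, built in code at test time.

# Enumerate all partitions of 1..n into exactly k non-empty blocks
# (restricted growth strings).
all_k_partitions <- function(n, k) {
  out <- list()
  rgs <- integer(n)
  recurse <- function(i, maxblock) {
    if (i > n) {
      if (maxblock == k) out[[length(out) + 1L]] <<- rgs[seq_len(n)]
      return(invisible())
    }
    for (b in seq_len(min(maxblock + 1L, k))) {
      rgs[i] <<- b
      recurse(i + 1L, max(maxblock, b))
    }
  }
  recurse(1L, 0L)
  out
}

# Best achievable GEV for a fixed partition: per cluster, the optimal
# polarity-invariant centroid is the principal eigenvector of the weighted
# outer-product sum, so the cluster's explained share is its top eigenvalue.
# Computed on the members' Gram matrix (t x t), which shares the nonzero
# spectrum with the channels x channels form but stays tiny.
oracle_partition_gev <- function(maps, weights, assignment) {
  total <- sum(weights^2)
  expl <- 0
  for (cl in unique(assignment)) {
    idx <- which(assignment == cl)
    uw <- maps[, idx, drop = FALSE] * rep(weights[idx], each = nrow(maps))
    g <- crossprod(uw)
    expl <- expl + eigen(g, symmetric = TRUE, only.values = TRUE)$values[1]
  }
  expl / total
}

# Canonical form of a partition label vector, for comparing partitions
# irrespective of block numbering.
canonical_partition <- function(assignment) {
  match(assignment, unique(assignment))
}

# A separable clustering instance: maps drawn around orthogonal templates
# with small perturbation and random sign flips.
make_separable_instance <- function(n_channels, k, n_maps, noise_sd = 0.05) {
  templates <- make_templates(n_channels, k)$maps
  truth <- sort(rep_len(seq_len(k), n_maps))
  maps <- sapply(truth, function(s) {
    v <- templates[, s] + rnorm(n_channels, sd = noise_sd)
    v <- v - mean(v)
    sample(c(-1, 1), 1) * v / sqrt(sum(v^2))
  })
  list(maps = maps, truth = truth, templates = templates,
       weights = runif(n_maps, 0.5, 2))
}

# Small deterministic epoch built from two antisymmetric channels patterns.
toy_epoch <- function(n = 100, sfreq = 100) {
  t <- seq_len(n) / sfreq
  data <- rbind(sin(2 * pi * 5 * t), -sin(2 * pi * 5 * t),
                cos(2 * pi * 5 * t), -cos(2 * pi * 5 * t))
  eeg_epoch(data, sfreq = sfreq)
}
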