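---
title: "Microstate analysis: model, design choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate analysis: model, design choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microstates)
```

## The model

EEG microstate analysis treats the multichannel scalp potential as a sequence
of quasi-stable topographies. The package implements the standard pipeline:

1. **Global field power.** For an average-referenced sample over N
   electrodes, `GFP(t)` is the uncorrected (population) standard deviation of
   the potentials across channels. It is invariant to a common offset and
   proportional to overall topographic signal strength. Topographies are most
   reliable at local GFP maxima, so only GFP-peak maps enter clustering.

2. **Polarity-invariant AAHC.** Atomize-and-agglomerate hierarchical
   clustering starts from singleton clusters and repeatedly dissolves one
   cluster, reassigning its maps to the surviving cluster of highest absolute
   spatial correlation (Pearson correlation of average-referenced maps, sign
   ignored). Centroids are sign-aligned, renormalized means of members.

3. **Template hierarchy.** Trial-level template sets are averaged (after
   optimal label alignment) into condition-level sets and those into a global
   set; condition sets are label-aligned to the global set, and back-fitted to
   each trial to produce a per-sample label sequence.

4. **Dynamics features.** Per class: mean run duration (ms), occurrence
   (runs per second of labelled time), coverage (% of labelled samples), and
   row-normalized transition probabilities between runs — 24 features for
   K = 4. Features are averaged per participant and condition.

5. **Statistics.** Duration/occurrence/coverage are compared across
   conditions with a normality-gated one-way repeated-measures ANOVA
   (Shapiro–Wilk per condition at alpha 0.05; Mauchly's test; sphericity
   correction by Huynh–Feldt epsilon when Greenhouse–Geisser epsilon exceeds
   0.75 and by Greenhouse–Geisser epsilon otherwise) or the Friedman test,
   with Bonferroni post hocs after significant omnibus tests. Transition
   probabilities are compared against the reference condition with two-sided
   paired t-tests or Wilcoxon signed-rank tests, again normality-gated.
   Sample-size calculators invert the noncentral-t and noncentral-F power
   functions under the G*Power conventions (`required_n_paired_t(d = 0.5)`
   gives 34; `required_n_rm_anova(f = 0.25, m = 3, rho = 0.5)` gives 28).

## The synthetic generator

`generate_study()` produces recordings with a fully known ground truth so
that every stage can be validated against planted parameters:

* `n_states = 4` orthonormal, zero-mean template maps over
  `n_channels = 59` channels (a 64-channel montage minus non-EEG leads);
* a first-order Markov state sequence with geometric run lengths
  (memoryless; the field's "approximately 100 ms" stability fixes only the
  mean, so the maximum-entropy dwell model is used) at per-condition mean
  dwell times — 140 ms (negative), 125 ms (neutral), 110 ms (positive) —
  spanning the range typically reported for affect studies;
* per-condition transition matrices: uniform for neutral; negative raises
  the A–D coupling to 0.5; positive weakens B–C coupling to 0.1 and raises
  D-to-C — mirroring the kind of condition-specific transition structure the
  statistics stage is meant to detect;
* a rectified 10 Hz sinusoid as amplitude carrier, so GFP maxima are dense
  (two per carrier cycle) and well defined;
* spatially smoothed Gaussian noise (circular moving average over the
  channel index, emulating the spatial smearing of volume conduction; iid
  noise by flag) scaled to a signal-to-noise RMS ratio `snr = 4`;
* per-subject random orthogonal rotations of the templates (maximum angle
  5 degrees) restricted to the zero-mean subspace, so cross-subject template
  averaging is nontrivial. No published estimate of inter-subject
  topographic variability was available; 5 degrees keeps within-class
  correlations near 0.996, comparable to the test-retest topography
  consistency reported for the canonical maps.
* integer valence ratings drawn from each condition's range (negative 1–3,
  neutral 4–5, positive 6–9), so the rating-to-condition categorization path
  is exercised.

What the generator does **not** emulate: volume-conducted source geometry
(no head model), ocular or muscle artifacts (amplitude rejection is tested
with injected out-of-range samples instead), line noise, non-geometric dwell
distributions, and 1/f background spectra. Passing recovery tests therefore
show that the pipeline is correct under its own assumptions, not that it is
robust to every property of real EEG.

## Design choices

* **AAHC victim selection.** The textbook shortcut dissolves the cluster
  with the smallest current GEV contribution. On 2-s epochs (~40 GFP-peak
  maps) that rule loses rare-but-real classes irrecoverably — a class seen in
  two short runs has a small total contribution even when its maps are
  identical, and once atomized it cannot re-form; in our simulations most
  trials lost a class this way even with noise-free data. The package
  therefore evaluates the *removal cost* — a cluster's contribution minus
  what its members would recover in the best surviving clusters — which is
  the literal reading of "the cluster whose disappearance costs the least".
  Duplicated clusters then dissolve first (cost ~ 0) and tight rare classes
  survive. Both rules are available (`criterion =` `"cost"` /
  `"contribution"`), and both attain the exhaustive-search GEV optimum on
  separable instances.
* **Back-fit template level.** Condition-level template sets, aligned to the
  global set, are back-fitted to every trial by default: labels are then
  comparable across trials and robust to single-trial clustering noise.
  Trial-level and global-level back-fitting are available via
  `pipeline_config(template_level =)`.
* **Back-fit mode.** `"samplewise"` labels every sample independently;
  `"peaks"` labels GFP peaks and propagates each label to the midpoints
  toward the neighbouring peaks. For amplitude-modulated data the samples
  between peaks carry almost no topographic signal, so peaks mode is the
  appropriate choice there; neither mode applies temporal smoothing unless
  requested (`smoothing`, off by default).
* **Baseline removal.** Subtracting each channel's epoch mean is the
  classical drift remover and the default. For the synthetic carrier —
  nonnegative by construction — the per-channel mean itself carries
  topographic information, and removing it folds a class-mixture map into
  every sample, corrupting low-amplitude topographies (peak-label accuracy
  dropped from 1.00 to 0.82 in our ground-truth measurements). Synthetic
  analyses therefore run with `baseline = FALSE`; with band-passed real EEG
  (zero DC) the step is harmless and stays on.
* **Occurrence denominator** is labelled time, not epoch time, so unassigned
  samples do not dilute rates. Terminal runs have no outgoing transition and
  are excluded from transition denominators; unassigned gaps split runs and
  break transition adjacency; boundary-truncated runs are included in
  duration/occurrence/coverage (excludable by flag). Run start indices are
  1-based, following R convention.
* **GFP peaks** are strict local maxima; a flat plateau counts once, at its
  first sample; endpoints are never peaks. `min_separation` (default 1
  sample) greedily keeps the taller of two close peaks — with an amplitude
  carrier, genuine maxima cannot be closer than the carrier half-period.
* **Sphericity rule.** Corrections are applied when Mauchly's test is
  significant at 0.05 ("where necessary"); `sphericity = "always"/"never"`
  override. Effect sizes: partial eta squared (ANOVA), Kendall's W
  (Friedman), Cohen's d_z (paired t), matched-pairs rank-biserial
  correlation (Wilcoxon, zeros dropped per Wilcoxon's convention, exact null
  for n <= 25 without ties). No multiplicity adjustment is applied across
  the 12 transition features by default; Holm is available behind a flag.
* **Exact Friedman p values** (`exact = TRUE`) come from a dynamic programme
  over per-subject rank permutations, feasible for `(m!)^n` up to about two
  million; ties fall back to the asymptotic chi-squared form.

## Numerical choices

* Filters are linear-phase Hamming-window FIR band-passes applied as a
  centred convolution after reflection padding (exactly zero phase); the
  length scales with the transition width (~3.3 cycles) and is capped so the
  padding fits the epoch. Out-of-band attenuation is at least 20 dB and
  in-band ripple below 1 dB by construction.
* Maps are normalized to zero mean and unit norm before any correlation;
  zero-GFP samples are unassignable and stay `NA`.
* Label alignment uses exhaustive assignment over permutations (exact for
  K <= 8); ties in AAHC break toward the lower cluster index, making every
  stage deterministic for a given seed.
* Template averaging aligns members to the highest-GEV member, then performs
  one re-alignment pass against the provisional mean.

## Validation scale

The test suite validates GFP against the population-SD identity (1000 random
samples), AAHC against exhaustive partition enumeration (60 separable
instances, up to 10/9/8 maps for K = 2/3/4), the statistics against
`aov()`/`anova.mlm()`/`t.test()`/exact enumerations, Monte-Carlo power at
the returned sample sizes, and the full pipeline against planted dynamics
over 40 simulation seeds (10 subjects x 3 conditions x 5 trials, 59
channels, 250 Hz, 2-s epochs, snr 4): seed-averaged transition estimates are
required to sit within ±0.05 of the planted probabilities entrywise, the
per-seed mean absolute error within 0.05 in at least 95% of seeds, and the
planted dwell ordering (negative slower than positive) to be recovered in at
least 95% of seeds. These sizes were chosen to exercise the estimator's bias
and variance at the scale of a realistic study.

## Known limitations

* No electrode-geometry-aware steps: bad-channel interpolation and
  topographic map plotting on a head layout need montage coordinates that
  plain channel labels do not provide.
* The artifact path is amplitude rejection only; ICA/PCA-based cleaning is a
  user-supplied hook (`clean_artifacts()`).
* AAHC is deterministic but order-dependent in principle; polarity-sensitive
  clustering and modified k-means are out of scope.
* Recordings are read from delimited text matrices; binary EEG formats are
  not parsed.
* Transition estimates from run sequences are slightly biased when true
  dwell times approach the label resolution (runs shorter than the distance
  between GFP peaks can be missed); the recovery suite quantifies this bias
  at study scale (< 0.05 per entry).
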