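test_that("synthetic speech envelopes are nonnegative, reproducible, syllable-paced", {
  e1 <- gen_speech_envelope(20, seed = 40)
  e2 <- gen_speech_envelope(20, seed = 40)
  expect_identical(e1$values, e2$values)
  expect_gte(min(e1$values), 0)
  expect_gt(mean(e1$values), 0)
  peaks <- vapply(1:10, function(s) {
    spectral_peak_hz(gen_speech_envelope(20, seed = s)$values, 150)
  }, numeric(1))
  expect_true(all(peaks >= 3 & peaks <= 6))
})

test_that("neural generator realizes coupling and alpha structure", {
  env <- gen_speech_envelope(15 * 2, seed = 41)
  ee <- segment_trials(env, epoch_s = 2)

  # kappa = 0: coherence sits at the independence floor (~1/(trials*tapers))
  br0 <- gen_neural(env, 15, 4, coupled_channels = 1:2, kappa = 0,
                    noise_exponent = 0, seed = 42)
  C0 <- band_average(coherence(mtm_cross_spectra(br0, ee)), c(1, 7))
  expect_lt(max(C0), 10 / (15 * 11))

  # strong coupling: coherence in the coupled patch exceeds 0.5 at the
  # envelope's dominant bins, and stays at floor elsewhere
  br1 <- gen_neural(env, 15, 4, coupled_channels = 1:2, kappa = 3,
                    noise_exponent = 0, seed = 43)
  est1 <- mtm_cross_spectra(br1, ee)
  C1 <- coherence(est1)
  # dominant syllable-band bin (1-2 Hz bins are dominated by DC leakage
  # of the nonnegative envelope through the 3 Hz taper window)
  syl <- which(est1$freqs >= 4 & est1$freqs <= 7)
  dom <- syl[which.max(est1$syy[syl])]
  expect_gt(min(C1[1:2, dom]), 0.5)
  expect_lt(max(band_average(C1, c(1, 7))[3:4]), 0.1)

  # doubling alpha amplitude quadruples alpha power in the alpha patch
  br_a1 <- gen_neural(env, 15, 4, alpha_channels = 3:4, alpha_gain = 1,
                      noise_exponent = 0, seed = 44)
  br_a2 <- gen_neural(env, 15, 4, alpha_channels = 3:4, alpha_gain = 2,
                      noise_exponent = 0, seed = 44)
  p1 <- alpha_power(mtm_cross_spectra(br_a1))
  p2 <- alpha_power(mtm_cross_spectra(br_a2))
  # subtract the (shared-seed) noise contribution before comparing
  osc1 <- p1[3:4] - p1[1:2]
  osc2 <- p2[3:4] - p2[1:2]
  expect_equal(unname(osc2 / osc1), c(4, 4), tolerance = 0.2)
})

test_that("behavioral generator respects its probabilities", {
  cfg <- sim_config(n_subjects = 40, seed = 50,
                    p_hit = c(1, 0.9, 0.8, 0.7, 0.6, 0.5))
  beh <- gen_behavior(cfg)
  expect_equal(nrow(beh), 40 * 6)
  rates <- tapply(beh$hit_rate, beh$level, mean)
  expect_true(all(beh$hit_rate[beh$level == 1] == 1))  # p = 1: all hits
  # p = 0.5: long-run rate within the binomial 99% CI
  n_draws <- 40 * cfg$behav_trials
  expect_lt(abs(rates[6] - 0.5), 2.58 * sqrt(0.25 / n_draws))
  # programmed ordering recovered in the means
  expect_true(all(diff(rates) < 0))
})

test_that("datasets are bit-reproducible and dimensioned by the config", {
  cfg <- sim_config(n_subjects = 2, n_trials = 3, grid = c(3, 3),
                    coupled_patch = 1:2, alpha_patch = 8:9, seed = 60)
  d1 <- make_dataset(cfg)
  d2 <- make_dataset(cfg)
  expect_identical(d1$neural[[2]][["voc5"]]$data, d2$neural[[2]][["voc5"]]$data)
  expect_identical(d1$behavior, d2$behavior)
  expect_equal(dim(d1$neural[[1]][["orig"]]$data), c(3L, 9L, 300L))
  expect_length(d1$neural, 2L)
  expect_length(d1$neural[[1]], 6L)
  expect_equal(dim(d1$envelope_epochs[[1]][["voc1"]]), c(3L, 300L))
  expect_length(d1$adjacency, 9L)
})

test_that("pipeline recovers the programmed condition orderings", {
  # group-mean coherence maximal at the middle (5-channel) condition and
  # group-mean alpha decreasing from clear to the 5-channel floor
  hits_coh <- 0
  hits_alpha <- 0
  n_seeds <- 4
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(n_subjects = 6, n_trials = 12, seed = 600 + s)
    ds <- make_dataset(cfg)
    k <- length(cfg$conditions)
    coh_mean <- matrix(0, 6, k)
    alpha_mean <- matrix(0, 6, k)
    for (su in 1:6) {
      for (co in seq_len(k)) {
        est <- mtm_cross_spectra(ds$neural[[su]][[co]],
                                 ds$envelope_epochs[[su]][[co]])
        coh_mean[su, co] <- mean(band_average(coherence(est),
                                              c(1, 7))[cfg$coupled_patch])
        alpha_mean[su, co] <- mean(alpha_power(est)[cfg$alpha_patch])
      }
    }
    gc_ <- colMeans(coh_mean)
    ga <- colMeans(alpha_mean)
    if (which.max(gc_) == 3L && gc_[1] < gc_[2] && gc_[6] < gc_[3]) {
      hits_coh <- hits_coh + 1
    }
    if (ga[1] > ga[2] && ga[2] > ga[3] &&
        max(abs(ga[3:6] - mean(ga[3:6]))) < 0.25 * (ga[1] - ga[3])) {
      hits_alpha <- hits_alpha + 1
    }
  }
  expect_gte(hits_coh, n_seeds - 1)
  expect_gte(hits_alpha, n_seeds - 1)
})

test_that("measure tables expose ground truth and plausible scales", {
  cfg <- sim_config(n_subjects = 20, seed = 70)
  tab <- make_measure_table(cfg)
  gt <- attr(tab, "ground_truth")
  expect_equal(nrow(tab), 20 * 6)
  expect_true(all(tab$tracking > 0))
  expect_true(all(tab$alpha > 0))
  # condition means track the programmed profiles
  mt <- tapply(tab$tracking, tab$level, mean)
  expect_equal(which.max(mt), c(`3` = 3L))
  ma <- tapply(tab$alpha, tab$level, mean)
  expect_gt(ma[1], ma[3])
})
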