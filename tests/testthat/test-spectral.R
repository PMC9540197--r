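test_that("segmentation arithmetic and partition property hold", {
  set.seed(10)
  ts <- matrix(rnorm(3 * 1050), 3, 1050)  # 7.0 s at 150 Hz
  ep <- segment_trials(ts, rate = 150, epoch_s = 2)
  expect_equal(dim(ep$data), c(3L, 3L, 300L))
  # concatenating the epochs reproduces the first 6 s exactly
  recon <- do.call(cbind, lapply(1:3, function(tr) ep$data[tr, , ]))
  expect_identical(recon, ts[, 1:900])

  one <- segment_trials(matrix(rnorm(300), 1), rate = 150, epoch_s = 2)
  expect_equal(dim(one$data)[1], 1L)
  expect_error(segment_trials(matrix(rnorm(100), 1), rate = 150), "shorter")

  # vector input returns a trials x samples matrix
  v <- segment_trials(rnorm(750), rate = 150, epoch_s = 2)
  expect_equal(dim(v), c(2L, 300L))
})

test_that("epoch-count equalization subsamples to the minimum, deterministically", {
  set.seed(11)
  sets <- list(a = matrix(rnorm(10 * 300), 10),
               b = matrix(rnorm(8 * 300), 8),
               c = matrix(rnorm(12 * 300), 12))
  eq1 <- equalize_epoch_counts(sets, seed = 5)
  expect_true(all(vapply(eq1, nrow, integer(1)) == 8L))
  eq2 <- equalize_epoch_counts(sets, seed = 5)
  expect_identical(eq1, eq2)
  expect_false(identical(eq1$a, equalize_epoch_counts(sets, seed = 6)$a))
  # equal counts in -> unchanged
  expect_identical(equalize_epoch_counts(eq1, seed = 1), eq1)
})

test_that("DPSS tapers: count, orthonormality, spectral concentration", {
  tp <- dpss_tapers(300, 150, 3)
  expect_equal(nrow(tp), 11L)  # K = 2 T W - 1 for T = 2 s, W = 3 Hz
  gram <- tp %*% t(tp)
  expect_lt(max(abs(gram - diag(11))), 1e-8)
  # concentration of the first taper in +/- 3 Hz via the sinc kernel
  # (independent of the tridiagonal construction)
  N <- 300
  w <- 3 / 150
  ij <- outer(0:(N - 1), 0:(N - 1), `-`)
  S <- sin(2 * pi * w * ij) / (pi * ij)
  diag(S) <- 2 * w
  lambda1 <- drop(tp[1, ] %*% S %*% tp[1, ])
  expect_gt(lambda1, 0.999)
  expect_error(dpss_tapers(20, 150, 3), "time-bandwidth")
})

test_that("multitaper spectra localize peaks and conserve variance", {
  t <- (0:299) / 150
  x <- sin(2 * pi * 10 * t)
  arr <- array(rep(x, each = 1), c(1, 1, 300))
  est <- mtm_cross_spectra(epoch_set(arr, 150))
  pk <- est$freqs[which.max(est$sxx[1, ])]
  expect_equal(pk, 10)
  ap <- alpha_power(est)
  expect_gt(ap, mean(band_average(power_spectra(est), c(1, 7))))
  # doubling amplitude quadruples power
  est2 <- mtm_cross_spectra(epoch_set(arr * 2, 150))
  expect_equal(unname(alpha_power(est2) / ap), 4, tolerance = 1e-9)

  # zero signal -> zero spectra
  est0 <- mtm_cross_spectra(epoch_set(array(0, c(2, 1, 300)), 150))
  expect_true(all(est0$sxx == 0))

  # Parseval within taper leakage on white noise: total in-grid power
  # approximates the variance falling in the 0.5-25.5 Hz slice
  set.seed(12)
  wn <- array(rnorm(20 * 300), c(20, 1, 300))
  estw <- mtm_cross_spectra(epoch_set(wn, 150), fmin = 1, fmax = 25)
  p_bin <- mean(estw$sxx / (estw$n_trials * estw$n_tapers)) / 300
  # expected per-bin power of unit-variance white noise: sigma^2 * N / rate
  # per 1 Hz... normalized: E |FFT taper-weighted|^2 = sigma^2 (unit-norm
  # taper), so sxx/(trials*tapers) ~ sigma^2 = 1 at each bin
  expect_equal(mean(estw$sxx / (estw$n_trials * estw$n_tapers)), 1,
               tolerance = 0.05)
})

test_that("coherence is exact for copied signals and degenerate cases", {
  set.seed(13)
  env <- matrix(rnorm(15 * 300), 15, 300)
  arr <- array(0, c(15, 1, 300))
  arr[, 1, ] <- env
  est <- mtm_cross_spectra(epoch_set(arr, 150), env)
  expect_lt(max(abs(coherence(est) - 1)), 1e-9)

  # one trial, one taper: coherence is identically 1 (rank-1 degeneracy)
  est1 <- mtm_cross_spectra(epoch_set(array(rnorm(300), c(1, 1, 300)), 150),
                            matrix(rnorm(300), 1), half_bandwidth = 0.5)
  expect_equal(est1$n_tapers, 1L)
  expect_lt(max(abs(coherence(est1) - 1)), 1e-9)
})

test_that("coherence is bounded, scale-invariant, and reversal-invariant", {
  set.seed(14)
  for (i in 1:5) {
    ep <- make_noise_epochs(8, 3)
    C <- coherence(mtm_cross_spectra(ep$brain, ep$env))
    expect_lt(max(C), 1 + 1e-12)
    expect_gte(min(C), 0)
    # per-channel rescaling leaves coherence unchanged
    sc <- ep$brain
    sc$data <- sc$data * rep(c(2, 0.1, 7), each = dim(sc$data)[1])
    Cs <- coherence(mtm_cross_spectra(sc, ep$env))
    expect_equal(unclass(Cs), unclass(C), tolerance = 1e-9)
    # joint time reversal of both signals leaves coherence unchanged
    rv <- ep$brain
    rv$data <- rv$data[, , 300:1, drop = FALSE]
    Cr <- coherence(mtm_cross_spectra(rv, ep$env[, 300:1, drop = FALSE]))
    expect_equal(unclass(Cr), unclass(C), tolerance = 1e-9)
  }
})

test_that("band-averaged coherence increases with coupling strength", {
  kappas <- c(0, 0.25, 0.5, 1, 2)
  means <- vapply(kappas, function(kap) {
    mean(vapply(1:6, function(s) {
      set.seed(1000 * kap + s)
      env <- gen_speech_envelope(20 * 2, rate = 150)
      ee <- segment_trials(env, epoch_s = 2)
      br <- gen_neural(env, 20, 1, coupled_channels = 1L, kappa = kap,
                       noise_exponent = 0, noise_sd = 1)
      est <- mtm_cross_spectra(br, ee)
      mean(band_average(coherence(est), c(1, 7)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("band averaging selects inclusive bins", {
  m <- matrix(rep(1:25, each = 2), 2, 25)
  attr(m, "freqs") <- 1:25
  expect_equal(unname(band_average(m, c(1, 7))), rep(mean(1:7), 2))
  expect_equal(unname(band_average(m, c(10, 10))), c(10, 10))
  cm <- matrix(0.3, 4, 25)
  attr(cm, "freqs") <- 1:25
  expect_equal(unname(band_average(cm, c(8, 12))), rep(0.3, 4))
})
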