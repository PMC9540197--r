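# Independent oracles and small fixture builders used across tests.

# Brute-force one-way within-subjects F via the explicit sums-of-squares
# decomposition (independent of the matrix implementation in the package).
bf_rm_anova_f <- function(v) {
  n <- nrow(v)
  k <- ncol(v)
  gm <- mean(v)
  ss_a <- 0
  for (j in seq_len(k)) ss_a <- ss_a + n * (mean(v[, j]) - gm)^2
  ss_s <- 0
  for (i in seq_len(n)) ss_s <- ss_s + k * (mean(v[i, ]) - gm)^2
  ss_t <- sum((v - gm)^2)
  ss_e <- ss_t - ss_a - ss_s
  (ss_a / (k - 1)) / (ss_e / ((n - 1) * (k - 1)))
}

# Brute-force Benjamini-Hochberg step-up adjusted p-values.
bf_bh_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  adj
}

# Dominant non-DC frequency of a series (Hz).
spectral_peak_hz <- function(x, rate, f_min = 0.5) {
  v <- x - mean(x)
  sp <- Mod(stats::fft(v))^2
  fr <- (seq_along(v) - 1) * rate / length(v)
  sel <- fr > f_min & fr <= rate / 2
  fr[sel][which.max(sp[sel])]
}

# White-noise epoch set plus matched envelope epochs for coherence tests.
make_noise_epochs <- function(n_trials, n_channels, ns = 300, rate = 150) {
  arr <- array(stats::rnorm(n_trials * n_channels * ns),
               c(n_trials, n_channels, ns))
  list(brain = epoch_set(arr, rate),
       env = matrix(stats::rnorm(n_trials * ns), n_trials, ns))
}

# Mean per-seed coherence of independent white noise (1 channel).
indep_noise_mean_coherence <- function(n_trials, seed, ns = 300, rate = 150) {
  set.seed(seed)
  ep <- make_noise_epochs(n_trials, 1, ns, rate)
  mean(coherence(mtm_cross_spectra(ep$brain, ep$env)))
}
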