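#' Simulation configuration for a degraded-speech listening study
#'
#' Defines the generating parameters of a fully synthetic dataset with the
#' statistical structure a degraded-speech MEG experiment assumes: six
#' degradation conditions (original plus 7-, 5-, 3-, 2-, 1-channel
#' vocoding), an inverted-U profile of envelope-brain coupling across
#' conditions (weakest for clear and unintelligible speech, strongest at
#' the intermediate 5-channel level), a monotonically declining alpha-power
#' profile that reaches a floor from the 5-channel level onward, speech
#' envelopes with syllable-rate energy near 4.3 Hz, and two-alternative
#' forced-choice hit rates descending from ceiling to the 50% chance
#' level (roughly logistic in the base-2 log of the channel count).
#'
#' Channels live on a `grid[1] x grid[2]` toy sensor grid (row-major
#' numbering, 4-neighborhood adjacency). Envelope-coupled channels form a
#' compact "temporal" patch and alpha-generating channels a disjoint
#' "parietal" patch.
#'
#' @param n_subjects Number of subjects (default 12).
#' @param conditions Condition labels, clearest first.
#' @param n_channels_per_condition Nominal vocoder channel counts
#'   (`Inf` = original / unprocessed).
#' @param kappa Envelope-to-brain coupling gain per condition (>= 0).
#' @param alpha_gain 10 Hz oscillation amplitude per condition (>= 0).
#' @param p_hit 2AFC hit probability per condition (in [0.5, 1]); default
#'   derived from the channel counts by [default_hit_profile()].
#' @param n_trials 2-s epochs per subject and condition (default 20).
#' @param behav_trials Behavioral 2AFC trials per subject and condition
#'   (default 20).
#' @param rate Neural sampling rate in Hz (default 150).
#' @param epoch_s Epoch length in seconds (default 2).
#' @param grid Sensor grid dimensions (default `c(8, 8)`).
#' @param coupled_patch,alpha_patch Channel index vectors of the coupled
#'   ("temporal") and alpha ("parietal") patches; defaults are two
#'   disjoint 6-channel blocks on the default grid.
#' @param noise_exponent Spectral exponent of the 1/f background noise
#'   (default 1).
#' @param noise_sd Noise standard deviation per channel (default 1).
#' @param lag_s Envelope-to-brain lag in seconds (default 0.1; coherence
#'   magnitude is lag-invariant).
#' @param alpha_freq Alpha oscillation frequency in Hz (default 10).
#' @param syllable_rate Mean syllable rate of the generated envelopes in
#'   Hz (default 4.3).
#' @param seed Master seed; a dataset is bit-reproducible from
#'   `(config, seed)`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 12,
                       conditions = c("orig", "voc7", "voc5", "voc3",
                                      "voc2", "voc1"),
                       n_channels_per_condition = c(Inf, 7, 5, 3, 2, 1),
                       kappa = c(0.5, 0.9, 1.2, 1.0, 0.75, 0.5),
                       alpha_gain = c(1.0, 0.8, 0.6, 0.6, 0.6, 0.6),
                       p_hit = NULL,
                       n_trials = 20, behav_trials = 20,
                       rate = 150, epoch_s = 2, grid = c(8, 8),
                       coupled_patch = NULL, alpha_patch = NULL,
                       noise_exponent = 1, noise_sd = 1, lag_s = 0.1,
                       alpha_freq = 10, syllable_rate = 4.3, seed = 1L) {
  k <- length(conditions)
  stopifnot(k >= 2L, length(kappa) == k, length(alpha_gain) == k,
            all(kappa >= 0), all(alpha_gain >= 0), n_subjects >= 2)
  p_hit <- p_hit %||% default_hit_profile(n_channels_per_condition)
  stopifnot(length(p_hit) == k, all(p_hit >= 0.5), all(p_hit <= 1))
  n_ch <- grid[1L] * grid[2L]
  coupled_patch <- coupled_patch %||% patch_channels(grid, rows = 3:4, cols = 2:4)
  alpha_patch <- alpha_patch %||% patch_channels(grid, rows = 6:7, cols = 5:7)
  stopifnot(all(coupled_patch >= 1), all(coupled_patch <= n_ch),
            all(alpha_patch >= 1), all(alpha_patch <= n_ch))
  structure(list(n_subjects = as.integer(n_subjects),
                 conditions = conditions,
                 n_channels_per_condition = n_channels_per_condition,
                 kappa = kappa, alpha_gain = alpha_gain, p_hit = p_hit,
                 n_trials = as.integer(n_trials),
                 behav_trials = as.integer(behav_trials),
                 rate = rate, epoch_s = epoch_s, grid = grid,
                 coupled_patch = coupled_patch, alpha_patch = alpha_patch,
                 noise_exponent = noise_exponent, noise_sd = noise_sd,
                 lag_s = lag_s, alpha_freq = alpha_freq,
                 syllable_rate = syllable_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
patch_channels <- function(grid, rows, cols) {
  as.integer(outer((rows - 1L) * grid[2L], cols, `+`))
}

#' Default 2AFC hit-rate profile
#'
#' Hit probability as a logistic function of the base-2 log of the
#' vocoder channel count, descending from ceiling for clear speech to the
#' 50% chance level for 1-channel vocoding (anchored to typical
#' degraded-speech word-recognition performance).
#'
#' @param n_channels Vocoder channel counts; `Inf` (original) is treated
#'   as 20 channels (spectrally intact for this task).
#' @return Vector of hit probabilities in `[0.5, 1]`.
#' @export
default_hit_profile <- function(n_channels) {
  nc <- pmin(n_channels, 20)
  0.5 + 0.5 * stats::plogis((log2(nc) - 2.1) / 0.59)
}

#' Generate a synthetic speech envelope
#'
#' Nonnegative quasi-periodic burst train emulating the slow amplitude
#' modulation of connected speech: syllable onsets with gamma-jittered
#' inter-burst intervals around `1 / syllable_rate`, gamma-shaped energy
#' bursts with lognormal amplitudes, and a slow multiplicative
#' (prosodic) modulation. The power spectrum peaks near the syllable rate
#' (within 3--6 Hz for the default 4.3 Hz).
#'
#' @param duration_s Duration in seconds.
#' @param rate Sampling rate in Hz (default 150).
#' @param syllable_rate Mean burst rate in Hz (default 4.3).
#' @param seed Optional seed (`NULL` uses the ambient RNG stream).
#' @return An [envelope_series].
#' @export
gen_speech_envelope <- function(duration_s, rate = 150, syllable_rate = 4.3,
                                seed = NULL) {
  with_seed(seed, {
    n <- round(duration_s * rate)
    # syllable onsets: gamma-distributed intervals, mean 1/rate_syl, CV 0.2
    shape <- 25
    t_now <- stats::rgamma(1, shape, rate = shape * syllable_rate) / 2
    onsets <- numeric(0)
    while (t_now < duration_s) {
      onsets <- c(onsets, t_now)
      t_now <- t_now + stats::rgamma(1, shape, rate = shape * syllable_rate)
    }
    tk <- seq(0, 0.25, by = 1 / rate)
    kernel <- stats::dgamma(tk, shape = 2, scale = 0.03)
    kernel <- kernel / max(kernel)
    x <- numeric(n + length(tk))
    amps <- stats::rlnorm(length(onsets), 0, 0.3)
    for (i in seq_along(onsets)) {
      s0 <- round(onsets[i] * rate) + 1L
      span <- s0:(s0 + length(tk) - 1L)
      x[span] <- x[span] + amps[i] * kernel
    }
    x <- x[seq_len(n)]
    slow <- butter_lowpass(stats::rnorm(n), 1.5, rate, order = 2)
    slow <- 1 + 0.2 * slow / stats::sd(slow)
    envelope_series(pmax(x * pmax(slow, 0), 0), rate)
  })
}

#' Generate speech-like audio
#'
#' Noise-carrier waveform with speech-like amplitude structure: the
#' spectrum (100 Hz to 0.9 of Nyquist, capped at 9 kHz) is split into
#' `n_subbands` cochlear-spaced subbands, and each subband carrier is
#' amplitude-modulated by its own syllabic envelope (a mixture of a
#' shared master envelope and a band-specific one from
#' [gen_speech_envelope()], mimicking the partly coherent band envelopes
#' of natural speech). There is no harmonic fine structure. Because the
#' subband envelopes differ, coarse vocoding (few channels) genuinely
#' discards envelope detail, as it does for real speech.
#'
#' @param duration_s Duration in seconds.
#' @param rate Audio sampling rate in Hz (default 22,050; must exceed
#'   20 kHz if the result feeds [cochlear_envelope()]).
#' @param syllable_rate Mean syllable rate in Hz.
#' @param n_subbands Number of independently modulated subbands
#'   (default 3).
#' @param seed Optional seed.
#' @return An [audio_signal].
#' @export
gen_speech_audio <- function(duration_s, rate = 22050, syllable_rate = 4.3,
                             n_subbands = 3, seed = NULL) {
  with_seed(seed, {
    n <- round(duration_s * rate)
    t_hi <- (1:n) / rate
    up <- function(env) {
      stats::approx(seq_along(env$values) / 150, env$values,
                    xout = t_hi, rule = 2)$y
    }
    master <- up(gen_speech_envelope(duration_s, rate = 150,
                                     syllable_rate = syllable_rate))
    top <- min(9000, 0.9 * rate / 2)
    bands <- design_cochlear_bands(n_subbands, 100, top)
    x <- numeric(n)
    for (b in seq_len(n_subbands)) {
      own <- up(gen_speech_envelope(duration_s, rate = 150,
                                    syllable_rate = syllable_rate))
      env_b <- (master + own) / 2
      carrier <- butter_bandpass(stats::rnorm(n), bands$low_hz[b],
                                 bands$high_hz[b], rate, order = 4)
      x <- x + env_b * carrier
    }
    audio_signal(x, rate)
  })
}

#' Generate synthetic neural epochs coupled to a speech envelope
#'
#' Builds `n_trials` epochs of multichannel activity: channels in the
#' coupled patch receive a 1--7 Hz band-limited, lag-shifted, unit-SD
#' transform of the envelope scaled by `kappa`; channels in the alpha
#' patch receive a `alpha_freq` Hz sinusoid of amplitude `alpha_gain`
#' with a fresh random phase per trial and channel; all channels receive
#' 1/f background noise. With `kappa = 0` the envelope-brain coherence of
#' every channel sits at the independence floor; doubling `alpha_gain`
#' quadruples alpha-band power in the alpha patch.
#'
#' @param envelope An [envelope_series] (or numeric vector at `rate`)
#'   with at least `n_trials * epoch_s * rate` samples.
#' @param n_trials Number of epochs.
#' @param n_channels Number of channels.
#' @param coupled_channels,alpha_channels Channel index vectors.
#' @param kappa Coupling gain (>= 0).
#' @param alpha_gain Alpha amplitude (>= 0).
#' @param rate,epoch_s Sampling rate (Hz) and epoch length (s).
#' @param noise_exponent,noise_sd 1/f noise shape and scale.
#' @param lag_s Envelope-to-brain lag in seconds.
#' @param alpha_freq Alpha frequency in Hz.
#' @param seed Optional seed.
#' @param ... Metadata passed to [epoch_set()].
#' @return An [epoch_set] (`n_trials x n_channels x samples`).
#' @export
gen_neural <- function(envelope, n_trials, n_channels,
                       coupled_channels = integer(0),
                       alpha_channels = integer(0),
                       kappa = 0, alpha_gain = 0, rate = 150, epoch_s = 2,
                       noise_exponent = 1, noise_sd = 1, lag_s = 0.1,
                       alpha_freq = 10, seed = NULL, ...) {
  e <- if (inherits(envelope, "envelope_series")) envelope$values else envelope
  ns <- round(epoch_s * rate)
  n <- n_trials * ns
  if (length(e) < n) stop("envelope shorter than n_trials * epoch_s")
  e <- e[seq_len(n)]
  with_seed(seed, {
    X <- t(one_over_f_noise(n, n_channels, rate, noise_exponent, noise_sd))
    if (kappa > 0 && length(coupled_channels)) {
      eb <- butter_bandpass(e - mean(e), 1, 7, rate, order = 4)
      eb <- eb / stats::sd(eb)
      lag <- round(lag_s * rate)
      ebl <- if (lag > 0) c(numeric(lag), eb[seq_len(n - lag)]) else eb
      X[coupled_channels, ] <- X[coupled_channels, ] +
        matrix(kappa * ebl, length(coupled_channels), n, byrow = TRUE)
    }
    if (alpha_gain > 0 && length(alpha_channels)) {
      tt <- (0:(ns - 1L)) / rate
      for (tr in seq_len(n_trials)) {
        span <- ((tr - 1L) * ns + 1L):(tr * ns)
        ph <- stats::runif(length(alpha_channels), 0, 2 * pi)
        osc <- sin(outer(ph, 2 * pi * alpha_freq * tt, `+`))
        X[alpha_channels, span] <- X[alpha_channels, span] + alpha_gain * osc
      }
    }
    arr <- array(0, c(n_trials, n_channels, ns))
    for (tr in seq_len(n_trials)) {
      arr[tr, , ] <- X[, ((tr - 1L) * ns + 1L):(tr * ns)]
    }
    epoch_set(arr, rate = rate, ...)
  })
}

#' Generate a behavioral 2AFC table
#'
#' Hits per subject and condition drawn as
#' `Binomial(behav_trials, p_hit)`; chance performance is 50%.
#'
#' @param config A [sim_config].
#' @param seed Optional seed (default: the config seed).
#' @return Data frame with `subject`, `condition`, `level`, `n_trials`,
#'   `n_hits`, `hit_rate`.
#' @export
gen_behavior <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  k <- length(config$conditions)
  with_seed(seed %||% config$seed, {
    grid_tab <- expand.grid(condition_idx = seq_len(k),
                            subject = seq_len(config$n_subjects))
    hits <- stats::rbinom(nrow(grid_tab), config$behav_trials,
                          config$p_hit[grid_tab$condition_idx])
    data.frame(subject = paste0("S", sprintf("%02d", grid_tab$subject)),
               condition = config$conditions[grid_tab$condition_idx],
               level = grid_tab$condition_idx,
               n_trials = config$behav_trials,
               n_hits = hits,
               hit_rate = hits / config$behav_trials)
  })
}

#' Generate a complete synthetic dataset
#'
#' Draws, for every subject and condition, a fresh synthetic speech
#' envelope and a neural [epoch_set] realizing the config's coupling and
#' alpha profiles, plus the sensor adjacency graph and a behavioral
#' table. The full generating parameter set is retained as ground truth
#' so every pipeline stage can be checked by parameter recovery. The
#' result is bit-reproducible from the config (and its seed).
#'
#' @param config A [sim_config].
#' @return A list of class `synthetic_dataset`: `neural` (list by subject
#'   then condition of [epoch_set]s), `envelope_epochs` (matching
#'   `trials x samples` matrices), `adjacency`, `behavior`,
#'   `ground_truth`.
#' @export
make_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- length(config$conditions)
  subj_ids <- paste0("S", sprintf("%02d", seq_len(config$n_subjects)))
  with_seed(config$seed, {
    neural <- vector("list", config$n_subjects)
    env_epochs <- vector("list", config$n_subjects)
    names(neural) <- names(env_epochs) <- subj_ids
    dur <- config$n_trials * config$epoch_s
    for (s in seq_len(config$n_subjects)) {
      neural[[s]] <- vector("list", k)
      env_epochs[[s]] <- vector("list", k)
      names(neural[[s]]) <- names(env_epochs[[s]]) <- config$conditions
      for (c in seq_len(k)) {
        env <- gen_speech_envelope(dur, config$rate, config$syllable_rate)
        neural[[s]][[c]] <- gen_neural(
          env, config$n_trials, config$grid[1L] * config$grid[2L],
          coupled_channels = config$coupled_patch,
          alpha_channels = config$alpha_patch,
          kappa = config$kappa[c], alpha_gain = config$alpha_gain[c],
          rate = config$rate, epoch_s = config$epoch_s,
          noise_exponent = config$noise_exponent,
          noise_sd = config$noise_sd, lag_s = config$lag_s,
          alpha_freq = config$alpha_freq,
          subject_id = subj_ids[s], condition_id = config$conditions[c]
        )
        env_epochs[[s]][[c]] <- segment_trials(env, epoch_s = config$epoch_s)
      }
    }
    behavior <- gen_behavior(config, seed = NULL)
    structure(list(neural = neural, envelope_epochs = env_epochs,
                   adjacency = grid_adjacency(config$grid[1L], config$grid[2L]),
                   behavior = behavior,
                   ground_truth = config),
              class = "synthetic_dataset")
  })
}

# quadratic coefficient of the group-mean profile over centered ordinal
# levels; used to express measure noise relative to the programmed
# curvature
quad_coef <- function(levels, mu) {
  lc <- levels - mean(levels)
  unname(stats::lm(mu ~ lc + I(lc^2))$coefficients[3L])
}

#' Generate a measure-level subject-by-condition table
#'
#' Draws per-subject tracking, alpha and behavioral measures directly at
#' the summary level (without simulating time series): tracking means
#' follow `0.015 + 0.1 * kappa^2` (coherence-scale image of the coupling
#' profile), alpha means follow `alpha_gain`, and hits are binomial.
#' Subject heterogeneity enters as Gaussian random intercepts; residual
#' tracking noise is scaled to the programmed curvature (SD = 0.3 times
#' the absolute quadratic coefficient of the tracking profile), and alpha
#' residual noise is 0.05 in the units of `alpha_gain`. This is the fast
#' generator used for model-recovery studies of the mixed-model stage.
#'
#' @param config A [sim_config].
#' @param seed Optional seed (default: the config seed).
#' @return Data frame with `subject`, `condition`, `level`, `tracking`,
#'   `alpha`, `n_trials`, `n_hits`, `hit_rate`, plus attribute
#'   `"ground_truth"` holding the generating profiles.
#' @export
make_measure_table <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  k <- length(config$conditions)
  n <- config$n_subjects
  levels_ <- seq_len(k)
  mu_track <- 0.015 + 0.1 * config$kappa^2
  mu_alpha <- config$alpha_gain
  sd_track_resid <- 0.3 * abs(quad_coef(levels_, mu_track))
  sd_alpha_resid <- 0.05
  sd_track_subj <- 0.02
  sd_alpha_subj <- 0.1
  with_seed(seed %||% config$seed, {
    beh <- gen_behavior(config, seed = NULL)
    u_t <- stats::rnorm(n, 0, sd_track_subj)
    u_a <- stats::rnorm(n, 0, sd_alpha_subj)
    si <- match(beh$subject, unique(beh$subject))
    beh$tracking <- pmax(mu_track[beh$level] + u_t[si] +
                           stats::rnorm(nrow(beh), 0, sd_track_resid), 1e-3)
    beh$alpha <- pmax(mu_alpha[beh$level] + u_a[si] +
                        stats::rnorm(nrow(beh), 0, sd_alpha_resid), 1e-2)
    attr(beh, "ground_truth") <- list(mu_track = mu_track,
                                      mu_alpha = mu_alpha,
                                      p_hit = config$p_hit,
                                      sd_track_resid = sd_track_resid,
                                      sd_alpha_resid = sd_alpha_resid)
    beh
  })
}

#' Generate a table with behavior driven by a known neural mechanism
#'
#' Builds normalized tracking and activation predictors (lognormal
#' per-row measurement noise around the programmed profiles; subject
#' scale factors cancel in the normalization) and then generates observed
#' intelligibility from a chosen ground-truth mechanism: a monotone
#' function of the tracking/activation ratio (`"ratio"`), of tracking
#' alone (`"tracking"`), or independent of both (`"constant"`), plus
#' Gaussian response noise. Used for generative-recovery and specificity
#' checks of [intelligibility_models()].
#'
#' @param config A [sim_config].
#' @param mechanism `"ratio"`, `"tracking"`, or `"constant"`.
#' @param seed Optional seed.
#' @return Data frame of vocoded-condition rows with `subject`,
#'   `condition`, `level`, `tracking_norm`, `activation_norm`, `response`.
#' @export
gen_intelligibility_table <- function(config,
                                      mechanism = c("ratio", "tracking",
                                                    "constant"),
                                      seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  mechanism <- match.arg(mechanism)
  k <- length(config$conditions)
  n <- config$n_subjects
  mu_track <- 0.015 + 0.1 * config$kappa^2
  mu_alpha <- config$alpha_gain
  with_seed(seed %||% config$seed, {
    tab <- expand.grid(level = seq_len(k), subject_idx = seq_len(n))
    tab$subject <- paste0("S", sprintf("%02d", tab$subject_idx))
    tab$condition <- config$conditions[tab$level]
    f_t <- stats::rlnorm(n, 0, 0.15)  # subject scale, cancels on normalization
    f_a <- stats::rlnorm(n, 0, 0.15)
    tab$tracking <- mu_track[tab$level] * f_t[tab$subject_idx] *
      stats::rlnorm(nrow(tab), 0, 0.12)
    tab$activation <- mu_alpha[tab$level] * f_a[tab$subject_idx] *
      stats::rlnorm(nrow(tab), 0, 0.12)
    norm <- normalize_by_clear(tab, measures = c("tracking", "activation"),
                               clear = config$conditions[1L])
    pred <- switch(mechanism,
      ratio = 0.45 + 0.05 * (norm$tracking_norm / norm$activation_norm),
      tracking = 0.40 + 0.10 * norm$tracking_norm,
      constant = rep(0.75, nrow(norm))
    )
    norm$response <- pmin(pmax(pred + stats::rnorm(nrow(norm), 0, 0.05), 0), 1)
    norm[, c("subject", "condition", "level", "tracking_norm",
             "activation_norm", "response")]
  })
}
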