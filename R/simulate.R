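#' Motor-imagery simulation configuration
#'
#' Stated world for the synthetic two-class fixture: 8-second trials (2000
#' samples at 250 Hz) on C3/Cz/C4-like channels carrying mu (8-12 Hz) and
#' beta (18-26 Hz) oscillations over 1/f background noise. Imagery trials
#' attenuate the contralateral (C3, for right-hand imagery) mu and beta
#' amplitudes by `erd_depth` — the event-related desynchronization. The mu
#' amplitude is 1 and beta 0.5 (beta rhythms are weaker); `snr_db` is the
#' per-channel ratio of full-amplitude oscillation power to noise power.
#'
#' @param n_trials_per_class Trials per class.
#' @param channels Channel names; the first is the ERD-attenuated one.
#' @param sampling_rate Hz.
#' @param samples_per_trial Samples per trial.
#' @param mu_band,beta_band Frequency bands in Hz (`c(low, high)`).
#' @param erd_depth Fractional amplitude attenuation in `[0, 1]`.
#' @param background `"pink"` (1/f) or `"white"` noise.
#' @param snr_db Signal-to-noise ratio in dB.
#' @param seed Master seed; generation is a pure function of the config.
#' @return An `mi_sim_config`.
#' @export
mi_sim_config <- function(n_trials_per_class = 100L,
                          channels = c("C3", "Cz", "C4"),
                          sampling_rate = 250, samples_per_trial = 2000L,
                          mu_band = c(8, 12), beta_band = c(18, 26),
                          erd_depth = 0.5,
                          background = c("pink", "white"),
                          snr_db = 5, seed = 1L) {
  background <- match.arg(background)
  if (erd_depth < 0 || erd_depth > 1) {
    stop(errorCondition("erd_depth must lie in [0, 1]",
                        class = c("eemdbci_config_error", "error", "condition")))
  }
  structure(list(n_trials_per_class = as.integer(n_trials_per_class),
                 channels = channels, sampling_rate = sampling_rate,
                 samples_per_trial = as.integer(samples_per_trial),
                 mu_band = mu_band, beta_band = beta_band,
                 erd_depth = erd_depth, background = background,
                 snr_db = snr_db, seed = as.integer(seed)),
            class = "mi_sim_config")
}

# 1/f-shaped (pink) noise with unit variance, via spectral shaping.
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  k <- seq_len(n) - 1L
  freq <- pmin(k, n - k)            # symmetric frequency index
  scale <- ifelse(freq == 0, 0, 1 / sqrt(freq))
  x <- Re(stats::fft(spec * scale, inverse = TRUE)) / n
  x / stats::sd(x)
}

# one narrowband rhythm: tone at a random in-band frequency, random phase,
# slow sinusoidal amplitude modulation
rhythm <- function(t, band, amplitude) {
  f <- stats::runif(1, band[1], band[2])
  phi <- stats::runif(1, 0, 2 * pi)
  fm <- stats::runif(1, 0.05, 0.3)
  phm <- stats::runif(1, 0, 2 * pi)
  env <- 1 + 0.25 * sin(2 * pi * fm * t + phm)
  amplitude * env * sin(2 * pi * f * t + phi)
}

#' Deterministic analytic test signals
#'
#' Fixture generator for the decomposition tests. Every kind returns the
#' signal together with its ground-truth parts, which always sum exactly
#' to the signal.
#'
#' @param kind One of `"tone"`, `"two_tone"`, `"chirp"`,
#'   `"tone_plus_trend"`, `"intermittent"`.
#' @param params Named list of overrides; see Details. Common: `fs`
#'   (default 250), `duration` seconds (default 8).
#' @param seed Seed for the stochastic pieces (only `"intermittent"` burst
#'   placement uses it; analytic kinds are deterministic regardless).
#' @details Kind parameters (defaults): tone `f = 10, a = 1`; two_tone
#'   `f1 = 1, a1 = 1, f2 = 12, a2 = 0.5`; chirp `f0 = 2, f1 = 20` (linear);
#'   tone_plus_trend `f = 10, a = 1, slope = 0.1` (per second);
#'   intermittent `f = 2, a = 1, fb = 30, ab = 0.3, burst_frac = 0.2`.
#' @return List with `signal` (an `eeg_signal`) and `parts` (named list of
#'   numeric ground-truth components).
#' @export
make_test_signal <- function(kind, params = list(), seed = 1L) {
  p <- utils::modifyList(list(fs = 250, duration = 8), params)
  t <- seq(0, p$duration, by = 1 / p$fs)
  t <- t[-length(t)]
  parts <- switch(
    kind,
    tone = {
      q <- utils::modifyList(list(f = 10, a = 1), p)
      list(tone = q$a * sin(2 * pi * q$f * t))
    },
    two_tone = {
      q <- utils::modifyList(list(f1 = 1, a1 = 1, f2 = 12, a2 = 0.5), p)
      list(slow = q$a1 * sin(2 * pi * q$f1 * t),
           fast = q$a2 * sin(2 * pi * q$f2 * t))
    },
    chirp = {
      q <- utils::modifyList(list(f0 = 2, f1 = 20), p)
      rate <- (q$f1 - q$f0) / p$duration
      list(chirp = sin(2 * pi * (q$f0 * t + rate * t^2 / 2)))
    },
    tone_plus_trend = {
      q <- utils::modifyList(list(f = 10, a = 1, slope = 0.1), p)
      list(tone = q$a * sin(2 * pi * q$f * t), trend = q$slope * t)
    },
    intermittent = {
      q <- utils::modifyList(list(f = 2, a = 1, fb = 30, ab = 0.3,
                                  burst_frac = 0.2), p)
      burst <- with_substream(seed, 1L, function() {
        n <- length(t)
        len <- max(2L, round(q$burst_frac * n))
        start <- sample.int(n - len, 1L)
        mask <- numeric(n)
        mask[start:(start + len - 1L)] <- 1
        mask
      })
      list(tone = q$a * sin(2 * pi * q$f * t),
           burst = q$ab * burst * sin(2 * pi * q$fb * t))
    },
    stop(errorCondition(sprintf("unknown test-signal kind '%s'", kind),
                        class = c("eemdbci_config_error", "error", "condition")))
  )
  x <- Reduce(`+`, parts)
  list(signal = signal(x, p$fs), parts = parts)
}

#' Simulate two-class motor-imagery trials
#'
#' See [mi_sim_config()] for the generative model. Relaxed trials carry
#' full-amplitude mu and beta rhythms on all channels; imagery trials
#' attenuate both rhythms on the first (contralateral) channel by
#' `erd_depth`. Noise power is set from the full-amplitude rhythm power,
#' so the noise law is identical across classes. Fully reproducible per
#' seed; the caller's RNG state is untouched.
#'
#' @param config An [mi_sim_config()].
#' @return A [trial_set()] with balanced labels `"relaxed"` / `"imagery"`
#'   (all relaxed trials first).
#' @export
simulate_mi_trials <- function(config = mi_sim_config()) {
  with_substream(config$seed, 0L, function() {
    n <- config$samples_per_trial
    t <- (seq_len(n) - 1) / config$sampling_rate
    noise_fun <- if (config$background == "pink") pink_noise else
      function(n) stats::rnorm(n)
    gen_trial <- function(label) {
      trial <- matrix(0, length(config$channels), n,
                      dimnames = list(config$channels, NULL))
      for (ci in seq_along(config$channels)) {
        mu <- rhythm(t, config$mu_band, 1)
        beta <- rhythm(t, config$beta_band, 0.5)
        clean_full <- mu + beta
        atten <- if (label == "imagery" && ci == 1L) 1 - config$erd_depth else 1
        clean <- atten * clean_full
        noise_sd <- sqrt(mean(clean_full^2) / 10^(config$snr_db / 10))
        trial[ci, ] <- clean + noise_sd * noise_fun(n)
      }
      trial
    }
    labels <- rep(c("relaxed", "imagery"), each = config$n_trials_per_class)
    trials <- lapply(labels, gen_trial)
    trial_set(trials, labels, config$channels, config$sampling_rate)
  })
}

#' Simulate amplitude-contrasted signal sets
#'
#' Two seeded sets of oscillatory signals that differ only in amplitude
#' gain, for exercising [imf_energy_profile()] separation between high-
#' and low-arousal training states.
#'
#' @param gain_high,gain_low Amplitude gains, `gain_high > gain_low > 0`.
#' @param n_signals Signals per set.
#' @param seed Master seed.
#' @param snr_db Per-signal SNR of the oscillation over white noise.
#' @return List with `high` and `low`, each a list of `eeg_signal`s; the
#'   i-th signals of the two sets share the same underlying realization.
#' @export
simulate_state_energy_pair <- function(gain_high = 2, gain_low = 1,
                                       n_signals = 10L, seed = 1L,
                                       snr_db = 20) {
  if (!(gain_high > gain_low && gain_low > 0)) {
    stop(errorCondition("need gain_high > gain_low > 0",
                        class = c("eemdbci_config_error", "error", "condition")))
  }
  fs <- 250
  n <- 1000L
  t <- (seq_len(n) - 1) / fs
  base <- lapply(seq_len(n_signals), function(i) {
    with_substream(seed, i, function() {
      osc <- rhythm(t, c(8, 12), 1) + rhythm(t, c(18, 26), 0.5)
      noise_sd <- sqrt(mean(osc^2) / 10^(snr_db / 10))
      list(osc = osc, noise = noise_sd * stats::rnorm(n))
    })
  })
  # gain scales the oscillation only; the noise floor is shared, so the
  # energy ratio tracks gain^2 up to the (small) noise contribution
  mk <- function(gain) lapply(base, function(b)
    signal(gain * b$osc + b$noise, fs))
  list(high = mk(gain_high), low = mk(gain_low))
}
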