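# Independent oracles and shared fixtures for the suite. Oracles are kept
# deliberately naive (brute-force loops) so they stay independent of the
# implementation paths they check.

# brute-force local extrema by direct neighbor comparison, flat runs kept
# at their first index
oracle_extrema <- function(x) {
  n <- length(x)
  maxi <- integer(0); mini <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L   # flat run [i, j]
    if (j < n) {
      left <- x[i - 1L]; right <- x[j + 1L]
      if (x[i] > left && x[i] > right) maxi <- c(maxi, i)
      if (x[i] < left && x[i] < right) mini <- c(mini, i)
    }
    i <- j + 1L
  }
  list(maxima = maxi, minima = mini)
}

# brute-force weighted pairwise scatter, double loop
oracle_pairwise_scatter <- function(points, weights) {
  n <- nrow(points); d <- ncol(points)
  s <- matrix(0, d, d)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      v <- points[i, ] - points[j, ]
      s <- s + weights[i, j] * tcrossprod(v)
    }
  }
  s / 2
}

# band energy fraction from the periodogram
band_energy_fraction <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  half <- f <= fs / 2
  sum(p[half & f >= lo & f <= hi]) / sum(p[half])
}

# fixed two-tone fixture used throughout (1 Hz + 0.5 * 12 Hz, 8 s @ 250 Hz)
two_tone_fixture <- function() make_test_signal("two_tone")

zero_crossings <- function(x) {
  s <- sign(x); s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(s[-1] != s[-length(s)])
}

# small labeled MI fixture shared by the feature/classifier tests
small_mi_fixture <- function(n = 20L, seed = 42L, erd_depth = 0.5) {
  simulate_mi_trials(mi_sim_config(n_trials_per_class = n, seed = seed,
                                   erd_depth = erd_depth))
}
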