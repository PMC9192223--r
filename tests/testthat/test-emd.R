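test_that("find_extrema matches the brute-force oracle and its tie rule", {
  fs <- 1000
  t <- seq(0, 1, by = 1 / fs)[-1001]
  cases <- list(
    sine5 = sin(2 * pi * 5 * t),
    noisy = {set.seed(7); cumsum(rnorm(500))},
    flat = c(0, 1, 1, 0, -1, -1, -1, 0.5, 0, 0.2, -0.3, 1)
  )
  for (nm in names(cases)) {
    got <- find_extrema(cases[[nm]])
    want <- oracle_extrema(cases[[nm]])
    expect_identical(got$maxima, want$maxima, label = nm)
    expect_identical(got$minima, want$minima, label = nm)
  }
  e <- find_extrema(sin(2 * pi * 5 * t))
  expect_true(abs(length(e$maxima) - 5L) <= 1L)
  expect_true(abs(length(e$minima) - 5L) <= 1L)
  # constant signal: no extrema; flat run keeps its first index
  expect_identical(find_extrema(rep(1, 10)),
                   list(maxima = integer(0), minima = integer(0)))
  expect_identical(find_extrema(c(0, 1, 1, 0))$maxima, 2L)
  expect_error(find_extrema(c(1, 2)), class = "eemdbci_degenerate_input")
})

test_that("mean_envelope is near zero for a tone, affine, and tracks slow tones", {
  fs <- 500
  t <- seq(0, 4, by = 1 / fs)[-(4 * fs + 1)]
  a <- 2.5
  x <- a * sin(2 * pi * 8 * t)
  env <- mean_envelope(x)
  interior <- seq(round(0.1 * length(x)), round(0.9 * length(x)))
  expect_lt(max(abs(env[interior])), 0.05 * a)
  # adding a constant shifts the envelope by exactly that constant
  expect_equal(mean_envelope(x + 3), env + 3, tolerance = 1e-10)
  # two-tone: the envelope mean follows the slow component
  slow <- sin(2 * pi * 1 * t)
  env2 <- mean_envelope(slow + 0.5 * sin(2 * pi * 10 * t))
  expect_gt(cor(env2[interior], slow[interior]), 0.9)
  expect_error(mean_envelope(seq(1, 10)), class = "eemdbci_envelope_undefined")
})

test_that("sd_criterion evaluates the ratio-of-sums formula", {
  prev <- c(1, -2, 3, 0.5)
  expect_equal(sd_criterion(prev, prev), 0)
  expect_equal(sd_criterion(2 * prev, prev), 1)
  eps <- c(1, 1, -1, 1)
  eps <- eps * sqrt(0.04 * sum(prev^2) / sum(eps^2))
  expect_equal(sd_criterion(prev + eps, prev), 0.04, tolerance = 1e-12)
  expect_error(sd_criterion(prev, rep(0, 4)), class = "eemdbci_degenerate_input")
  expect_error(sd_criterion(prev, prev[-1]), class = "eemdbci_config_error")
})

test_that("a pure tone sifts to itself in a few iterations", {
  pt <- make_test_signal("tone")
  s <- extract_imf(pt$signal$samples)
  expect_true(s$converged)
  expect_lte(nrow(s$trace), 3L)
  rel <- sqrt(sum((s$imf - pt$signal$samples)^2) / sum(pt$signal$samples^2))
  expect_lt(rel, 1e-3)
  # the stopping rule: terminal SD below the configured threshold
  expect_lt(s$trace$sd[nrow(s$trace)], emd_config()$sd_threshold)
})

test_that("emd separates known components and terminates on trends", {
  # monotone ramp: nothing to extract
  ramp <- emd(seq(0, 1, length.out = 100))
  expect_length(ramp$imfs, 0L)
  expect_equal(ramp$residual, seq(0, 1, length.out = 100))
  # two tones + trend: fast tone first, slow second, trend in the residual
  tt <- make_test_signal("tone_plus_trend",
                         list(f = 12, a = 0.5, slope = 0.1))
  t <- signal_time(tt$signal)
  x <- tt$parts$tone + sin(2 * pi * 1 * t) + tt$parts$trend
  d <- emd(x)
  expect_gte(length(d$imfs), 2L)
  expect_gt(abs(cor(d$imfs[[1]], tt$parts$tone)), 0.9)
  expect_gt(abs(cor(d$imfs[[2]], sin(2 * pi * 1 * t))), 0.9)
  expect_lt(max(abs(x - reconstruct(d))), 1e-10 * max(abs(x)))
})

test_that("reconstruction, IMF condition and local-mean hold over random signals", {
  set.seed(123)
  for (rep in 1:12) {
    n <- sample(200:600, 1)
    x <- cumsum(rnorm(n)) + sin(2 * pi * sample(3:20, 1) * seq(0, 1, length.out = n))
    d <- emd(x)
    expect_lt(max(abs(x - reconstruct(d))), 1e-10 * max(abs(x)))
    for (c_j in d$imfs) {
      expect_lte(eemdbci:::imf_condition_gap(c_j), 1L)
    }
  }
  # near-zero local mean of accepted IMFs, away from a 5% boundary margin
  d <- emd(two_tone_fixture()$signal$samples)
  for (j in which(d$converged)) {
    imf <- d$imfs[[j]]
    env <- tryCatch(mean_envelope(imf), eemdbci_envelope_undefined = function(e) NULL)
    if (is.null(env)) next
    n <- length(imf)
    margin <- seq(ceiling(0.05 * n), floor(0.95 * n))
    expect_lt(max(abs(env[margin])), 0.1 * max(abs(imf)))
  }
})

test_that("emd is equivariant under positive scaling of the input", {
  # exact a-homogeneity: every sifting quantity (envelopes, SD values,
  # stop decisions) scales with a, so the decomposition scales too.
  # a DC offset b is NOT exactly neutral: the SD denominator at the first
  # sift of each IMF sees the offset and can flip a stop decision, so only
  # the scale part of the shift/scale property is testable at 1e-8; the
  # offset enters the envelope level instead (see the mean_envelope test).
  set.seed(5)
  x <- sin(2 * pi * 3 * seq(0, 2, length.out = 400)) + 0.3 * rnorm(400)
  a <- 2.5
  d0 <- emd(x)
  d1 <- emd(a * x)
  expect_length(d1$imfs, length(d0$imfs))
  scale <- max(abs(a * x))
  for (j in seq_along(d0$imfs)) {
    expect_lt(max(abs(d1$imfs[[j]] - a * d0$imfs[[j]])), 1e-8 * scale)
  }
  expect_lt(max(abs(d1$residual - a * d0$residual)), 1e-8 * scale)
  expect_identical(d1$n_sifts, d0$n_sifts)
})
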