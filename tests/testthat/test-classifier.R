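test_that("fit_discriminant recovers simulated Gaussian parameters", {
  set.seed(20)
  n <- 500
  mu_a <- c(0, 0); mu_b <- c(4, 2)
  sig <- matrix(c(1, 0.3, 0.3, 0.5), 2)
  ch <- chol(sig)
  xa <- matrix(rnorm(2 * n), n) %*% ch
  xb <- sweep(matrix(rnorm(2 * n), n) %*% ch, 2, mu_b, `+`)
  feats <- rbind(xa, xb)
  labels <- rep(c("a", "b"), each = n)
  m <- fit_discriminant(feats, labels)
  se <- sqrt(diag(sig) / n)
  expect_true(all(abs(m$class_means$a - mu_a) < 3 * se))
  expect_true(all(abs(m$class_means$b - mu_b) < 3 * se))
  expect_lt(norm(m$gamma - sig, "F") / norm(sig, "F"), 0.2)
  expect_equal(m$projection, diag(2))
  # duplicating every sample barely moves the model at n = 500
  m2 <- fit_discriminant(rbind(feats, feats), c(labels, labels))
  expect_equal(m2$class_means, m$class_means, tolerance = 1e-12)
  expect_lt(norm(m2$gamma - m$gamma, "F") / norm(m$gamma, "F"), 0.01)
  expect_error(fit_discriminant(feats[c(1, 501), ], labels[c(1, 501)]),
               class = "eemdbci_config_error")
})

test_that("decision values match the closed-form specializations", {
  feats <- rbind(matrix(rnorm(40), 20), sweep(matrix(rnorm(40), 20), 2, 3, `+`))
  labels <- rep(c("relaxed", "imagery"), each = 20)
  m <- fit_discriminant(feats, labels)
  # at a class mean the Mahalanobis term vanishes
  g <- decision_value(m, m$class_means$imagery)$g
  ldet <- determinant(m$gamma, logarithm = TRUE)$modulus[1]
  expect_equal(g[, "imagery"], log(2) - 0.5 * ldet, tolerance = 1e-10,
               ignore_attr = TRUE)
  # Gamma = I: the rule reduces to nearest-mean with the ln K constant
  mi <- m
  mi$gamma <- diag(2)
  x <- c(1.2, -0.7)
  gi <- decision_value(mi, x)$g
  for (cl in c("imagery", "relaxed")) {
    expect_equal(gi[, cl],
                 -0.5 * sum((x - mi$class_means[[cl]])^2) + log(2),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # equidistant point between the means with shared Gamma: score 0
  mid <- (m$class_means$imagery + m$class_means$relaxed) / 2
  expect_equal(decision_value(m, mid)$score, 0, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("pooled-Gamma discriminant agrees with a shared-covariance oracle", {
  # equal-prior LDA on a 50-point fixture, label for label
  set.seed(30)
  xa <- matrix(rnorm(50), 25) %*% matrix(c(1, 0.4, 0.4, 1), 2)
  xb <- sweep(matrix(rnorm(50), 25) %*% matrix(c(1, 0.4, 0.4, 1), 2), 2,
              c(2.5, 1), `+`)
  feats <- rbind(xa, xb)
  labels <- rep(c("relaxed", "imagery"), each = 25)
  m <- fit_discriminant(feats, labels)
  score <- decision_value(m, feats)$score
  # oracle: plug-in LDA with the same pooled covariance estimate
  si <- solve(m$gamma)
  ora <- apply(feats, 1, function(x) {
    -0.5 * mahalanobis(x, m$class_means$imagery, m$gamma) +
      0.5 * mahalanobis(x, m$class_means$relaxed, m$gamma)
  })
  expect_equal(score, ora, tolerance = 1e-8, ignore_attr = TRUE)
  expect_identical(score >= 0, ora >= 0)
})

test_that("decision densities are proper and equivariant", {
  set.seed(31)
  v <- rnorm(1000)
  d <- decision_density(v)
  expect_true(all(d$density >= 0))
  area <- sum(diff(d$grid) * (d$density[-1] + d$density[-512]) / 2)
  expect_lt(abs(area - 1), 1e-3)
  at0 <- approx(d$grid, d$density, 0)$y
  expect_lt(abs(at0 - 1 / sqrt(2 * pi)) / (1 / sqrt(2 * pi)), 0.15)
  ds <- decision_density(v + 5, bandwidth = d$bandwidth)
  expect_equal(ds$grid, d$grid + 5, tolerance = 1e-9)
  expect_equal(ds$density, d$density, tolerance = 1e-9)
  expect_error(decision_density(1:3), class = "eemdbci_degenerate_input")
  expect_warning(decision_density(rep(2, 10)), "spike")
})

test_that("overlap area follows the closed-form normal result", {
  set.seed(32)
  mk <- function(mu) {
    v <- rnorm(4000, mu)
    decision_density(v)
  }
  a <- mk(0)
  expect_equal(overlap_area(a, a), 1, tolerance = 1e-3)
  # equal-variance normals d apart overlap by 2*pnorm(-d/2); d = 2
  b <- mk(2)
  expect_lt(abs(overlap_area(a, b) - 2 * pnorm(-1)), 0.03)
  far <- mk(10)
  expect_lt(overlap_area(a, far), 0.01)
})

test_that("threshold selection caps the empirical FPR with conservative ties", {
  thr <- select_threshold(1:100, 0.10)
  expect_gt(thr$value, 90); expect_lt(thr$value, 91)
  expect_equal(thr$achieved_fpr, 0.10)
  expect_equal(mean(1:100 >= thr$value), 0.10)
  # fpr 0.5 on symmetric scores: threshold near the median
  s <- c(-50:-1, 1:50)
  t5 <- select_threshold(s, 0.5)
  expect_lt(abs(t5$value), 1.01)
  # ties: all-equal scores push the threshold just above, FPR 0
  te <- select_threshold(rep(3, 20), 0.10)
  expect_gt(te$value, 3)
  expect_equal(te$achieved_fpr, 0)
  # monotonicity: higher cap, weakly lower threshold, non-decreasing FPR
  set.seed(33)
  sc <- rnorm(200)
  caps <- c(0.05, 0.1, 0.2, 0.4)
  fits <- lapply(caps, function(f) select_threshold(sc, f))
  vals <- vapply(fits, `[[`, 0, "value")
  fprs <- vapply(fits, `[[`, 0, "achieved_fpr")
  expect_true(all(diff(vals) <= 0))
  expect_true(all(diff(fprs) >= 0))
  expect_true(all(fprs <= caps))
  expect_error(select_threshold(1:5, 0.1), class = "eemdbci_degenerate_input")
  expect_error(select_threshold(1:100, 1.2), class = "eemdbci_config_error")
})

test_that("classification respects the threshold and the binomial FPR bound", {
  set.seed(34)
  relaxed <- rnorm(400)
  imagery <- rnorm(400, 3)
  feats <- cbind(c(relaxed, imagery), 0.5 * rnorm(800))
  labels <- rep(c("relaxed", "imagery"), each = 400)
  m <- fit_discriminant(feats, labels)
  sc <- decision_value(m, feats)$score
  thr <- select_threshold(sc[labels == "relaxed"][1:200], 0.10)
  expect_identical(classify(m, thr, score = thr$value + 10), "imagery")
  expect_identical(classify(m, thr, score = thr$value - 10), "relaxed")
  # held-out relaxed trials: binomial slack around the cap
  held <- sc[labels == "relaxed"][201:400]
  fpr <- mean(classify(m, thr, score = held) == "imagery")
  expect_lte(fpr, 0.10 + 2 * sqrt(0.10 * 0.90 / 200))
})

test_that("score-density overlap shrinks as ERD deepens", {
  overlaps <- vapply(c(0.1, 0.3, 0.5), function(depth) {
    tr <- small_mi_fixture(n = 15L, seed = 55L, erd_depth = depth)
    m <- mi_train(tr)
    m$report$overlap_area
  }, 0)
  expect_true(all(diff(overlaps) < 0))
})
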