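test_that("class covariances are trace-normalized averages", {
  set.seed(4)
  x <- matrix(rnorm(8 * 4000), 8)          # independent white rows
  cc <- class_covariances(list(x), list(x))
  expect_equal(cc$sigma_L, cc$sigma_R)
  expect_equal(sum(diag(cc$sigma_L)), 1, tolerance = 1e-12)
  off <- cc$sigma_L - diag(diag(cc$sigma_L))
  expect_lt(max(abs(off)), 0.05)
  # duplicating a trial leaves the average unchanged
  y <- matrix(rnorm(8 * 500), 8)
  expect_equal(class_covariances(list(y), list(y))$sigma_L,
               class_covariances(list(y, y, y), list(y))$sigma_L)
  expect_warning(class_covariances(list(y, matrix(0, 8, 500)), list(y)),
                 "all-zero")
  expect_error(suppressWarnings(
    class_covariances(list(matrix(0, 8, 500)), list(y))),
    class = "eemdbci_degenerate_input")
})

test_that("csp_fit solves the hand-solved 2x2 eigenproblem and whitens", {
  sl <- diag(c(2, 1)); sr <- diag(c(1, 2))
  m <- csp_fit(sl, sr, n_pairs = 1L, ridge = 0)
  expect_equal(sort(m$eigenvalues), c(1 / 3, 2 / 3), tolerance = 1e-10)
  # filters align with the coordinate axes
  w <- abs(m$filters / sqrt(rowSums(m$filters^2)))
  expect_equal(sort(w[1, ]), c(0, 1), tolerance = 1e-8)
  expect_equal(sort(w[2, ]), c(0, 1), tolerance = 1e-8)
  # identical classes: all eigenvalues 1/2
  m2 <- csp_fit(diag(3), diag(3), n_pairs = 1L, ridge = 0)
  expect_equal(m2$eigenvalues, rep(0.5, 2), tolerance = 1e-10)
})

test_that("csp filters simultaneously diagonalize both class covariances", {
  set.seed(11)
  a <- matrix(rnorm(64), 8); sl <- crossprod(a) / 8
  b <- matrix(rnorm(64), 8); sr <- crossprod(b) / 8
  m <- csp_fit(sl, sr, n_pairs = 4L)
  for (s in list(sl, sr)) {
    proj <- m$filters %*% s %*% t(m$filters)
    expect_lt(max(abs(proj - diag(diag(proj)))), 1e-6)
  }
  comp <- m$filters %*% (sl + sr) %*% t(m$filters)
  expect_equal(comp, diag(8), tolerance = 1e-5)
  # complementary eigenvalues: lambda_L + lambda_R = 1 per filter
  lam_l <- diag(m$filters %*% sl %*% t(m$filters))
  lam_r <- diag(m$filters %*% sr %*% t(m$filters))
  expect_equal(lam_l + lam_r, rep(1, 8), tolerance = 1e-5)
})

test_that("log-variance features are scale-invariant and discriminative", {
  set.seed(12)
  sl <- diag(c(4, 1, 1, 0.25)); sr <- diag(c(0.25, 1, 1, 4))
  m <- csp_fit(sl, sr, n_pairs = 1L)
  x <- matrix(rnorm(4 * 500), 4) * sqrt(diag(sl))
  f <- csp_features(m, x)
  expect_length(f, 2L)
  expect_equal(csp_features(m, 10 * x), f, tolerance = 1e-10)
  # class-L trials: first-pair feature exceeds the last-pair feature
  hits <- replicate(50, {
    xl <- matrix(rnorm(4 * 500), 4) * sqrt(diag(sl))
    fl <- csp_features(m, xl)
    fl[1] > fl[2]
  })
  expect_gte(mean(hits), 0.9)
  one <- structure(list(filters = matrix(1, 1, 1), eigenvalues = 1,
                        n_pairs = 1L), class = "csp_model")
  expect_equal(csp_features(one, matrix(rnorm(100), 1)), 0)
})

test_that("weighted pairwise scatter matches the brute-force oracle", {
  # two 1-D points {0, 2}, unit weights both directions -> 4
  s <- weighted_pairwise_scatter(matrix(c(0, 2), 2, 1), matrix(1, 2, 2))
  expect_equal(s$matrix[1, 1], 4)
  expect_equal(weighted_pairwise_scatter(matrix(rnorm(10), 5), matrix(0, 5, 5))$matrix,
               matrix(0, 2, 2))
  set.seed(13)
  for (rep in 1:3) {
    n <- sample(4:10, 1); d <- sample(2:4, 1)
    pts <- matrix(rnorm(n * d), n)
    w <- matrix(runif(n * n), n); w <- (w + t(w)) / 2
    got <- weighted_pairwise_scatter(pts, w)$matrix
    expect_equal(got, oracle_pairwise_scatter(pts, w), tolerance = 1e-10)
    ev <- eigen(got, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
  # uniform weights reduce to n times the centered scatter
  pts <- matrix(rnorm(12), 6)
  su <- weighted_pairwise_scatter(pts, matrix(1 / 6, 6, 6))$matrix
  centered <- sweep(pts, 2, colMeans(pts))
  expect_equal(su, crossprod(centered), tolerance = 1e-10)
})

test_that("imf energy profiles scale quadratically and localize tones", {
  pt <- make_test_signal("tone")
  d <- emd(pt$signal$samples)
  e <- imf_energy_profile(d, normalize = TRUE)
  expect_gt(max(e), 0.95)
  d2 <- emd(2 * pt$signal$samples)
  expect_equal(imf_energy_profile(d2), 4 * imf_energy_profile(d),
               tolerance = 1e-6)
  expect_true(all(imf_energy_profile(d) >= 0))
})
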