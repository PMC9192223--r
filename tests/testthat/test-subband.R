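test_that("correlation-based IMF selection reproduces the first-orders rule", {
  # pure fast tone: IMF 1 carries everything
  pt <- make_test_signal("tone")
  d <- emd(pt$signal$samples)
  sel <- select_imfs_by_correlation(d, pt$signal$samples, 1L)
  expect_identical(sel$indices, 1L)
  # mu+beta style sub-band mix: IMFs 1-2 dominate the correlation table
  fs <- 250
  t <- (0:1999) / fs
  x <- sin(2 * pi * 22 * t) + 0.8 * sin(2 * pi * 10 * t) +
    0.02 * sin(2 * pi * 0.4 * t)
  d2 <- emd(x)
  sel2 <- select_imfs_by_correlation(d2, x, 2L)
  expect_identical(sel2$indices, c(1L, 2L))
  expect_gt(sum(sel2$correlations[1:2]), 0.9 * sum(sel2$correlations))
  # k >= #IMFs returns everything, flagged when strictly fewer
  all_sel <- select_imfs_by_correlation(d2, x, length(d2$imfs))
  expect_identical(all_sel$indices, seq_along(d2$imfs))
  expect_false(all_sel$flagged)
  expect_true(select_imfs_by_correlation(d2, x, length(d2$imfs) + 5L)$flagged)
})

test_that("the class matrix has channels x nodes x imfs rows in lexicographic order", {
  tr <- small_mi_fixture(n = 2L, seed = 9L)
  mats <- build_class_matrix(tr)
  expect_named(mats, c("imagery", "relaxed"), ignore.order = TRUE)
  m <- mats$relaxed[[1]]
  expect_identical(dim(m$data), c(8L, 2000L))
  ann <- m$row_annotations
  expect_identical(ann$channel, rep(c("C3", "C4"), each = 4L))
  expect_identical(ann$node, rep(rep(c("(4,1)", "(4,3)"), each = 2L), 2L))
  expect_true(all(diff(ann$imf_index) != 0 | ann$node[-1] != ann$node[-8]))
  # degenerate configuration: 1 channel, 1 node, 1 IMF -> that IMF itself
  sel1 <- subband_selection(nodes = list(c(4L, 1L)), imfs_kept = 1L)
  one <- build_class_matrix(tr, sel1, channels = "C3")
  expect_identical(dim(one$imagery[[1]]$data), c(1L, 2000L))
  band <- wpt_decompose(wavelet_denoise(tr$trials[[1]]["C3", ]), sel1)[[1]]
  d <- emd(band, emd_config(max_imfs = 8L))
  pick <- select_imfs_by_correlation(d, band, 1L)$indices
  idx_relaxed1 <- which(tr$labels == "relaxed")[1]
  band1 <- wpt_decompose(wavelet_denoise(tr$trials[[idx_relaxed1]]["C3", ]), sel1)[[1]]
  d1 <- emd(band1, emd_config(max_imfs = 8L))
  pick1 <- select_imfs_by_correlation(d1, band1, 1L)$indices
  expect_equal(one$relaxed[[1]]$data[1, ], d1$imfs[[pick1]])
  # row-count formula for an arbitrary configuration
  sel3 <- subband_selection(nodes = list(c(4L, 1L), c(4L, 2L), c(4L, 3L)),
                            imfs_kept = 3L)
  m3 <- build_class_matrix(tr, sel3, channels = c("C3", "Cz", "C4"))
  expect_identical(nrow(m3$relaxed[[1]]$data), 3L * 3L * 3L)
  expect_error(build_class_matrix(tr, channels = c("C3", "C7")),
               class = "eemdbci_config_error", regexp = "C7")
})

test_that("reconstructed rows concentrate energy in the mu/beta range", {
  tr <- small_mi_fixture(n = 3L, seed = 21L)
  mats <- build_class_matrix(tr)
  fracs <- unlist(lapply(c(mats$relaxed, mats$imagery), function(m) {
    apply(m$data, 1L, band_energy_fraction, fs = 250, lo = 7, hi = 30)
  }))
  expect_gt(mean(fracs), 0.6)
})
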