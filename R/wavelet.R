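# Orthonormal Daubechies filters (analysis lowpass, ascending index).
# db4 = 4 vanishing moments, 8 taps.
daubechies_filter <- function(wavelet_name) {
  filters <- list(
    db1 = c(0.7071067811865476, 0.7071067811865476),
    db2 = c(-0.12940952255092145, 0.22414386804185735,
            0.836516303737469, 0.48296291314469025),
    db4 = c(-0.010597401784997278, 0.032883011666982945,
            0.030841381835986965, -0.18703481171888114,
            -0.02798376941698385, 0.6308807679295904,
            0.7148465705525415, 0.23037781330885523)
  )
  h <- filters[[wavelet_name]]
  if (is.null(h)) {
    stop(errorCondition(
      sprintf("unknown wavelet '%s' (available: %s)", wavelet_name,
              paste(names(filters), collapse = ", ")),
      class = c("eemdbci_config_error", "error", "condition")))
  }
  h
}

qmf <- function(h) {
  m <- seq_along(h) - 1L
  (-1)^m * rev(h)
}

# One periodized analysis step: x (even length) -> list(a, d) of length n/2.
dwt_step <- function(x, h, g) {
  n <- length(x)
  n2 <- n %/% 2L
  a <- numeric(n2); d <- numeric(n2)
  base <- 2L * (seq_len(n2) - 1L)
  for (m in seq_along(h)) {
    idx <- (base + (m - 1L)) %% n + 1L
    a <- a + h[m] * x[idx]
    d <- d + g[m] * x[idx]
  }
  list(a = a, d = d)
}

# One periodized synthesis step: exact inverse of dwt_step.
idwt_step <- function(a, d, h, g) {
  n2 <- length(a)
  n <- 2L * n2
  x <- numeric(n)
  base <- 2L * (seq_len(n2) - 1L)
  for (m in seq_along(h)) {
    idx <- (base + (m - 1L)) %% n + 1L
    x[idx] <- x[idx] + h[m] * a + g[m] * d
  }
  x
}

# Pad x at the end by symmetric reflection so its length is a multiple of
# 2^level; returns list(x, n_orig).
pad_dyadic <- function(x, level) {
  n <- length(x)
  block <- 2L^level
  rem <- n %% block
  if (rem == 0L) return(list(x = x, n_orig = n))
  k <- block - rem
  if (k > n) {
    stop(errorCondition("signal too short for the requested level",
                        class = c("eemdbci_degenerate_input", "error", "condition")))
  }
  list(x = c(x, x[n:(n - k + 1L)]), n_orig = n)
}

#' Wavelet denoising by universal soft thresholding
#'
#' Multilevel discrete wavelet transform, soft thresholding of all detail
#' coefficients at the universal threshold `sigma * sqrt(2 log n)` with
#' `sigma = median(|finest details|) / 0.6745`, and inverse transform.
#' Signals whose length is not a multiple of `2^level` are symmetrically
#' padded and the result truncated back.
#'
#' @param x An `eeg_signal` or numeric vector, length >= `2^level`.
#' @param wavelet_name Wavelet family, one of `"db1"`, `"db2"`, `"db4"`.
#' @param level Decomposition depth (default 4).
#' @return Same type as the input, denoised, same length.
#' @export
wavelet_denoise <- function(x, wavelet_name = "db4", level = 4L) {
  samp <- sig_samples(x)
  if (length(samp) < 2L^level) {
    stop(errorCondition("signal shorter than 2^level; reduce the level",
                        class = c("eemdbci_degenerate_input", "error", "condition")))
  }
  h <- daubechies_filter(wavelet_name)
  g <- qmf(h)
  p <- pad_dyadic(samp, level)
  a <- p$x
  details <- vector("list", level)
  for (l in seq_len(level)) {
    s <- dwt_step(a, h, g)
    a <- s$a
    details[[l]] <- s$d
  }
  sigma <- stats::median(abs(details[[1L]])) / 0.6745
  thr <- sigma * sqrt(2 * log(length(p$x)))
  soft <- function(w) sign(w) * pmax(abs(w) - thr, 0)
  details <- lapply(details, soft)
  for (l in rev(seq_len(level))) {
    a <- idwt_step(a, details[[l]], h, g)
  }
  out <- a[seq_len(p$n_orig)]
  if (inherits(x, "eeg_signal")) {
    x$samples <- out
    x
  } else out
}

#' Sub-band selection configuration
#'
#' Defines which wavelet-packet nodes are kept and how many IMFs of each
#' node's decomposition are retained. Node indices follow `node_order`:
#' `"frequency"` (default) numbers the `2^level` leaves by ascending
#' passband, so node `(level, i)` covers roughly
#' `[i, i + 1] * fs / 2^(level + 1)` Hz; `"natural"` uses the filter-bank
#' tree order. The defaults — level-4 nodes (4,1) and (4,3), two IMFs each,
#' db4 — target the sensorimotor mu and beta rhythms at 250 Hz sampling.
#'
#' @param wpt_level Wavelet-packet depth.
#' @param nodes List of `c(level, index)` pairs; all at `wpt_level`.
#' @param imfs_kept IMFs retained per node (>= 1).
#' @param wavelet_name Wavelet family (see [wavelet_denoise()]).
#' @param node_order `"frequency"` or `"natural"`.
#' @return A `subband_selection` list.
#' @export
subband_selection <- function(wpt_level = 4L,
                              nodes = list(c(4L, 1L), c(4L, 3L)),
                              imfs_kept = 2L, wavelet_name = "db4",
                              node_order = c("frequency", "natural")) {
  node_order <- match.arg(node_order)
  if (imfs_kept < 1) {
    stop(errorCondition("imfs_kept must be >= 1",
                        class = c("eemdbci_config_error", "error", "condition")))
  }
  for (nd in nodes) {
    if (length(nd) != 2L || nd[1] != wpt_level || nd[2] < 0 || nd[2] >= 2^nd[1]) {
      stop(errorCondition(
        sprintf("invalid node (%s): need (wpt_level, 0 <= index < 2^level)",
                paste(nd, collapse = ", ")),
        class = c("eemdbci_config_error", "error", "condition")))
    }
  }
  structure(list(wpt_level = as.integer(wpt_level), nodes = nodes,
                 imfs_kept = as.integer(imfs_kept),
                 wavelet_name = wavelet_name, node_order = node_order),
            class = "subband_selection")
}

# frequency-order position f -> natural (tree) index: binary-reflected
# Gray code, accounting for the highpass branch band reversal.
freq_to_natural <- function(f) {
  bitwXor(as.integer(f), bitwShiftR(as.integer(f), 1L))
}

#' Wavelet-packet decomposition with per-node reconstruction
#'
#' Builds the full wavelet-packet tree to `wpt_level` and reconstructs each
#' requested node back to full signal length with all other nodes zeroed.
#' The reconstructions of all `2^level` nodes sum to the input exactly
#' (perfect-reconstruction filter bank).
#'
#' @param x An `eeg_signal` or numeric vector, length >= `2^wpt_level`.
#' @param selection A [subband_selection()]; all its `nodes` are returned.
#' @param all_nodes If `TRUE`, reconstruct every node at `wpt_level`
#'   instead of only the selected ones.
#' @return Named list of numeric vectors (full signal length), one per
#'   node, named `"(level,index)"` in the selection's `node_order`.
#' @export
wpt_decompose <- function(x, selection = subband_selection(),
                          all_nodes = FALSE) {
  samp <- sig_samples(x)
  L <- selection$wpt_level
  if (length(samp) < 2L^L) {
    stop(errorCondition("signal shorter than 2^wpt_level",
                        class = c("eemdbci_degenerate_input", "error", "condition")))
  }
  h <- daubechies_filter(selection$wavelet_name)
  g <- qmf(h)
  p <- pad_dyadic(samp, L)
  # full tree, natural order: level l has 2^l coefficient vectors
  coefs <- list(list(p$x))
  for (l in seq_len(L)) {
    prev <- coefs[[l]]
    cur <- vector("list", 2L * length(prev))
    for (i in seq_along(prev)) {
      s <- dwt_step(prev[[i]], h, g)
      cur[[2L * i - 1L]] <- s$a
      cur[[2L * i]] <- s$d
    }
    coefs[[l + 1L]] <- cur
  }
  leaves <- coefs[[L + 1L]]
  wanted <- if (all_nodes) lapply(0:(2L^L - 1L), function(i) c(L, i)) else selection$nodes
  out <- vector("list", length(wanted))
  names(out) <- vapply(wanted, function(nd) sprintf("(%d,%d)", nd[1], nd[2]), "")
  for (w in seq_along(wanted)) {
    idx <- wanted[[w]][2]
    nat <- if (selection$node_order == "frequency") freq_to_natural(idx) else as.integer(idx)
    a <- leaves[[nat + 1L]]
    # synthesize up the tree: at each level the sibling branch is zero
    bits <- integer(L)
    v <- nat
    for (l in seq_len(L)) {
      bits[l] <- v %% 2L
      v <- v %/% 2L
    }
    for (l in seq_len(L)) {   # bits[1] = deepest branch
      z <- numeric(length(a))
      a <- if (bits[l] == 0L) idwt_step(a, z, h, g) else idwt_step(z, a, h, g)
    }
    out[[w]] <- a[seq_len(p$n_orig)]
  }
  out
}

#' Passband of a frequency-ordered wavelet-packet node
#'
#' @param node `c(level, index)` in frequency order.
#' @param sampling_rate Sampling rate in Hz.
#' @return `c(low, high)` nominal band edges in Hz.
#' @export
wpt_node_band <- function(node, sampling_rate) {
  width <- sampling_rate / 2 / 2^node[1]
  c(node[2], node[2] + 1) * width
}
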