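#' EEMD configuration
#'
#' @param ensemble_size Number of noise-perturbed copies `m` (>= 1).
#' @param noise_std_ratio Added white-noise SD as a fraction of the
#'   signal's SD (>= 0). 0.2 is the conventional operating point.
#' @param seed Master seed; every ensemble member draws from its own
#'   deterministic substream derived from `(seed, member index)`.
#' @param emd An [emd_config()] used for every member decomposition.
#' @return An `eemd_config` list.
#' @export
eemd_config <- function(ensemble_size = 100L, noise_std_ratio = 0.2,
                        seed = 1L, emd = emd_config()) {
  if (ensemble_size < 1) {
    stop(errorCondition("ensemble_size must be >= 1",
                        class = c("eemdbci_config_error", "error", "condition")))
  }
  if (noise_std_ratio < 0) {
    stop(errorCondition("noise_std_ratio must be >= 0",
                        class = c("eemdbci_config_error", "error", "condition")))
  }
  structure(list(ensemble_size = as.integer(ensemble_size),
                 noise_std_ratio = noise_std_ratio,
                 seed = as.integer(seed), emd = emd),
            class = "eemd_config")
}

# Deterministic substream seed from (master seed, stream index); kept
# within the 32-bit signed range R requires.
substream_seed <- function(seed, stream_index) {
  (as.double(seed) * 69069 + as.double(stream_index) * 40014 + 12345) %%
    2147483647
}

# Run fn() under a temporary RNG state seeded from (seed, stream_index),
# restoring the caller's RNG state afterwards.
with_substream <- function(seed, stream_index, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, stream_index))
  fn()
}

#' Add one white-noise realization to a signal
#'
#' Adds iid Gaussian noise with the given SD, drawn from a reproducible
#' substream: identical `(seed, stream_index)` pairs give bitwise-identical
#' output, distinct stream indices give independent streams. The caller's
#' RNG state is left untouched.
#'
#' @param x An `eeg_signal` or numeric vector.
#' @param noise_std Noise standard deviation (>= 0, absolute units).
#' @param stream_index Integer substream index (ensemble member number).
#' @param seed Master seed.
#' @return Same type as the input with noise added.
#' @export
add_noise_realization <- function(x, noise_std, stream_index, seed) {
  if (noise_std < 0) {
    stop(errorCondition("noise_std must be >= 0",
                        class = c("eemdbci_config_error", "error", "condition")))
  }
  samp <- sig_samples(x)
  if (noise_std == 0) return(x)
  noise <- with_substream(seed, stream_index,
                          function() stats::rnorm(length(samp), 0, noise_std))
  if (inherits(x, "eeg_signal")) {
    x$samples <- samp + noise
    x
  } else samp + noise
}

#' Ensemble empirical mode decomposition
#'
#' Decomposes `m` white-noise-perturbed copies of the signal with [emd()]
#' and averages IMFs across members, index-aligned (members with fewer
#' IMFs are zero-padded at the high-index end). The added noise realizations
#' cancel in the average, which suppresses the mode mixing that plain EMD
#' shows on intermittent signals. With `noise_std_ratio = 0` and
#' `ensemble_size = 1` the result equals plain EMD exactly.
#'
#' @inheritParams add_noise_realization
#' @param config An [eemd_config()].
#' @return An `eemd_decomposition`: `mean_imfs` (list), `mean_residual`,
#'   `ensemble_size`, `per_member_imf_counts`, `noise_std` (absolute SD
#'   used) and `mean_added_noise` (average of the injected noise; the mean
#'   components sum to `signal + mean_added_noise` exactly).
#' @export
eemd <- function(x, config = eemd_config()) {
  samp <- sig_samples(x)
  noise_std <- config$noise_std_ratio * stats::sd(samp)
  m <- config$ensemble_size
  counts <- integer(m)
  sum_imfs <- list()
  sum_residual <- numeric(length(samp))
  sum_noise <- numeric(length(samp))
  for (j in seq_len(m)) {
    noisy <- if (noise_std > 0)
      add_noise_realization(samp, noise_std, j, config$seed) else samp
    sum_noise <- sum_noise + (noisy - samp)
    d <- emd(noisy, config$emd)
    counts[j] <- length(d$imfs)
    for (k in seq_along(d$imfs)) {
      if (k > length(sum_imfs)) sum_imfs[[k]] <- numeric(length(samp))
      sum_imfs[[k]] <- sum_imfs[[k]] + d$imfs[[k]]
    }
    sum_residual <- sum_residual + d$residual
  }
  structure(list(mean_imfs = lapply(sum_imfs, function(v) v / m),
                 mean_residual = sum_residual / m,
                 ensemble_size = m,
                 per_member_imf_counts = counts,
                 noise_std = noise_std,
                 mean_added_noise = sum_noise / m),
            class = "eemd_decomposition")
}

#' @export
print.eemd_decomposition <- function(x, ...) {
  cat(sprintf("<eemd_decomposition: %d mean IMFs, ensemble of %d, noise SD %.4g>\n",
              length(x$mean_imfs), x$ensemble_size, x$noise_std))
  invisible(x)
}
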