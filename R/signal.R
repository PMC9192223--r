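#' Construct a single-channel signal
#'
#' Light container for one channel of uniformly sampled data. All
#' decomposition functions accept either an `eeg_signal` or a bare numeric
#' vector (in which case a sampling rate of 1 Hz is assumed).
#'
#' @param samples Numeric vector of at least 4 finite samples (arbitrary
#'   units, typically microvolts).
#' @param sampling_rate Sampling rate in Hz, strictly positive.
#' @param channel_label Optional channel name (e.g. `"C3"`).
#' @return An object of class `eeg_signal` with fields `samples`,
#'   `sampling_rate` and `channel_label`.
#' @examples
#' s <- signal(sin(2 * pi * 10 * seq(0, 1, by = 1 / 250)), 250, "C3")
#' s
#' @export
signal <- function(samples, sampling_rate, channel_label = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 4L) {
    stop(errorCondition("signal must have at least 4 samples",
                        class = c("eemdbci_degenerate_input", "error", "condition")))
  }
  if (!all(is.finite(samples))) {
    stop(errorCondition("signal samples must all be finite",
                        class = c("eemdbci_degenerate_input", "error", "condition")))
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop(errorCondition("sampling_rate must be a single positive number",
                        class = c("eemdbci_config_error", "error", "condition")))
  }
  structure(list(samples = samples, sampling_rate = as.numeric(sampling_rate),
                 channel_label = channel_label),
            class = "eeg_signal")
}

#' @export
print.eeg_signal <- function(x, ...) {
  lab <- if (is.null(x$channel_label)) "" else paste0(" [", x$channel_label, "]")
  cat(sprintf("<eeg_signal%s: %d samples @ %g Hz (%.3g s)>\n", lab,
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  invisible(x)
}

# Coerce numeric vectors to eeg_signal; validate existing signals.
as_signal <- function(x, sampling_rate = 1) {
  if (inherits(x, "eeg_signal")) return(x)
  signal(x, sampling_rate)
}

# Extract raw samples from eeg_signal or numeric vector.
sig_samples <- function(x) {
  if (inherits(x, "eeg_signal")) x$samples else as.numeric(x)
}

#' Time axis of a signal
#'
#' @param x An `eeg_signal`.
#' @return Numeric vector of times in seconds, `t = (index - 1) / fs`.
#' @export
signal_time <- function(x) {
  stopifnot(inherits(x, "eeg_signal"))
  (seq_along(x$samples) - 1) / x$sampling_rate
}
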