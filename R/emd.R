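#' EMD configuration
#'
#' Parameters controlling the sifting loop of empirical mode decomposition.
#' The sifting-stop statistic is the normalized squared change between
#' successive proto-IMFs,
#' \deqn{SD = \sum_t (h_k(t) - h_{k-1}(t))^2 / \sum_t h_{k-1}(t)^2,}
#' and sifting stops once it falls below `sd_threshold`. Values between 0.2
#' and 0.3 are the accepted operating range; the default is the midpoint.
#'
#' @param sd_threshold Sifting-stop threshold in (0, 1]. Default 0.25.
#' @param max_sift_iterations Safety cap on sifting iterations per IMF.
#' @param max_imfs Maximum number of IMFs to extract (`Inf` = until the
#'   residual is non-oscillatory).
#' @param boundary_mode Envelope boundary handling: `"mirror"` reflects two
#'   extrema about each end before spline fitting, `"clamp"` holds the
#'   nearest extremum value at the endpoints.
#' @return An `emd_config` list.
#' @export
emd_config <- function(sd_threshold = 0.25, max_sift_iterations = 100L,
                       max_imfs = Inf, boundary_mode = c("mirror", "clamp")) {
  boundary_mode <- match.arg(boundary_mode)
  if (!is.numeric(sd_threshold) || length(sd_threshold) != 1L ||
      sd_threshold <= 0 || sd_threshold > 1) {
    stop(errorCondition("sd_threshold must lie in (0, 1]",
                        class = c("eemdbci_config_error", "error", "condition")))
  }
  if (max_sift_iterations < 1) {
    stop(errorCondition("max_sift_iterations must be >= 1",
                        class = c("eemdbci_config_error", "error", "condition")))
  }
  structure(list(sd_threshold = sd_threshold,
                 max_sift_iterations = as.integer(max_sift_iterations),
                 max_imfs = max_imfs,
                 boundary_mode = boundary_mode),
            class = "emd_config")
}

#' Locate local extrema
#'
#' Strict local maxima and minima by neighbor comparison. A flat run of
#' equal samples contributes exactly one extremum, at the first index of the
#' run. Endpoints are never reported as interior extrema.
#'
#' @param x An `eeg_signal` or numeric vector (length >= 4).
#' @return A list with integer vectors `maxima` and `minima` (strictly
#'   increasing sample indices, 1-based).
#' @export
find_extrema <- function(x) {
  x <- sig_samples(x)
  n <- length(x)
  if (n < 4L) {
    stop(errorCondition("find_extrema needs at least 4 samples",
                        class = c("eemdbci_degenerate_input", "error", "condition")))
  }
  d <- diff(x)
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2L) return(list(maxima = integer(0), minima = integer(0)))
  # positions (within nz) where the slope sign flips
  flip <- which(s[nz[-1]] != s[nz[-length(nz)]])
  if (!length(flip)) return(list(maxima = integer(0), minima = integer(0)))
  # the extremum is the sample just after the last rising/falling step;
  # a flat run [x_k == x_{k+1} == ...] keeps only its first index
  at <- nz[flip] + 1L
  is_max <- s[nz[flip]] > 0
  list(maxima = at[is_max], minima = at[!is_max])
}

# Cubic-spline envelope through the given extrema, extended at the
# boundaries. mirror: reflect up to two extrema about each end; clamp: pin
# the end samples at the nearest extremum value.
spline_envelope <- function(x, idx, boundary_mode) {
  n <- length(x)
  val <- x[idx]
  if (boundary_mode == "mirror") {
    k <- min(2L, length(idx))
    lx <- 2L - idx[seq_len(k)]                       # reflect about index 1
    ly <- val[seq_len(k)]
    rx <- 2L * n - idx[length(idx) - seq_len(k) + 1L] # reflect about index n
    ry <- val[length(val) - seq_len(k) + 1L]
    xs <- c(rev(lx), idx, rev(rx))
    ys <- c(rev(ly), val, rev(ry))
  } else {
    xs <- c(if (idx[1] > 1L) 1L, idx, if (idx[length(idx)] < n) n)
    ys <- c(if (idx[1] > 1L) val[1], val, if (idx[length(idx)] < n) val[length(val)])
  }
  stats::spline(xs, ys, xout = seq_len(n), method = "fmm")$y
}

#' Mean of the upper and lower extrema envelopes
#'
#' The quantity subtracted from the signal at each sifting step: cubic
#' splines are fitted through the maxima and through the minima, and their
#' pointwise mean is returned.
#'
#' @inheritParams find_extrema
#' @param boundary_mode See [emd_config()].
#' @return Numeric vector of the same length as the input.
#' @export
mean_envelope <- function(x, boundary_mode = c("mirror", "clamp")) {
  boundary_mode <- match.arg(boundary_mode)
  x <- sig_samples(x)
  e <- find_extrema(x)
  if (length(e$maxima) < 2L || length(e$minima) < 2L) {
    stop(errorCondition("envelope undefined: fewer than 2 maxima or 2 minima",
                        class = c("eemdbci_envelope_undefined", "error", "condition")))
  }
  upper <- spline_envelope(x, e$maxima, boundary_mode)
  lower <- spline_envelope(x, e$minima, boundary_mode)
  (upper + lower) / 2
}

#' Sifting-stop statistic
#'
#' Normalized squared change between successive proto-IMFs,
#' `sum((curr - prev)^2) / sum(prev^2)`.
#'
#' @param curr,prev Numeric vectors of equal length; `prev` must not be
#'   identically zero.
#' @return Nonnegative scalar.
#' @export
sd_criterion <- function(curr, prev) {
  if (length(curr) != length(prev)) {
    stop(errorCondition("curr and prev must have equal length",
                        class = c("eemdbci_config_error", "error", "condition")))
  }
  denom <- sum(prev^2)
  if (denom == 0) {
    stop(errorCondition("sd_criterion undefined: prev is identically zero",
                        class = c("eemdbci_degenerate_input", "error", "condition")))
  }
  sum((curr - prev)^2) / denom
}

# |#extrema - #zero-crossings| for the IMF admissibility condition.
imf_condition_gap <- function(x) {
  e <- find_extrema(x)
  n_ext <- length(e$maxima) + length(e$minima)
  s <- sign(x)
  s <- s[s != 0]
  n_zc <- if (length(s) > 1L) sum(s[-1] != s[-length(s)]) else 0L
  abs(n_ext - n_zc)
}

#' Sift one intrinsic mode function from a signal
#'
#' Iterates `h <- h - mean_envelope(h)` until the SD statistic between
#' successive proto-IMFs falls below the configured threshold (and the IMF
#' admissibility condition, |#extrema - #zero-crossings| <= 1, holds), or
#' the iteration cap is reached.
#'
#' @inheritParams find_extrema
#' @param config An [emd_config()].
#' @return A list with `imf` (numeric vector) and `trace`, a data frame
#'   with one row per sifting iteration (`iteration`, `sd`) plus a
#'   `converged` attribute-like column on the last row via the `converged`
#'   list field.
#' @export
extract_imf <- function(x, config = emd_config()) {
  h <- sig_samples(x)
  sds <- numeric(0)
  converged <- FALSE
  for (it in seq_len(config$max_sift_iterations)) {
    m <- tryCatch(mean_envelope(h, config$boundary_mode),
                  eemdbci_envelope_undefined = function(e) NULL)
    if (is.null(m)) break   # sifting stripped the extrema; keep current h
    h_new <- h - m
    sd_val <- sd_criterion(h_new, h)
    sds[it] <- sd_val
    h <- h_new
    if (sd_val < config$sd_threshold && imf_condition_gap(h) <= 1L) {
      converged <- TRUE
      break
    }
  }
  list(imf = h,
       trace = data.frame(iteration = seq_along(sds), sd = sds),
       converged = converged)
}

#' Empirical mode decomposition
#'
#' Peels IMFs from successive residuals, `r_j = r_{j-1} - c_j`, until the
#' residual has fewer than 2 maxima or fewer than 2 minima (a monotone or
#' trend-like remainder) or `max_imfs` is reached. The components always
#' satisfy the reconstruction identity `x = sum(c_j) + r_n` exactly, by
#' construction.
#'
#' @inheritParams extract_imf
#' @return An `emd_decomposition`: list with `imfs` (list of numeric
#'   vectors, fastest mode first), `residual`, `source_length`,
#'   `sd_threshold_used`, `terminal_sd` (SD at the accepting iteration per
#'   IMF; `NA` when sifting hit the iteration cap), `n_sifts` and
#'   `converged` per IMF.
#' @examples
#' t <- seq(0, 4, by = 1 / 250)
#' x <- sin(2 * pi * 1 * t) + 0.5 * sin(2 * pi * 12 * t)
#' d <- emd(x)
#' length(d$imfs)
#' max(abs(x - reconstruct(d)))  # ~ machine precision
#' @export
emd <- function(x, config = emd_config()) {
  x <- sig_samples(x)
  if (length(x) < 4L) {
    stop(errorCondition("emd needs at least 4 samples",
                        class = c("eemdbci_degenerate_input", "error", "condition")))
  }
  r <- x
  imfs <- list()
  terminal_sd <- numeric(0)
  n_sifts <- integer(0)
  converged <- logical(0)
  while (length(imfs) < config$max_imfs) {
    e <- find_extrema(r)
    if (length(e$maxima) < 2L || length(e$minima) < 2L) break
    s <- extract_imf(r, config)
    imfs[[length(imfs) + 1L]] <- s$imf
    terminal_sd <- c(terminal_sd,
                     if (s$converged) s$trace$sd[nrow(s$trace)] else NA_real_)
    n_sifts <- c(n_sifts, nrow(s$trace))
    converged <- c(converged, s$converged)
    r <- r - s$imf
  }
  structure(list(imfs = imfs, residual = r, source_length = length(x),
                 sd_threshold_used = config$sd_threshold,
                 terminal_sd = terminal_sd, n_sifts = n_sifts,
                 converged = converged),
            class = "emd_decomposition")
}

#' @export
print.emd_decomposition <- function(x, ...) {
  cat(sprintf("<emd_decomposition: %d IMFs + residual, n = %d, SD threshold %g>\n",
              length(x$imfs), x$source_length, x$sd_threshold_used))
  invisible(x)
}

#' Sum the components of a decomposition
#'
#' @param d An `emd_decomposition` or `eemd_decomposition`.
#' @return Numeric vector `sum(IMFs) + residual`.
#' @export
reconstruct <- function(d) {
  imfs <- if (inherits(d, "eemd_decomposition")) d$mean_imfs else d$imfs
  res <- if (inherits(d, "eemd_decomposition")) d$mean_residual else d$residual
  out <- res
  for (c_j in imfs) out <- out + c_j
  out
}
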