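#' Labeled multichannel trial set
#'
#' @param trials List of channel-by-sample numeric matrices, all the same
#'   shape, one per trial.
#' @param labels Character/factor vector, one label per trial (e.g.
#'   `"relaxed"` / `"imagery"`).
#' @param channel_names Channel names, length `nrow(trials[[1]])`.
#' @param sampling_rate Sampling rate in Hz.
#' @return A `trial_set`.
#' @export
trial_set <- function(trials, labels, channel_names, sampling_rate) {
  if (!length(trials)) {
    stop(errorCondition("empty trial list",
                        class = c("eemdbci_degenerate_input", "error", "condition")))
  }
  if (length(labels) != length(trials)) {
    stop(errorCondition("labels length must equal the number of trials",
                        class = c("eemdbci_config_error", "error", "condition")))
  }
  dims <- dim(trials[[1]])
  for (i in seq_along(trials)) {
    trials[[i]] <- as.matrix(trials[[i]])
    if (!identical(dim(trials[[i]]), dims)) {
      stop(errorCondition(sprintf("trial %d has a different shape", i),
                          class = c("eemdbci_config_error", "error", "condition")))
    }
    rownames(trials[[i]]) <- channel_names
  }
  if (length(channel_names) != dims[1]) {
    stop(errorCondition("channel_names length must equal the channel count",
                        class = c("eemdbci_config_error", "error", "condition")))
  }
  structure(list(trials = trials, labels = as.character(labels),
                 channel_names = channel_names,
                 sampling_rate = as.numeric(sampling_rate)),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<trial_set: %d trials (%s), %d channels [%s], %d samples @ %g Hz>\n",
              length(x$trials),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              length(x$channel_names),
              paste(x$channel_names, collapse = ","),
              ncol(x$trials[[1]]), x$sampling_rate))
  invisible(x)
}

#' Retain the IMFs most correlated with the source signal
#'
#' Ranks IMFs by the absolute Pearson correlation with the original signal
#' and keeps the `k` highest, ties broken toward the lower IMF index. On
#' sub-band signals whose energy sits in the fastest modes this reproduces
#' the "first two orders" rule. A zero-variance IMF scores 0.
#'
#' @param decomp An `emd_decomposition` from [emd()].
#' @param original The signal that was decomposed (`eeg_signal` or numeric).
#' @param k Number of IMFs to keep.
#' @return List with `indices` (ascending), `correlations` (per IMF) and
#'   `flagged` (`TRUE` when fewer than `k` IMFs were available).
#' @export
select_imfs_by_correlation <- function(decomp, original, k = 2L) {
  if (!length(decomp$imfs)) {
    stop(errorCondition("decomposition has no IMFs",
                        class = c("eemdbci_degenerate_input", "error", "condition")))
  }
  if (k < 1) {
    stop(errorCondition("k must be >= 1",
                        class = c("eemdbci_config_error", "error", "condition")))
  }
  x <- sig_samples(original)
  cors <- vapply(decomp$imfs, function(c_j) {
    if (stats::sd(c_j) == 0 || stats::sd(x) == 0) return(0)
    abs(stats::cor(c_j, x))
  }, 0)
  if (length(cors) <= k) {
    return(list(indices = seq_along(cors), correlations = cors,
                flagged = length(cors) < k))
  }
  ord <- order(-cors, seq_along(cors))   # ties -> lower IMF index
  list(indices = sort(ord[seq_len(k)]), correlations = cors, flagged = FALSE)
}

# Decompose one trial into its stacked sub-band IMF rows.
# Returns a reconstructed_matrix: rows = |channels| * |nodes| * imfs_kept.
trial_subband_matrix <- function(trial, channels, selection, emd_cfg,
                                 denoise = TRUE, class_label = NA_character_) {
  missing_ch <- setdiff(channels, rownames(trial))
  if (length(missing_ch)) {
    stop(errorCondition(
      sprintf("channel(s) not present in trial: %s",
              paste(missing_ch, collapse = ", ")),
      class = c("eemdbci_config_error", "error", "condition")))
  }
  k <- selection$imfs_kept
  n_nodes <- length(selection$nodes)
  n_rows <- length(channels) * n_nodes * k
  n_samp <- ncol(trial)
  data <- matrix(0, n_rows, n_samp)
  ann <- data.frame(channel = character(n_rows), node = character(n_rows),
                    imf_index = NA_integer_, stringsAsFactors = FALSE)
  row <- 0L
  for (ch in channels) {
    x <- trial[ch, ]
    if (denoise) x <- wavelet_denoise(x, selection$wavelet_name)
    bands <- wpt_decompose(x, selection)
    for (b in seq_len(n_nodes)) {
      band <- bands[[b]]
      node_name <- names(bands)[b]
      d <- emd(band, emd_cfg)
      sel <- if (length(d$imfs))
        select_imfs_by_correlation(d, band, k) else
        list(indices = integer(0), flagged = TRUE)
      if (sel$flagged) {
        warning(sprintf("fewer than %d IMFs for %s node %s; zero-padding rows",
                        k, ch, node_name))
      }
      for (j in seq_len(k)) {
        row <- row + 1L
        ann$channel[row] <- ch
        ann$node[row] <- node_name
        if (j <= length(sel$indices)) {
          idx <- sel$indices[j]
          data[row, ] <- d$imfs[[idx]]
          ann$imf_index[row] <- idx
        }
      }
    }
  }
  structure(list(data = data, row_annotations = ann,
                 class_label = class_label),
            class = "reconstructed_matrix")
}

#' Per-class stacked sub-band IMF matrices
#'
#' For every trial, every requested channel and every selected
#' wavelet-packet node: (optionally) wavelet-denoise the channel, extract
#' the node sub-band, decompose it with EMD, retain `imfs_kept` IMFs by the
#' correlation rule, and stack the retained IMFs as rows. Rows are ordered
#' lexicographically by (channel, node, IMF). With the defaults — 2
#' channels (C3, C4), 2 nodes, 2 IMFs — each 2000-sample trial yields an
#' 8 x 2000 matrix.
#'
#' @param trials A [trial_set()].
#' @param selection A [subband_selection()].
#' @param channels Channels to use (must exist in the trial set).
#' @param emd_cfg [emd_config()] for the per-node decompositions;
#'   `max_imfs` is capped by default to bound runtime.
#' @param denoise Apply [wavelet_denoise()] to each channel first.
#' @param concatenate If `TRUE`, cbind each class's trial matrices into one
#'   wide matrix; otherwise (default) keep a per-trial list.
#' @return Named list, one entry per class label; each entry a list of
#'   `reconstructed_matrix` objects (or a single wide matrix when
#'   `concatenate = TRUE`).
#' @export
build_class_matrix <- function(trials, selection = subband_selection(),
                               channels = c("C3", "C4"),
                               emd_cfg = emd_config(max_imfs = 8L),
                               denoise = TRUE, concatenate = FALSE) {
  missing_ch <- setdiff(channels, trials$channel_names)
  if (length(missing_ch)) {
    stop(errorCondition(
      sprintf("channel(s) missing from trial set: %s",
              paste(missing_ch, collapse = ", ")),
      class = c("eemdbci_config_error", "error", "condition")))
  }
  mats <- lapply(seq_along(trials$trials), function(i) {
    trial_subband_matrix(trials$trials[[i]], channels, selection, emd_cfg,
                         denoise, trials$labels[i])
  })
  out <- split(mats, trials$labels)
  if (concatenate) {
    out <- lapply(out, function(ms) do.call(cbind, lapply(ms, `[[`, "data")))
  }
  out
}
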