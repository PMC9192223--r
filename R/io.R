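# FNV-1a 32-bit hash of a string; used to stamp artifacts with the config
# that produced them (no cryptographic intent).
fnv1a_hash <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Hash a configuration object
#'
#' Stable 8-hex-digit fingerprint of any R list/config, written into every
#' artifact manifest so outputs can be traced to the settings that
#' produced them.
#'
#' @param config Any serializable R object.
#' @return 8-character hex string.
#' @export
config_hash <- function(config) {
  fnv1a_hash(paste(deparse(config), collapse = "\n"))
}

#' Write a trial set as plain-text CSV files
#'
#' One `trial_NNN.csv` per trial (first column `channel`, remaining columns
#' samples), a `labels.csv` sidecar (`trial_id,label`) and a
#' `manifest.json` carrying the sampling rate, channel names and config
#' hash.
#'
#' @param trials A [trial_set()].
#' @param dir Output directory (created if missing).
#' @param extra Optional named list merged into the manifest.
#' @return The directory path, invisibly.
#' @export
write_trials <- function(trials, dir, extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("trial_%03d", seq_along(trials$trials))
  for (i in seq_along(trials$trials)) {
    df <- data.frame(channel = trials$channel_names,
                     trials$trials[[i]], check.names = FALSE)
    names(df)[-1] <- paste0("s", seq_len(ncol(trials$trials[[i]])))
    utils::write.csv(df, file.path(dir, paste0(ids[i], ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(data.frame(trial_id = ids, label = trials$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  manifest <- c(list(sampling_rate = trials$sampling_rate,
                     channels = trials$channel_names,
                     n_trials = length(trials$trials),
                     n_samples = ncol(trials$trials[[1]])),
                extra)
  manifest$config_hash <- config_hash(manifest)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a trial set from disk
#'
#' CSV layout: one file per trial with a `channel` column followed by
#' sample columns, a `labels.csv` sidecar and a `manifest.json` with the
#' sampling rate (see [write_trials()]). EDF layout: one EDF file per
#' trial (each read as a single epoch), plus the same `labels.csv`.
#'
#' @param path Directory containing the files.
#' @param format `"csv"` or `"edf"`.
#' @param valid_labels Accepted class tokens.
#' @return A [trial_set()].
#' @export
read_trials <- function(path, format = c("csv", "edf"),
                        valid_labels = c("relaxed", "imagery", "left", "right")) {
  format <- match.arg(format)
  labels_file <- file.path(path, "labels.csv")
  if (!file.exists(labels_file)) {
    stop(errorCondition(sprintf("no labels.csv in %s", path),
                        class = c("eemdbci_io_error", "error", "condition")))
  }
  lab <- utils::read.csv(labels_file, stringsAsFactors = FALSE)
  bad <- setdiff(unique(lab$label), valid_labels)
  if (length(bad)) {
    stop(errorCondition(
      sprintf("unknown label token(s): %s", paste(bad, collapse = ", ")),
      class = c("eemdbci_io_error", "error", "condition")))
  }
  if (!nrow(lab)) {
    stop(errorCondition("labels.csv lists no trials",
                        class = c("eemdbci_io_error", "error", "condition")))
  }
  if (format == "csv") {
    manifest_file <- file.path(path, "manifest.json")
    if (!file.exists(manifest_file)) {
      stop(errorCondition(sprintf("no manifest.json in %s", path),
                          class = c("eemdbci_io_error", "error", "condition")))
    }
    manifest <- jsonlite::read_json(manifest_file, simplifyVector = TRUE)
    trials <- lapply(lab$trial_id, function(id) {
      f <- file.path(path, paste0(id, ".csv"))
      if (!file.exists(f)) {
        stop(errorCondition(sprintf("missing trial file %s", f),
                            class = c("eemdbci_io_error", "error", "condition")))
      }
      df <- utils::read.csv(f, stringsAsFactors = FALSE, check.names = FALSE)
      m <- as.matrix(df[, -1, drop = FALSE])
      rownames(m) <- df$channel
      dimnames(m)[[2]] <- NULL
      m
    })
    channels <- rownames(trials[[1]])
    fs <- manifest$sampling_rate
  } else {
    recs <- lapply(lab$trial_id, function(id) {
      read_edf(file.path(path, paste0(id, ".edf")))
    })
    trials <- lapply(recs, `[[`, "data")
    channels <- recs[[1]]$channels
    fs <- recs[[1]]$sampling_rate
  }
  trial_set(trials, lab$label, channels, fs)
}

#' Read a European Data Format (EDF) recording
#'
#' Minimal reader for uncompressed EDF: parses the fixed-width ASCII
#' header, reads the 16-bit little-endian sample records and rescales to
#' physical units. All signals must share one sampling rate.
#'
#' @param path Path to a `.edf` file.
#' @return List with `data` (channel-by-sample matrix, rownames =
#'   channel labels), `channels` and `sampling_rate`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchar) trimws(rawToChar(readBin(con, "raw", nchar)))
  rd(8)                                   # version
  rd(80); rd(80); rd(8); rd(8)            # patient, recording, date, time
  rd(8)                                   # header bytes
  rd(44)                                  # reserved
  n_records <- as.integer(rd(8))
  record_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)           # transducer
  for (i in seq_len(ns)) rd(8)            # physical dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)           # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)           # reserved
  if (length(unique(spr / record_dur)) != 1L) {
    stop(errorCondition("EDF signals have differing sampling rates",
                        class = c("eemdbci_io_error", "error", "condition")))
  }
  data <- matrix(0, ns, n_records * spr[1],
                 dimnames = list(labels, NULL))
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", spr[i], size = 2L, endian = "little")
      cols <- (r - 1L) * spr[i] + seq_len(spr[i])
      data[i, cols] <- phys_min[i] + gain[i] * (raw - dig_min[i])
    }
  }
  list(data = data, channels = labels, sampling_rate = spr[1] / record_dur)
}

# Minimal EDF writer (integer rescaling, single data record per call unit);
# used by the tests to exercise read_edf round trips.
write_edf <- function(data, sampling_rate, path) {
  ns <- nrow(data)
  n_samp <- ncol(data)
  dig_min <- -32768; dig_max <- 32767
  # quantize the physical range to the 2 decimals the ASCII header holds,
  # so writer and reader use identical scaling
  phys_min <- floor(apply(data, 1, min) * 100) / 100
  phys_max <- ceiling(apply(data, 1, max) * 100) / 100
  phys_max <- ifelse(phys_max == phys_min, phys_min + 1, phys_max)
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(s, n) {
    s <- substr(as.character(s), 1, n)
    writeChar(formatC(s, width = -n), con, eos = NULL)
  }
  pad("0", 8); pad("synthetic", 80); pad("synthetic", 80)
  pad("01.01.26", 8); pad("00.00.00", 8)
  pad(256 + ns * 256, 8); pad("", 44)
  pad(1, 8); pad(1, 8)                      # 1 record of 1 s scaled below
  pad(ns, 4)
  for (i in seq_len(ns)) pad(rownames(data)[i], 16)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad("uV", 8)
  for (i in seq_len(ns)) pad(sprintf("%.2f", phys_min[i]), 8)
  for (i in seq_len(ns)) pad(sprintf("%.2f", phys_max[i]), 8)
  for (i in seq_len(ns)) pad(dig_min, 8)
  for (i in seq_len(ns)) pad(dig_max, 8)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad(n_samp, 8)     # record duration set to n/fs
  for (i in seq_len(ns)) pad("", 32)
  # fix record duration: rewrite at offset 236+8
  seek(con, 236 + 8)
  pad(sprintf("%g", n_samp / sampling_rate), 8)
  seek(con, 256 + ns * 256)
  for (i in seq_len(ns)) {
    gain <- (phys_max[i] - phys_min[i]) / (dig_max - dig_min)
    dig <- round((data[i, ] - phys_min[i]) / gain + dig_min)
    writeBin(as.integer(dig), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Serialize a trained model to JSON
#'
#' Flat JSON document holding the CSP filters, discriminant (means, Gamma,
#' projection), threshold, pipeline settings and a config hash;
#' [read_mi_model()] restores a working `mi_model`.
#'
#' @param model An `mi_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mi_model <- function(model, path) {
  doc <- list(
    channels = model$channels, n_pairs = model$n_pairs,
    denoise = model$denoise,
    positive_class = model$positive_class,
    negative_class = model$negative_class,
    sampling_rate = model$sampling_rate,
    selection = unclass(model$selection),
    emd_cfg = unclass(model$emd_cfg),
    csp = list(filters = model$csp$filters,
               eigenvalues = model$csp$eigenvalues,
               n_pairs = model$csp$n_pairs),
    discriminant = list(class_means = model$discriminant$class_means,
                        projection = model$discriminant$projection,
                        gamma = model$discriminant$gamma,
                        n_classes = model$discriminant$n_classes,
                        class_counts = model$discriminant$class_counts,
                        classes = model$discriminant$classes,
                        pooled = model$discriminant$pooled),
    threshold = unclass(model$threshold),
    report = model$report
  )
  doc$config_hash <- config_hash(doc[c("selection", "emd_cfg", "channels",
                                       "n_pairs", "denoise")])
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Restore a model written by [write_mi_model()]
#'
#' @param path JSON file.
#' @return An `mi_model` usable with [mi_predict()].
#' @export
read_mi_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  sel <- doc$selection
  sel$nodes <- if (is.matrix(sel$nodes)) {
    lapply(seq_len(nrow(sel$nodes)), function(i) as.integer(sel$nodes[i, ]))
  } else lapply(sel$nodes, as.integer)
  selection <- subband_selection(sel$wpt_level, sel$nodes, sel$imfs_kept,
                                 sel$wavelet_name, sel$node_order)
  ec <- doc$emd_cfg
  emd_cfg <- emd_config(ec$sd_threshold, ec$max_sift_iterations,
                        if (is.null(ec$max_imfs) || is.character(ec$max_imfs))
                          Inf else ec$max_imfs,
                        ec$boundary_mode)
  disc <- doc$discriminant
  disc$class_means <- lapply(disc$class_means, as.numeric)
  disc$projection <- as.matrix(disc$projection)
  disc$gamma <- if (disc$pooled) as.matrix(disc$gamma) else
    lapply(disc$gamma, as.matrix)
  structure(list(selection = selection, channels = doc$channels,
                 n_pairs = doc$n_pairs, emd_cfg = emd_cfg,
                 denoise = doc$denoise,
                 positive_class = doc$positive_class,
                 negative_class = doc$negative_class,
                 sampling_rate = doc$sampling_rate,
                 csp = structure(list(filters = as.matrix(doc$csp$filters),
                                      eigenvalues = doc$csp$eigenvalues,
                                      n_pairs = doc$csp$n_pairs),
                                 class = "csp_model"),
                 discriminant = structure(disc, class = "discriminant_model"),
                 threshold = structure(doc$threshold,
                                       class = "decision_threshold"),
                 report = doc$report),
            class = "mi_model")
}

#' Read a sectioned key=value configuration file
#'
#' INI-style: `[section]` headers, `key = value` lines, `#` comments.
#' Values are parsed as numbers when possible, `true`/`false` as logicals,
#' comma-separated values as vectors.
#'
#' @param path Config file.
#' @return Nested named list `config[[section]][[key]]`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("config file not found: %s", path),
                        class = c("eemdbci_io_error", "error", "condition")))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  section <- "global"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) {
      stop(errorCondition(sprintf("malformed config line: '%s'", ln),
                          class = c("eemdbci_io_error", "error", "condition")))
    }
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    parsed <- suppressWarnings(as.numeric(parts))
    out <- if (!anyNA(parsed)) parsed
           else if (all(tolower(parts) %in% c("true", "false")))
             tolower(parts) == "true"
           else parts
    cfg[[section]][[key]] <- out
  }
  cfg
}
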