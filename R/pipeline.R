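#' Train the full motor-imagery decoding model
#'
#' Runs the complete chain on a labeled trial set: per-channel wavelet
#' denoising, wavelet-packet sub-band extraction, EMD of each sub-band with
#' correlation-based IMF retention, CSP spatial filtering with log-variance
#' features, the regularized quadratic discriminant, and threshold
#' selection capping the relaxed-state false-positive rate.
#'
#' @param trials A [trial_set()] with exactly the two classes named by
#'   `positive_class` / `negative_class`.
#' @param selection A [subband_selection()].
#' @param channels Channels used for decoding.
#' @param n_pairs CSP filter pairs.
#' @param fpr_max False-positive-rate cap for [select_threshold()].
#' @param emd_cfg [emd_config()] for the sub-band decompositions.
#' @param denoise Wavelet-denoise each channel before sub-banding.
#' @param positive_class,negative_class Class labels (imagery is positive:
#'   scores at or above the threshold are called `positive_class`).
#' @param threshold_scores Which relaxed-state decision values the
#'   threshold quantile is taken from: `"cv"` (default) uses out-of-fold
#'   scores from a stratified cross-validation over the training trials,
#'   which removes the in-sample optimism of the spatial filters and
#'   discriminant and so keeps the false-positive cap honest on unseen
#'   trials; `"training"` uses the final model's in-sample scores.
#' @param cv_folds Folds for `threshold_scores = "cv"`.
#' @return An `mi_model`: `csp`, `discriminant`, `threshold`, `features`
#'   (training feature matrix with labels), `scores`, `densities` (per
#'   class), and `report` (training accuracy, achieved FPR, overlap area).
#' @export
mi_train <- function(trials, selection = subband_selection(),
                     channels = c("C3", "C4"), n_pairs = 2L,
                     fpr_max = 0.10, emd_cfg = emd_config(max_imfs = 8L),
                     denoise = TRUE, positive_class = "imagery",
                     negative_class = "relaxed",
                     threshold_scores = c("cv", "training"), cv_folds = 5L) {
  threshold_scores <- match.arg(threshold_scores)
  got <- sort(unique(trials$labels))
  want <- sort(c(positive_class, negative_class))
  if (!identical(got, want)) {
    stop(errorCondition(
      sprintf("trial labels {%s} do not match the expected classes {%s}",
              paste(got, collapse = ", "), paste(want, collapse = ", ")),
      class = c("eemdbci_config_error", "error", "condition")))
  }
  mats <- lapply(seq_along(trials$trials), function(i) {
    trial_subband_matrix(trials$trials[[i]], channels, selection, emd_cfg,
                         denoise, trials$labels[i])
  })
  is_pos <- trials$labels == positive_class
  covs <- class_covariances(mats[!is_pos], mats[is_pos])
  csp <- csp_fit(covs$sigma_L, covs$sigma_R, n_pairs)
  feats <- t(vapply(mats, function(m) csp_features(csp, m),
                    numeric(2L * n_pairs)))
  disc <- fit_discriminant(feats, trials$labels)
  scores <- decision_value(disc, feats, positive_class = positive_class)$score
  thr_scores <- if (threshold_scores == "cv") {
    oof <- cv_decision_scores(mats, trials$labels, n_pairs, positive_class,
                              cv_folds)
    oof[!is_pos]
  } else scores[!is_pos]
  thr <- select_threshold(thr_scores, fpr_max)
  dens <- list()
  dens[[negative_class]] <- decision_density(scores[!is_pos])
  dens[[positive_class]] <- decision_density(scores[is_pos])
  pred <- classify(disc, thr, score = scores,
                   positive_class = positive_class,
                   negative_class = negative_class)
  report <- list(
    n_trials = length(trials$trials),
    training_accuracy = mean(pred == trials$labels),
    achieved_fpr = mean(scores[!is_pos] >= thr$value),
    threshold = thr$value,
    overlap_area = overlap_area(dens[[negative_class]], dens[[positive_class]])
  )
  structure(list(selection = selection, channels = channels,
                 n_pairs = as.integer(n_pairs), emd_cfg = emd_cfg,
                 denoise = denoise,
                 positive_class = positive_class,
                 negative_class = negative_class,
                 sampling_rate = trials$sampling_rate,
                 csp = csp, discriminant = disc, threshold = thr,
                 features = feats, labels = trials$labels,
                 scores = scores, densities = dens, report = report),
            class = "mi_model")
}

# Out-of-fold decision scores: refit CSP + discriminant on each training
# split and score the held fold. Deterministic stratified fold assignment
# (round-robin within class, in trial order).
cv_decision_scores <- function(mats, labels, n_pairs, positive_class, folds) {
  n <- length(mats)
  fold_id <- integer(n)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  scores <- numeric(n)
  for (f in seq_len(folds)) {
    in_tr <- fold_id != f
    is_pos <- labels == positive_class
    covs <- class_covariances(mats[in_tr & !is_pos], mats[in_tr & is_pos])
    csp <- csp_fit(covs$sigma_L, covs$sigma_R, n_pairs)
    tr_feats <- t(vapply(mats[in_tr], function(m) csp_features(csp, m),
                         numeric(2L * n_pairs)))
    disc <- fit_discriminant(tr_feats, labels[in_tr])
    te_feats <- t(vapply(mats[!in_tr], function(m) csp_features(csp, m),
                         numeric(2L * n_pairs)))
    scores[!in_tr] <- decision_value(disc, te_feats,
                                     positive_class = positive_class)$score
  }
  scores
}

#' @export
print.mi_model <- function(x, ...) {
  cat(sprintf(paste0("<mi_model: %d CSP filters on %s; threshold %.4g ",
                     "(FPR cap %.0f%%)>\n"),
              2L * x$n_pairs, paste(x$channels, collapse = "/"),
              x$threshold$value, 100 * x$threshold$fpr_max))
  cat(sprintf("  training accuracy %.1f%%, achieved FPR %.1f%%, overlap %.3f\n",
              100 * x$report$training_accuracy,
              100 * x$report$achieved_fpr, x$report$overlap_area))
  invisible(x)
}

#' Apply a trained motor-imagery model to new trials
#'
#' @param model An `mi_model` from [mi_train()].
#' @param trials A [trial_set()] (labels, if present, are ignored).
#' @return Data frame with `trial`, `score` and `decision` columns.
#' @export
mi_predict <- function(model, trials) {
  mats <- lapply(trials$trials, function(tr) {
    trial_subband_matrix(tr, model$channels, model$selection, model$emd_cfg,
                         model$denoise)
  })
  feats <- t(vapply(mats, function(m) csp_features(model$csp, m),
                    numeric(2L * model$n_pairs)))
  scores <- decision_value(model$discriminant, feats,
                           positive_class = model$positive_class)$score
  data.frame(trial = seq_along(trials$trials), score = scores,
             decision = classify(model$discriminant, model$threshold,
                                 score = scores,
                                 positive_class = model$positive_class,
                                 negative_class = model$negative_class),
             stringsAsFactors = FALSE)
}
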