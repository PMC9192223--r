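#' Average normalized class covariances
#'
#' Per trial, the spatial covariance `C = X X' / trace(X X')`; the class
#' covariance is the average over trials. Trace normalization removes
#' per-trial amplitude scale so no single strong trial dominates.
#'
#' @param matrices_L,matrices_R Lists of row-by-sample matrices (or of
#'   `reconstructed_matrix` objects), one list per class.
#' @return List with symmetric PSD matrices `sigma_L` and `sigma_R`.
#' @export
class_covariances <- function(matrices_L, matrices_R) {
  avg_cov <- function(ms, side) {
    ms <- lapply(ms, function(m) if (inherits(m, "reconstructed_matrix")) m$data else m)
    used <- 0L
    acc <- NULL
    for (m in ms) {
      cc <- tcrossprod(m)
      tr <- sum(diag(cc))
      if (tr == 0) {
        warning(sprintf("excluding an all-zero trial from class %s", side))
        next
      }
      cc <- cc / tr
      acc <- if (is.null(acc)) cc else acc + cc
      used <- used + 1L
    }
    if (used == 0L) {
      stop(errorCondition(sprintf("no usable trials in class %s", side),
                          class = c("eemdbci_degenerate_input", "error", "condition")))
    }
    acc / used
  }
  sl <- avg_cov(matrices_L, "L")
  sr <- avg_cov(matrices_R, "R")
  if (!identical(dim(sl), dim(sr))) {
    stop(errorCondition("classes have different row dimensions",
                        class = c("eemdbci_config_error", "error", "condition")))
  }
  list(sigma_L = sl, sigma_R = sr)
}

#' Fit common spatial pattern filters
#'
#' Solves the generalized eigenproblem `Sigma_L w = lambda (Sigma_L +
#' Sigma_R) w` after ridge regularization of the composite covariance, and
#' keeps the `n_pairs` most class-L-discriminative filters (largest
#' `lambda`) followed by the `n_pairs` most class-R-discriminative
#' (smallest `lambda`). Retained filters satisfy
#' `W (Sigma_L + Sigma_R) W' = I`.
#'
#' @param sigma_L,sigma_R Class covariance matrices from
#'   [class_covariances()].
#' @param n_pairs Filter pairs to retain.
#' @param ridge Ridge added to the composite covariance, as a fraction of
#'   `trace/d`.
#' @param sw Optional weighted pairwise scatter matrix (see
#'   [weighted_pairwise_scatter()]) blended into both class covariances as
#'   `(1 - alpha) Sigma + alpha sw / n_sw` for extra regularization.
#' @param alpha Blend weight for `sw` (default 0 = off).
#' @param n_sw Normalizer for `sw` (number of points it was built from).
#' @return A `csp_model` with `filters` (2*n_pairs x d, rows are filters),
#'   `eigenvalues` (per retained filter, in `[0,1]`) and `n_pairs`.
#' @export
csp_fit <- function(sigma_L, sigma_R, n_pairs = 2L, ridge = 1e-6,
                    sw = NULL, alpha = 0, n_sw = NULL) {
  d <- nrow(sigma_L)
  if (!is.null(sw) && alpha > 0) {
    if (is.null(n_sw)) n_sw <- d
    blend <- if (inherits(sw, "scatter_matrix")) sw$matrix else sw
    sigma_L <- (1 - alpha) * sigma_L + alpha * blend / n_sw
    sigma_R <- (1 - alpha) * sigma_R + alpha * blend / n_sw
  }
  if (2L * n_pairs > d) {
    stop(errorCondition("2 * n_pairs exceeds the matrix dimension",
                        class = c("eemdbci_config_error", "error", "condition")))
  }
  comp <- sigma_L + sigma_R
  comp <- comp + diag(ridge * sum(diag(comp)) / d, d)
  ec <- eigen((comp + t(comp)) / 2, symmetric = TRUE)
  if (min(ec$values) <= .Machine$double.eps * max(ec$values)) {
    stop(errorCondition("composite covariance is singular after regularization",
                        class = c("eemdbci_numerical_error", "error", "condition")))
  }
  whiten <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)
  s <- whiten %*% sigma_L %*% t(whiten)
  es <- eigen((s + t(s)) / 2, symmetric = TRUE)   # values descending
  keep <- c(seq_len(n_pairs), d - seq_len(n_pairs) + 1L)
  w <- t(es$vectors[, keep, drop = FALSE]) %*% whiten
  structure(list(filters = w, eigenvalues = es$values[keep],
                 n_pairs = as.integer(n_pairs)),
            class = "csp_model")
}

#' Log-variance CSP features for one trial
#'
#' `f_i = log( var(w_i X) / sum_j var(w_j X) )`: the normalized
#' log-variance of each spatially filtered trial, invariant to overall
#' trial scale.
#'
#' @param model A `csp_model` from [csp_fit()].
#' @param trial Row-by-sample matrix (or `reconstructed_matrix`) with the
#'   same row dimension the model was fitted on.
#' @return Numeric feature vector of length `2 * n_pairs`.
#' @export
csp_features <- function(model, trial) {
  if (inherits(trial, "reconstructed_matrix")) trial <- trial$data
  if (ncol(model$filters) != nrow(trial)) {
    stop(errorCondition("trial row count does not match the CSP model",
                        class = c("eemdbci_config_error", "error", "condition")))
  }
  proj <- model$filters %*% trial
  v <- apply(proj, 1L, stats::var)
  if (any(v == 0)) {
    warning("zero-variance CSP projection; flooring at machine epsilon")
    v[v == 0] <- .Machine$double.eps
  }
  log(v / sum(v))
}

#' Weighted pairwise scatter matrix
#'
#' \deqn{S_w = \tfrac12 \sum_i \sum_j W_{i,j} (x_i - x_j)(x_i - x_j)^T,}
#' computed via the graph-Laplacian identity
#' `S_w = X' (diag(rowSums(W)) - W) X` for symmetric weights.
#'
#' @param points n-by-d matrix of points (rows).
#' @param weights n-by-n symmetric nonnegative weight matrix.
#' @return A `scatter_matrix` with fields `matrix` (d x d, symmetric, PSD
#'   for nonnegative weights) and `weights_spec`.
#' @export
weighted_pairwise_scatter <- function(points, weights) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (!identical(dim(weights), c(n, n))) {
    stop(errorCondition("weights must be n x n for n points",
                        class = c("eemdbci_config_error", "error", "condition")))
  }
  lap <- diag(rowSums(weights), n) - (weights + t(weights)) / 2
  m <- t(points) %*% lap %*% points
  structure(list(matrix = (m + t(m)) / 2,
                 weights_spec = sprintf("%d x %d symmetric weights", n, n)),
            class = "scatter_matrix")
}

#' Per-IMF energy profile
#'
#' `E_j = sum_t c_j(t)^2` for each IMF of a decomposition; used to contrast
#' high- and low-arousal training states, whose signals differ mainly in
#' oscillation amplitude (energy scales with the square of the gain).
#'
#' @param decomp An `emd_decomposition` or `eemd_decomposition`.
#' @param normalize If `TRUE`, return fractions summing to 1 (all-zero
#'   profiles stay 0).
#' @return Numeric vector of IMF energies.
#' @export
imf_energy_profile <- function(decomp, normalize = FALSE) {
  imfs <- if (inherits(decomp, "eemd_decomposition")) decomp$mean_imfs else decomp$imfs
  if (!length(imfs)) {
    stop(errorCondition("decomposition has no IMFs",
                        class = c("eemdbci_degenerate_input", "error", "condition")))
  }
  e <- vapply(imfs, function(c_j) sum(c_j^2), 0)
  if (normalize && sum(e) > 0) e <- e / sum(e)
  e
}
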