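#' Fit the regularized quadratic discriminant
#'
#' Per-class means plus a projected, pooled covariance
#' \deqn{\Gamma = T_r' \Big[\sum_k \sum_{x \in C_k} (x - \bar x_k)(x - \bar x_k)'\Big] T_r
#'   \ /\ \sum_k (n_k - 1),}
#' where `T_r` holds the top-`r` principal directions of the pooled scatter
#' (the identity when `r = d`, the default). Decision values are computed
#' by [decision_value()]. A `per_class` mode keeps one Gamma per class
#' instead of pooling.
#'
#' @param features n-by-d numeric matrix (rows = samples).
#' @param labels Length-n class labels (two or more classes, >= 2 samples
#'   each).
#' @param projection_rank `r`, number of principal directions to project
#'   onto; `NULL` (default) keeps the full space with an identity
#'   projection.
#' @param pooled Pool the per-class projected scatters (default) or keep a
#'   per-class Gamma.
#' @param ridge Relative ridge added to Gamma if it is singular.
#' @return A `discriminant_model`: `class_means` (named list),
#'   `projection` (d x r), `gamma` (r x r, or named list in per-class
#'   mode), `n_classes`, `class_counts`, `classes`.
#' @export
fit_discriminant <- function(features, labels, projection_rank = NULL,
                             pooled = TRUE, ridge = 1e-8) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (nrow(features) != length(labels)) {
    stop(errorCondition("labels length must match the feature row count",
                        class = c("eemdbci_config_error", "error", "condition")))
  }
  classes <- sort(unique(labels))
  k_n <- table(labels)[classes]
  if (length(classes) < 2L) {
    stop(errorCondition("need at least 2 classes",
                        class = c("eemdbci_config_error", "error", "condition")))
  }
  if (any(k_n < 2L)) {
    stop(errorCondition("every class needs at least 2 samples",
                        class = c("eemdbci_config_error", "error", "condition")))
  }
  d <- ncol(features)
  means <- lapply(classes, function(cl) colMeans(features[labels == cl, , drop = FALSE]))
  names(means) <- classes
  scatters <- lapply(classes, function(cl) {
    xc <- sweep(features[labels == cl, , drop = FALSE], 2L, means[[cl]])
    crossprod(xc)
  })
  names(scatters) <- classes
  pooled_scatter <- Reduce(`+`, scatters)
  r <- if (is.null(projection_rank)) d else as.integer(projection_rank)
  if (r < 1L || r > d) {
    stop(errorCondition("projection_rank must lie in [1, d]",
                        class = c("eemdbci_config_error", "error", "condition")))
  }
  proj <- if (r == d) diag(d) else
    eigen((pooled_scatter + t(pooled_scatter)) / 2,
          symmetric = TRUE)$vectors[, seq_len(r), drop = FALSE]
  regularize <- function(g) {
    if (rcond_sym(g) < 1e-12) {
      warning("singular Gamma; adding ridge")
      g <- g + diag(ridge * max(sum(diag(g)) / nrow(g), 1), nrow(g))
    }
    g
  }
  if (pooled) {
    gamma <- t(proj) %*% pooled_scatter %*% proj / sum(k_n - 1L)
    gamma <- regularize((gamma + t(gamma)) / 2)
  } else {
    gamma <- lapply(classes, function(cl) {
      g <- t(proj) %*% scatters[[cl]] %*% proj / (k_n[[cl]] - 1L)
      regularize((g + t(g)) / 2)
    })
    names(gamma) <- classes
  }
  structure(list(class_means = means, projection = proj, gamma = gamma,
                 n_classes = length(classes),
                 class_counts = as.integer(k_n), classes = classes,
                 pooled = pooled),
            class = "discriminant_model")
}

# reciprocal condition number of a symmetric matrix via its spectrum
rcond_sym <- function(m) {
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(ev)) == 0) return(0)
  min(ev) / max(abs(ev))
}

#' Discriminant decision values
#'
#' For each class `k`,
#' \deqn{g_k(x) = -\tfrac12 (x - \bar x_k)' T_r \Gamma^{-1} T_r' (x - \bar x_k)
#'   + \ln K - \tfrac12 \ln \det \Gamma,}
#' and, for the two-class case, the scalar decision score
#' `g_positive(x) - g_negative(x)` (imagery positive by default): large
#' scores mean imagery-like, small scores relaxed-like.
#'
#' @param model A `discriminant_model`.
#' @param x A length-d vector or an n-by-d matrix of feature rows.
#' @param positive_class Class treated as positive for the score; defaults
#'   to `"imagery"` when present, else the second class alphabetically.
#' @return List with `g` (n-by-K matrix of decision values, columns named
#'   by class) and `score` (length-n vector; `NULL` unless exactly 2
#'   classes).
#' @export
decision_value <- function(model, x, positive_class = NULL) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  K <- model$n_classes
  d <- nrow(model$projection)
  if (ncol(x) != d) {
    stop(errorCondition("x dimension does not match the model",
                        class = c("eemdbci_config_error", "error", "condition")))
  }
  gamma_for <- function(cl) if (model$pooled) model$gamma else model$gamma[[cl]]
  g <- matrix(NA_real_, nrow(x), K, dimnames = list(NULL, model$classes))
  for (cl in model$classes) {
    gam <- gamma_for(cl)
    gi <- solve(gam)
    ldet <- determinant(gam, logarithm = TRUE)$modulus[1]
    xc <- sweep(x, 2L, model$class_means[[cl]])
    z <- xc %*% model$projection
    maha <- rowSums((z %*% gi) * z)
    g[, cl] <- -0.5 * maha + log(K) - 0.5 * ldet
  }
  score <- NULL
  if (K == 2L) {
    if (is.null(positive_class)) {
      positive_class <- if ("imagery" %in% model$classes) "imagery" else model$classes[2L]
    }
    neg <- setdiff(model$classes, positive_class)
    score <- g[, positive_class] - g[, neg]
  }
  list(g = g, score = score)
}

#' Kernel density estimate of decision values
#'
#' Gaussian KDE on a grid spanning `[min - 3h, max + 3h]`, bandwidth by
#' Silverman's rule unless overridden. Used for the relaxed-vs-imagery
#' decision-value density curves whose overlap summarizes separability.
#'
#' @param values Numeric vector, length >= 5.
#' @param bandwidth Optional fixed bandwidth.
#' @return A `density_curve` with `grid`, `density` and `bandwidth`.
#' @export
decision_density <- function(values, bandwidth = NULL) {
  if (length(values) < 5L) {
    stop(errorCondition("need at least 5 values for a density curve",
                        class = c("eemdbci_degenerate_input", "error", "condition")))
  }
  if (is.null(bandwidth)) {
    if (stats::sd(values) == 0) {
      warning("zero-variance scores; returning a narrow spike density")
      bandwidth <- max(abs(values[1]), 1) * 1e-3
    } else {
      bandwidth <- stats::bw.nrd0(values)
    }
  }
  de <- stats::density(values, bw = bandwidth, kernel = "gaussian",
                       n = 512L, cut = 3)
  structure(list(grid = de$x, density = de$y, bandwidth = bandwidth),
            class = "density_curve")
}

#' Overlap area of two density curves
#'
#' Trapezoid-rule integral of `min(f_a, f_b)` on a merged grid (each curve
#' is linearly interpolated and taken as 0 outside its own grid): 0 for
#' disjoint densities, 1 for identical ones. Smaller overlap means the two
#' decision-value distributions — relaxed vs. imagery — are easier to
#' separate by a threshold.
#'
#' @param curve_a,curve_b `density_curve` objects.
#' @return Scalar in `[0, 1]`.
#' @export
overlap_area <- function(curve_a, curve_b) {
  grid <- sort(unique(c(curve_a$grid, curve_b$grid)))
  fa <- stats::approx(curve_a$grid, curve_a$density, xout = grid,
                      yleft = 0, yright = 0)$y
  fb <- stats::approx(curve_b$grid, curve_b$density, xout = grid,
                      yleft = 0, yright = 0)$y
  lo <- pmin(fa, fb)
  sum(diff(grid) * (lo[-1] + lo[-length(lo)]) / 2)
}

#' Select the decision threshold under a false-positive-rate cap
#'
#' Chooses the smallest threshold such that the fraction of relaxed-state
#' scores at or above it does not exceed `fpr_max` (scores >= threshold
#' are classified as imagery). This is the empirical-quantile plug-in of
#' the density-area rule: the relaxed density mass above the threshold is
#' capped at `fpr_max`. Ties at the threshold count as positive.
#'
#' @param relaxed_scores Decision scores of relaxed-state trials (>= 10).
#' @param fpr_max Maximum tolerated false-positive rate in (0, 1);
#'   default 0.10.
#' @return A `decision_threshold` with `value`, `fpr_max`, `achieved_fpr`
#'   and `side = "above_is_positive"`.
#' @export
select_threshold <- function(relaxed_scores, fpr_max = 0.10) {
  if (!is.numeric(fpr_max) || length(fpr_max) != 1L ||
      fpr_max <= 0 || fpr_max >= 1) {
    stop(errorCondition("fpr_max must lie in (0, 1)",
                        class = c("eemdbci_config_error", "error", "condition")))
  }
  n <- length(relaxed_scores)
  if (n < 10L) {
    stop(errorCondition("need at least 10 relaxed-state scores",
                        class = c("eemdbci_degenerate_input", "error", "condition")))
  }
  s <- sort(relaxed_scores, decreasing = TRUE)
  k_max <- floor(fpr_max * n)
  value <- NULL
  # the largest admissible count of scores above the threshold at which a
  # strict gap exists (ties must fall on the same side)
  for (k in rev(seq_len(k_max))) {
    if (s[k] > s[k + 1L]) {
      value <- (s[k] + s[k + 1L]) / 2
      achieved <- k / n
      break
    }
  }
  if (is.null(value)) {
    value <- s[1L] + max(abs(s[1L]), 1) * 1e-9   # just above the maximum
    achieved <- 0
  }
  structure(list(value = value, fpr_max = fpr_max, achieved_fpr = achieved,
                 side = "above_is_positive"),
            class = "decision_threshold")
}

#' Threshold a decision score into a class label
#'
#' @param model A `discriminant_model` (two classes).
#' @param threshold A `decision_threshold`.
#' @param x Feature vector or matrix of rows; alternatively pass
#'   precomputed scores via `score`.
#' @param score Optional precomputed decision scores (skips `x`).
#' @param positive_class,negative_class Labels to emit; default
#'   `"imagery"` / `"relaxed"`.
#' @return Character vector of labels.
#' @export
classify <- function(model, threshold, x = NULL, score = NULL,
                     positive_class = "imagery", negative_class = "relaxed") {
  if (is.null(score)) {
    score <- decision_value(model, x, positive_class = positive_class)$score
  }
  pos <- if (threshold$side == "above_is_positive")
    score >= threshold$value else score <= threshold$value
  ifelse(pos, positive_class, negative_class)
}
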