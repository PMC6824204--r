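# Sensory-motor internal models: deterministic forward maps from motor
# commands to predicted sensory consequences, fitted by Gaussian RBF
# ridge regression on plant samples, with an additive adaptation offset
# for the auditory modality.

rbf_features <- function(x, centers, bandwidth) {
  x <- as.matrix(x)
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
  d2[d2 < 0] <- 0
  cbind(1, x, exp(-d2 / (2 * bandwidth^2)))
}

#' Fit a sensory-motor forward map
#'
#' Gaussian radial-basis-function regression (with an affine tail) from
#' control vectors to a 3-D sensory space, solved exactly by
#' ridge-regularized least squares. Centers are a k-means subset of the
#' training inputs; the bandwidth defaults to the median inter-center
#' distance. A held-out split reports the map's fidelity, which bounds
#' the accuracy attainable by any planning built on the map.
#'
#' @param x n x d matrix of control vectors (n >= 200).
#' @param y n x 3 matrix of sensory outputs (Hz or PC units).
#' @param modality `"auditory"` or `"somatosensory"`.
#' @param n_centers Number of RBF centers (k-means, seeded).
#' @param bandwidth Kernel width; `NULL` for the median-distance default.
#' @param ridge Ridge penalty on the normal equations.
#' @param holdout Fraction of rows held out for the fidelity estimate.
#' @param seed Integer seed controlling the split and k-means.
#' @return An object of class `sensory_map` with fields `centers`,
#'   `bandwidth`, `weights`, `adaptation_offset`, `rmse` (held-out, per
#'   output dimension) and `rmse_rel` (relative to each output's SD).
#' @export
fit_sensory_map <- function(x, y, modality = c("auditory", "somatosensory"),
                            n_centers = 500L, bandwidth = NULL,
                            ridge = 1e-8, holdout = 0.2, seed = 1L) {
  modality <- match.arg(modality)
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) < 200L) stop("need at least 200 training pairs")
  stopifnot(nrow(x) == nrow(y), ncol(y) == 3L)
  if (!is.null(bandwidth) && bandwidth <= 0) stop("bandwidth must be positive")

  set.seed(seed)
  n <- nrow(x)
  n_test <- max(1L, round(holdout * n))
  test_idx <- sample.int(n, n_test)
  xtr <- x[-test_idx, , drop = FALSE]; ytr <- y[-test_idx, , drop = FALSE]
  xte <- x[test_idx, , drop = FALSE];  yte <- y[test_idx, , drop = FALSE]

  k <- min(as.integer(n_centers), nrow(unique(xtr)) - 1L)
  km <- stats::kmeans(xtr, centers = k, iter.max = 100L, nstart = 1L)
  centers <- km$centers
  if (is.null(bandwidth)) {
    idx <- if (nrow(centers) > 400L) sample.int(nrow(centers), 400L) else seq_len(nrow(centers))
    bandwidth <- 0.65 * stats::median(stats::dist(centers[idx, , drop = FALSE]))
  }

  phi <- rbf_features(xtr, centers, bandwidth)
  G <- crossprod(phi)
  b <- crossprod(phi, ytr)
  lam <- ridge
  weights <- NULL
  while (is.null(weights) && lam < 1) {
    weights <- tryCatch(solve(G + lam * diag(ncol(phi)), b),
                        error = function(e) NULL)
    if (is.null(weights)) lam <- lam * 100
  }
  if (is.null(weights)) stop("singular RBF design despite regularization")

  pred_te <- rbf_features(xte, centers, bandwidth) %*% weights
  rmse <- sqrt(colMeans((pred_te - yte)^2))
  structure(list(
    modality = modality,
    centers = centers,
    bandwidth = bandwidth,
    weights = weights,
    adaptation_offset = c(0, 0, 0),
    rmse = rmse,
    rmse_rel = rmse / apply(y, 2, stats::sd),
    d = ncol(x)
  ), class = "sensory_map")
}

#' Predict sensory consequences of motor commands
#'
#' Deterministic forward prediction: RBF output plus the adaptation
#' offset (non-zero only after auditory adaptation).
#'
#' @param object A `sensory_map`.
#' @param newdata Control vector (length d) or n x d matrix.
#' @param ... Unused.
#' @return n x 3 matrix of predicted sensory values.
#' @export
predict.sensory_map <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  out <- rbf_features(newdata, object$centers, object$bandwidth) %*% object$weights
  sweep(out, 2, object$adaptation_offset, "+")
}

#' Adaptation of the auditory internal model
#'
#' After full adaptation to a constant formant-shifting perturbation
#' `delta`, the auditory forward map predicts the shifted consequence of
#' every motor command: the update is an exact additive offset, so the
#' adapted prediction equals the original prediction plus `delta` at
#' every control vector. Offsets compose additively, so adapting with
#' `delta` and then `-delta` restores the original map.
#'
#' @param map An auditory `sensory_map`.
#' @param delta Length-3 perturbation in Hz (reference experiment:
#'   `c(-100, 0, 0)`, a downward F1 shift).
#' @return The adapted `sensory_map`.
#' @export
adapt_auditory <- function(map, delta) {
  stopifnot(inherits(map, "sensory_map"))
  if (!identical(map$modality, "auditory")) {
    stop("adaptation applies to the auditory map only")
  }
  stopifnot(length(delta) == 3L, all(is.finite(delta)))
  map$adaptation_offset <- map$adaptation_offset + as.numeric(delta)
  map
}

#' @export
print.sensory_map <- function(x, ...) {
  cat(sprintf("<sensory_map> %s: %d centers, bandwidth %.3f\n",
              x$modality, nrow(x$centers), x$bandwidth))
  cat(sprintf("  held-out RMSE: %s (rel: %s)\n",
              paste(signif(x$rmse, 3), collapse = ", "),
              paste(signif(x$rmse_rel, 3), collapse = ", ")))
  if (any(x$adaptation_offset != 0)) {
    cat("  adaptation offset:", paste(x$adaptation_offset, collapse = ", "), "\n")
  }
  invisible(x)
}
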