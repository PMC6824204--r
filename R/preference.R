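# Sensory preference: target-based covariance scaling (kappa) and
# comparison-based soft matching (eta), plus the algebra connecting the
# two mechanisms.

#' Sensory preference parameters
#'
#' In the target-based mechanism, preference multiplies the covariance
#' of a modality's goal region by `kappa` (> 1 loosens, i.e. lowers the
#' precision of, that modality). In the comparison-based mechanism, the
#' exact sensory matching constraint is softened to a Gaussian kernel of
#' width `eta`; through the Gaussian convolution identity this adds
#' `eta^2 I` to the goal covariance. `eta` is expressed in the raw units
#' of its sensory space (Hz for auditory, PC units for somatosensory).
#'
#' @param mode `"none"`, `"target_based"` or `"comparison_based"`.
#' @param kappa_a,kappa_s Positive covariance scale factors.
#' @param eta_a,eta_s Non-negative soft-match widths.
#' @return An object of class `preference_params`.
#' @export
preference_params <- function(mode = c("none", "target_based", "comparison_based"),
                              kappa_a = 1, kappa_s = 1, eta_a = 0, eta_s = 0) {
  mode <- match.arg(mode)
  stopifnot(kappa_a > 0, kappa_s > 0, eta_a >= 0, eta_s >= 0)
  if (mode == "none") {
    kappa_a <- kappa_s <- 1
    eta_a <- eta_s <- 0
  }
  structure(list(mode = mode, kappa_a = kappa_a, kappa_s = kappa_s,
                 eta_a = eta_a, eta_s = eta_s),
            class = "preference_params")
}

#' Soft sensory matching probability
#'
#' Gaussian-kernel relaxation of the exact matching constraint between a
#' predicted sensory value and a sensory goal value:
#' `exp(-||x1 - x2||^2 / (2 eta^2))`. As `eta -> 0` the strict
#' all-or-nothing constraint is recovered; as `eta -> Inf` the
#' constraint vanishes (probability 1 everywhere).
#'
#' @param x1,x2 Sensory vectors of equal length.
#' @param eta Positive match width (use [strict_match()] for `eta = 0`).
#' @return A probability in (0, 1].
#' @export
soft_match_prob <- function(x1, x2, eta) {
  stopifnot(length(x1) == length(x2), eta > 0)
  exp(-sum((x1 - x2)^2) / (2 * eta^2))
}

#' Strict sensory matching constraint
#'
#' The all-or-nothing probabilistic switch: 1 iff the two sensory values
#' are exactly equal. Retained as the `eta -> 0` limit of
#' [soft_match_prob()]; the planner never uses it inside densities.
#'
#' @param x1,x2 Sensory vectors of equal length.
#' @return 0 or 1.
#' @export
strict_match <- function(x1, x2) {
  as.integer(isTRUE(all(x1 == x2)))
}

#' Effective goal covariance under sensory preference
#'
#' Target-based preference scales the covariance multiplicatively
#' (`kappa * Gamma`); comparison-based preference adds isotropic
#' variance (`Gamma + eta^2 I`), the closed-form consequence of the
#' Gaussian soft matching constraint.
#'
#' @param Gamma Symmetric positive-definite covariance matrix.
#' @param prefs A `preference_params`.
#' @param modality `"auditory"` or `"somatosensory"`.
#' @return The effective covariance (same dimension as `Gamma`).
#' @export
effective_covariance <- function(Gamma, prefs, modality = c("auditory", "somatosensory")) {
  modality <- match.arg(modality)
  Gamma <- as.matrix(Gamma)
  if (inherits(try(chol(Gamma), silent = TRUE), "try-error")) {
    stop("Gamma must be symmetric positive-definite")
  }
  switch(prefs$mode,
    none = Gamma,
    target_based = {
      k <- if (modality == "auditory") prefs$kappa_a else prefs$kappa_s
      k * Gamma
    },
    comparison_based = {
      e <- if (modality == "auditory") prefs$eta_a else prefs$eta_s
      Gamma + e^2 * diag(nrow(Gamma))
    }
  )
}

#' One-dimensional kappa/eta correspondence
#'
#' In one dimension the two preference mechanisms coincide: an additive
#' variance increase `Gamma + eta^2` equals the multiplicative increase
#' `kappa * Gamma` with `kappa = 1 + eta^2 / Gamma`. In higher
#' dimensions the mechanisms differ unless `Gamma` is isotropic.
#'
#' @param Gamma Positive scalar variance.
#' @param eta Non-negative match width.
#' @return The equivalent multiplicative factor `kappa`.
#' @export
kappa_equivalent_1d <- function(Gamma, eta) {
  if (Gamma <= 0) stop("Gamma must be positive")
  1 + eta^2 / Gamma
}

#' Anisotropy summary of a covariance matrix
#'
#' Condition number (ratio of extreme eigenvalues) and leading principal
#' axis. Multiplicative (kappa) scaling leaves both invariant; additive
#' (eta^2 I) inflation keeps the eigenvectors but drives the condition
#' number monotonically toward 1, so goal regions progressively lose
#' their elongation.
#'
#' @param Gamma Symmetric positive-definite matrix.
#' @return List with `condition` (>= 1) and `axis` (unit eigenvector of
#'   the largest eigenvalue).
#' @export
anisotropy <- function(Gamma) {
  e <- eigen(as.matrix(Gamma), symmetric = TRUE)
  if (min(e$values) <= 0) stop("Gamma must be positive-definite")
  list(condition = max(e$values) / min(e$values), axis = e$vectors[, 1])
}
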