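# Synthetic articulatory plant: deterministic ground-truth maps from a
# bounded 6-D control space to (i) a 17-node mid-sagittal tongue contour,
# (ii) the first three formants (Hz), and (iii) a 3-D somatosensory space
# defined as the leading principal components of the contour.

#' Default formant ranges (Hz)
#'
#' Plausible ranges for the first three formants of adult vowels; the
#' acoustic map squashes its output into these intervals.
#'
#' @return A 3 x 2 matrix with columns `lo`, `hi`, rows F1..F3.
#' @export
default_formant_ranges <- function() {
  m <- cbind(lo = c(150, 800, 2000), hi = c(900, 2800, 3800))
  rownames(m) <- c("f1", "f2", "f3")
  m
}

#' Build the synthetic articulatory plant
#'
#' Constructs a deterministic, seeded surrogate of a 2-D biomechanical
#' tongue model. Six control variables (one per modelled tongue muscle,
#' each bounded to a closed interval) drive a 17-node mid-sagittal tongue
#' contour through saturating (tanh) mixtures of the control values, and
#' drive the first three formants through a logistic-squashed quadratic
#' function of the same internal degrees of freedom, so that the acoustic
#' output is (up to a small residual term) a function of tongue shape, as
#' in a real vocal tract. The two maps use different nonlinearities, so
#' the geometry of the auditory and somatosensory spaces is mutually
#' distorted. A PCA basis over the flattened contour (34 coordinates,
#' node-major, x before y) defines the somatosensory space; corpus-level
#' standard deviations of both sensory spaces are stored as scales.
#'
#' @param seed Integer seed; the plant is a deterministic function of it.
#' @param n_pca Number of sampled control vectors used to fit the contour
#'   PCA and the sensory scales (default 5000).
#' @param bounds 6 x 2 matrix of per-dimension control bounds
#'   (default `[-1, 1]` for each dimension).
#' @param formant_ranges 3 x 2 matrix of formant ranges in Hz.
#' @return An object of class `plant_spec`.
#' @export
build_plant <- function(seed = 1L, n_pca = 5000L, bounds = NULL,
                        formant_ranges = default_formant_ranges()) {
  if (is.null(bounds)) {
    bounds <- cbind(lo = rep(-1, 6), hi = rep(1, 6))
  }
  bounds <- as.matrix(bounds)
  stopifnot(nrow(bounds) == 6L, ncol(bounds) == 2L,
            all(is.finite(bounds)), all(bounds[, 1] < bounds[, 2]))
  set.seed(seed)

  unit_rows <- function(nr, nc) {
    m <- matrix(stats::rnorm(nr * nc), nr, nc)
    m / sqrt(rowSums(m^2))
  }

  # Internal degrees of freedom: 3 strong + 2 weak saturating latents.
  V  <- unit_rows(3, 6)
  alpha <- c(1.0, 1.2, 1.4)
  V2 <- unit_rows(2, 6)

  # Resting contour: an arc spanning the mid-sagittal tongue dorsum.
  th <- seq(0.15 * pi, 0.85 * pi, length.out = 17)
  mu0 <- as.numeric(rbind(3 * cos(th), 2 * sin(th)))  # node-major, x then y

  Qb <- qr.Q(qr(matrix(stats::rnorm(34 * 5), 34, 5)))
  U  <- Qb[, 1:3]
  U2 <- Qb[, 4:5]
  s  <- c(3, 2, 1.2)
  s2 <- c(0.15, 0.1)
  # Small direct affine leak: keeps the contour Jacobian full rank 6
  # without disturbing the dominance of the three strong latents.
  B <- matrix(stats::rnorm(34 * 6, sd = 0.03), 34, 6)

  # Acoustic map: quadratic score of the 5 latent dofs (weak latents
  # damped so formants are, in effect, a function of tongue shape),
  # standardized at build time, scaled to realistic per-formant SDs and
  # soft-clipped into the formant ranges.
  w0 <- stats::rnorm(3, sd = 0.3)
  Wl <- matrix(stats::rnorm(15, sd = 1), 3, 5)
  Wl[, 4:5] <- 0.02 * Wl[, 4:5]
  Qq <- lapply(1:3, function(i) {
    q <- matrix(stats::rnorm(25, sd = 0.13), 5, 5)
    q <- (q + t(q)) / 2
    q[4:5, ] <- 0.02 * q[4:5, ]
    q[, 4:5] <- 0.02 * q[, 4:5]
    q
  })

  spec <- structure(list(
    seed = as.integer(seed),
    bounds = bounds,
    contour = list(mu0 = mu0, V = V, alpha = alpha, V2 = V2,
                   U = U, s = s, U2 = U2, s2 = s2, B = B),
    acoustic = list(w0 = w0, Wl = Wl, Qq = Qq,
                    q_center = c(0, 0, 0), q_scale = c(1, 1, 1),
                    out_sd = c(130, 330, 280),
                    ranges = as.matrix(formant_ranges)),
    pca = NULL,
    scales = NULL
  ), class = "plant_spec")

  m <- sample_control_space(n_pca, seed = seed + 101L, spec = spec)
  q <- acoustic_score(m, spec)
  spec$acoustic$q_center <- colMeans(q)
  spec$acoustic$q_scale <- apply(q, 2, stats::sd)
  contours <- synth_contour(m, spec)
  spec$pca <- fit_pca(contours)
  a <- plant_auditory(m, spec)
  sc <- project_contour(contours, spec$pca)
  spec$scales <- list(auditory_sd = apply(a, 2, stats::sd),
                      somato_sd = apply(sc, 2, stats::sd))
  spec
}

as_control_matrix <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  m <- as.matrix(m)
  stopifnot(ncol(m) == 6L, all(is.finite(m)))
  m
}

check_bounds <- function(m, spec, tol = 1e-9) {
  lo <- matrix(spec$bounds[, 1], nrow(m), 6, byrow = TRUE)
  hi <- matrix(spec$bounds[, 2], nrow(m), 6, byrow = TRUE)
  if (any(m < lo - tol) || any(m > hi + tol)) {
    stop("control vector outside the plant's control bounds")
  }
  invisible(m)
}

#' Sample the control space uniformly
#'
#' Draws i.i.d. uniform samples over the bounded control box; the
#' training corpus for the internal models is produced this way.
#'
#' @param n Number of samples (>= 1).
#' @param seed Integer seed.
#' @param spec A `plant_spec`.
#' @return An `n` x 6 matrix of control vectors.
#' @export
sample_control_space <- function(n, seed, spec) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  set.seed(seed)
  u <- matrix(stats::runif(n * 6L), n, 6L)
  lo <- spec$bounds[, 1]
  hi <- spec$bounds[, 2]
  m <- sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
  colnames(m) <- paste0("lambda_", 1:6)
  m
}

plant_latents <- function(m, spec) {
  cc <- spec$contour
  z <- tanh(sweep(m %*% t(cc$V), 2, cc$alpha, "*"))
  w <- tanh(m %*% t(cc$V2))
  cbind(z, w)
}

#' Tongue contour synthesis
#'
#' Deterministic map from a control vector to the 17-node mid-sagittal
#' tongue contour (flattened to 34 coordinates, node-major, x before y).
#'
#' @param m Control vector (length 6) or matrix (n x 6).
#' @param spec A `plant_spec`.
#' @return An n x 34 matrix of flattened contours (n = 1 for a vector).
#' @export
synth_contour <- function(m, spec) {
  m <- as_control_matrix(m)
  check_bounds(m, spec)
  cc <- spec$contour
  u <- plant_latents(m, spec)
  z <- u[, 1:3, drop = FALSE]
  w <- u[, 4:5, drop = FALSE]
  out <- matrix(cc$mu0, nrow(m), 34, byrow = TRUE) +
    z %*% t(sweep(cc$U, 2, cc$s, "*")) +
    w %*% t(sweep(cc$U2, 2, cc$s2, "*")) +
    m %*% t(cc$B)
  out
}

#' Fit the somatosensory PCA basis
#'
#' Principal components of a corpus of flattened tongue contours; the
#' somatosensory space is the score space of the leading three
#' components.
#'
#' @param contours n x 34 matrix of flattened contours (n >= 100).
#' @return A list with `center` (34-vector), `rotation` (34 x 3
#'   orthonormal loadings) and `evar` (explained-variance fractions).
#' @export
fit_pca <- function(contours) {
  contours <- as.matrix(contours)
  if (nrow(contours) < 100L) stop("need at least 100 contours to fit the PCA")
  p <- stats::prcomp(contours, center = TRUE, scale. = FALSE)
  if (length(p$sdev) < 3L || p$sdev[3] <= 0) {
    stop("contour corpus is rank deficient: fewer than 3 informative components")
  }
  list(center = p$center,
       rotation = p$rotation[, 1:3, drop = FALSE],
       evar = (p$sdev^2 / sum(p$sdev^2))[1:3])
}

project_contour <- function(contours, pca) {
  sc <- sweep(as.matrix(contours), 2, pca$center) %*% pca$rotation
  colnames(sc) <- paste0("pc", 1:3)
  sc
}

#' Auditory output of the plant
#'
#' Deterministic map from control vectors to the first three formants
#' (Hz). The formants are logistic-squashed quadratics of the plant's
#' internal tongue-shape degrees of freedom, guaranteeing outputs inside
#' the configured formant ranges.
#'
#' @inheritParams synth_contour
#' @return n x 3 matrix with columns `f1`, `f2`, `f3` (Hz).
#' @export
plant_auditory <- function(m, spec) {
  m <- as_control_matrix(m)
  check_bounds(m, spec)
  ac <- spec$acoustic
  q <- acoustic_score(m, spec)
  qs <- sweep(sweep(q, 2, ac$q_center), 2, ac$q_scale, "/")
  mid <- (ac$ranges[, 1] + ac$ranges[, 2]) / 2
  half <- (ac$ranges[, 2] - ac$ranges[, 1]) / 2
  f <- qs
  for (i in 1:3) {
    f[, i] <- mid[i] + half[i] * tanh(ac$out_sd[i] * qs[, i] / half[i])
  }
  colnames(f) <- c("f1", "f2", "f3")
  f
}

# Raw (unstandardized) quadratic acoustic score of the latent dofs.
acoustic_score <- function(m, spec) {
  ac <- spec$acoustic
  u <- plant_latents(m, spec)
  q <- sweep(u %*% t(ac$Wl), 2, ac$w0, "+")
  for (i in 1:3) {
    q[, i] <- q[, i] + 0.5 * rowSums((u %*% ac$Qq[[i]]) * u)
  }
  q
}

#' Somatosensory output of the plant
#'
#' Projection of the synthesized tongue contour onto the fitted
#' 3-component PCA basis.
#'
#' @inheritParams synth_contour
#' @return n x 3 matrix with columns `pc1`, `pc2`, `pc3`.
#' @export
plant_somato <- function(m, spec) {
  if (is.null(spec$pca)) stop("plant has no fitted PCA basis")
  project_contour(synth_contour(m, spec), spec$pca)
}

#' Apply an auditory perturbation
#'
#' Component-wise shift of an auditory point: the perceived output under
#' a formant-shifting perturbation is the produced output plus `delta`.
#'
#' @param a Auditory point (length-3 vector) or n x 3 matrix, Hz.
#' @param delta Length-3 shift in Hz.
#' @return Shifted point(s), same shape as `a`.
#' @export
apply_perturbation <- function(a, delta) {
  stopifnot(length(delta) == 3L, all(is.finite(delta)), all(is.finite(a)))
  if (is.null(dim(a))) {
    stopifnot(length(a) == 3L)
    a + delta
  } else {
    sweep(a, 2, delta, "+")
  }
}

#' Export a sensory-motor corpus
#'
#' Samples the control space and tabulates control values with their
#' auditory and somatosensory consequences.
#'
#' @param n Number of rows.
#' @param seed Integer seed.
#' @param spec A `plant_spec` with fitted PCA.
#' @param file Optional CSV path; when given, the table is written there.
#' @return A data.frame with columns lambda_1..6, f1..f3, pc1..3.
#' @export
plant_corpus <- function(n, seed, spec, file = NULL) {
  m <- sample_control_space(n, seed, spec)
  out <- data.frame(m, plant_auditory(m, spec), plant_somato(m, spec))
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
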