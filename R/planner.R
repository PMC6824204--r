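# Bayesian planning core: phoneme-conditioned posterior over motor
# commands. With deterministic internal models and uniform priors the
# posterior is, up to a constant, the product of the active modalities'
# Gaussian goal densities evaluated at the predicted sensory
# consequences; it is sampled by random-walk Metropolis-Hastings over
# the bounded control box.

#' Multivariate normal log density
#'
#' @param x Point (vector) or n x d matrix of points.
#' @param mu Mean vector.
#' @param Sigma Covariance matrix (SPD).
#' @return Log density value(s).
#' @export
logdmvnorm <- function(x, mu, Sigma) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  L <- chol(as.matrix(Sigma))
  z <- backsolve(L, t(sweep(x, 2, mu)), transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(L))) - 0.5 * ncol(x) * log(2 * pi)
}

# Precomputed fast handle for a sensory map: constant + linear + kernel
# weights split out so single-point prediction is cheap inside MCMC.
map_handle <- function(map) {
  d <- map$d
  w <- map$weights
  list(tc = t(map$centers),
       inv2b2 = 1 / (2 * map$bandwidth^2),
       w0 = as.numeric(w[1, ]) + map$adaptation_offset,
       Wl = w[2:(d + 1), , drop = FALSE],
       Wk = w[(d + 2):nrow(w), , drop = FALSE])
}

map_predict1 <- function(h, m) {
  d2 <- colSums((h$tc - m)^2)
  drop(h$w0 + crossprod(h$Wl, m) + crossprod(h$Wk, exp(-d2 * h$inv2b2)))
}

#' Construct a planning query
#'
#' Bundles the phoneme's goal regions, the internal models and the
#' sensory preference parameters, with coherence flags selecting the
#' planning process: auditory-only (`c_a` only), somatosensory-only
#' (`c_s` only) or fusion (both). Effective covariances (after
#' preference) are factorized once here.
#'
#' @param phoneme Phoneme label present in the inventory.
#' @param inventory A `phoneme_inventory`.
#' @param maps List with elements `auditory` and `somato`
#'   (`sensory_map`s); the auditory map may be adapted.
#' @param c_a,c_s Logical coherence flags; at least one must be set.
#' @param prefs A `preference_params`.
#' @param bounds 6 x 2 control bounds (defaults to the inventory's
#'   stored bounds).
#' @return An object of class `planning_query`.
#' @export
planning_query <- function(phoneme, inventory, maps, c_a = TRUE, c_s = TRUE,
                           prefs = preference_params("none"), bounds = NULL) {
  if (!c_a && !c_s) {
    stop("at least one coherence flag must be active: with both off the query is the uniform prior")
  }
  tg <- inventory$targets[[phoneme]]
  if (is.null(tg)) stop("unknown phoneme: ", phoneme)
  if (is.null(bounds)) bounds <- inventory$bounds
  q <- list(phoneme = phoneme, c_a = c_a, c_s = c_s, prefs = prefs,
            bounds = bounds, terms = list())
  if (c_a) {
    Sig <- effective_covariance(tg$Gamma_A, prefs, "auditory")
    L <- chol(Sig)
    q$terms$auditory <- list(
      h = map_handle(maps$auditory), mu = tg$mu_A,
      P = chol2inv(L),
      const = -sum(log(diag(L))) - 1.5 * log(2 * pi))
  }
  if (c_s) {
    Sig <- effective_covariance(tg$Gamma_S, prefs, "somatosensory")
    L <- chol(Sig)
    q$terms$somato <- list(
      h = map_handle(maps$somato), mu = tg$mu_S,
      P = chol2inv(L),
      const = -sum(log(diag(L))) - 1.5 * log(2 * pi))
  }
  structure(q, class = "planning_query")
}

#' Log posterior density of a motor command
#'
#' Normalized per active modality: each term is the full Gaussian log
#' density of the predicted sensory consequence under the (preference-
#' modulated) goal region; fusion is their sum. The flat priors over
#' commands and phonemes contribute only a constant and are omitted.
#'
#' @param m Control vector (length 6).
#' @param query A `planning_query`.
#' @return Unnormalized (over `m`) log posterior value.
#' @export
log_posterior <- function(m, query) {
  lp <- 0
  for (tm in query$terms) {
    r <- map_predict1(tm$h, m) - tm$mu
    lp <- lp + tm$const - 0.5 * sum(r * (tm$P %*% r))
  }
  lp
}

#' Random-walk Metropolis-Hastings over a bounded box
#'
#' Symmetric Gaussian proposals; proposals outside the box are rejected
#' (the bounded uniform prior's support constraint). During burn-in the
#' proposal scale adapts toward a 23% acceptance rate and is then
#' frozen. Each chain starts at the best of `init_probes` uniform
#' probes and uses a seed derived deterministically from `seed`.
#'
#' @param log_f Log target density, a function of a length-d vector.
#' @param lower,upper Box bounds (length d).
#' @param chains Number of independent chains.
#' @param burn,keep Discarded and retained iterations per chain.
#' @param seed Master integer seed.
#' @param prop_scale Initial proposal SD as a fraction of box width.
#' @param adapt Adapt the proposal scale during burn-in?
#' @param init_probes Uniform probes used to pick each chain's start.
#' @return Object of class `posterior_samples`: `draws`
#'   ((chains*keep) x d matrix), `chain` index per draw, `acceptance`
#'   per chain, and the sampler configuration.
#' @export
mh_sample <- function(log_f, lower, upper, chains = 20L, burn = 1000L,
                      keep = 1000L, seed = 1L, prop_scale = 0.05,
                      adapt = TRUE, init_probes = 200L) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower))
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)
  width <- upper - lower
  draws <- matrix(NA_real_, chains * keep, d)
  acc <- numeric(chains)
  scales <- numeric(chains)
  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    probes <- sweep(sweep(matrix(stats::runif(init_probes * d), init_probes, d),
                          2, width, "*"), 2, lower, "+")
    plp <- apply(probes, 1, log_f)
    if (!any(is.finite(plp))) stop("log density not finite at any initial probe")
    cur <- probes[which.max(plp), ]
    lp_cur <- max(plp)
    sdv <- prop_scale * width
    n_acc_win <- 0L; n_acc_keep <- 0L
    total <- burn + keep
    for (i in seq_len(total)) {
      prop <- cur + stats::rnorm(d) * sdv
      ok <- all(prop >= lower) && all(prop <= upper)
      if (ok) {
        lp_prop <- log_f(prop)
        if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp_cur) {
          cur <- prop; lp_cur <- lp_prop
          n_acc_win <- n_acc_win + 1L
          if (i > burn) n_acc_keep <- n_acc_keep + 1L
        }
      }
      if (adapt && i <= burn && i %% 50L == 0L) {
        rate <- n_acc_win / 50
        sdv <- sdv * exp(rate - 0.234)
        n_acc_win <- 0L
      }
      if (i > burn) draws[(ch - 1L) * keep + (i - burn), ] <- cur
    }
    acc[ch] <- n_acc_keep / keep
    scales[ch] <- sdv[1] / width[1]
  }
  if (all(acc < 0.01)) {
    stop("acceptance rate below 1% in every chain: proposal scale misconfigured")
  }
  structure(list(
    draws = draws,
    chain = rep(seq_len(chains), each = keep),
    acceptance = acc,
    final_scale = scales,
    config = list(chains = chains, burn = burn, keep = keep, seed = seed,
                  prop_scale = prop_scale, adapt = adapt,
                  init_probes = init_probes),
    chain_seeds = chain_seeds
  ), class = "posterior_samples")
}

#' Sample the planning posterior
#'
#' Runs [mh_sample()] on a planning query over the control box and
#' attaches the internal-model predictions of the retained draws. The
#' default protocol retains 2e4 draws from 20 chains after 1e3 burn-in
#' iterations each.
#'
#' @param query A `planning_query`.
#' @param chains,burn,keep,seed,prop_scale,adapt Sampler settings, see
#'   [mh_sample()].
#' @param maps Optional list of `sensory_map`s used to annotate draws
#'   with predicted sensory outcomes; `NULL` to skip.
#' @return A `posterior_samples` with optional `pred_aud` / `pred_som`.
#' @export
mcmc_sample <- function(query, chains = 20L, burn = 1000L, keep = 1000L,
                        seed = 1L, prop_scale = 0.05, adapt = TRUE,
                        maps = NULL) {
  lower <- query$bounds[, 1]; upper <- query$bounds[, 2]
  ps <- mh_sample(function(m) log_posterior(m, query), lower, upper,
                  chains = chains, burn = burn, keep = keep, seed = seed,
                  prop_scale = prop_scale, adapt = adapt)
  ps$phoneme <- query$phoneme
  if (!is.null(maps)) {
    ps$pred_aud <- predict(maps$auditory, ps$draws)
    ps$pred_som <- predict(maps$somato, ps$draws)
  }
  ps
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("<posterior_samples> %d draws (%d chains x %d), d = %d\n",
              nrow(x$draws), x$config$chains, x$config$keep, ncol(x$draws)))
  cat(sprintf("  acceptance: %.2f-%.2f\n", min(x$acceptance), max(x$acceptance)))
  invisible(x)
}

#' Dispersion ellipse of a 2-D point cloud
#'
#' Ellipse centered at the sample mean with semi-axes `order` times the
#' square roots of the sample-covariance eigenvalues, oriented along the
#' principal eigenvector.
#'
#' @param points n x 2 matrix (n >= 3, non-collinear).
#' @param order Multiplier of the covariance square-root axes.
#' @return List with `center`, `axes` (semi-axis lengths, decreasing)
#'   and `angle` (degrees in (-90, 90]).
#' @export
dispersion_ellipse <- function(points, order = 2) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L, nrow(points) >= 3L)
  S <- stats::cov(points)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) <= 0) stop("degenerate covariance: points are collinear")
  v <- e$vectors[, 1]
  ang <- atan2(v[2], v[1]) * 180 / pi
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  list(center = colMeans(points), axes = order * sqrt(e$values), angle = ang)
}

ellipse_path <- function(el, n = 120) {
  t <- seq(0, 2 * pi, length.out = n)
  a <- el$angle * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  xy <- t(R %*% rbind(el$axes[1] * cos(t), el$axes[2] * sin(t))) +
    matrix(el$center, n, 2, byrow = TRUE)
  data.frame(x = xy[, 1], y = xy[, 2])
}

#' Grid-normalized posterior marginals
#'
#' Exhaustive evaluation of a log density over a regular grid on a
#' low-dimensional box, normalized to per-dimension marginal CDFs. This
#' is an independent closed-form reference for validating the MCMC
#' sampler on reduced (2-D) problems.
#'
#' @param log_f Log density, function of a length-d vector.
#' @param lower,upper Box bounds (small d; the grid has `n_grid^d`
#'   cells).
#' @param n_grid Grid resolution per dimension.
#' @return List with per-dimension `grid` (cell midpoints) and `cdf`
#'   (marginal CDF at the cell right edges).
#' @export
grid_marginals <- function(log_f, lower, upper, n_grid = 201L) {
  d <- length(lower)
  axes <- lapply(seq_len(d), function(i) {
    seq(lower[i], upper[i], length.out = n_grid + 1L)
  })
  mids <- lapply(axes, function(a) (a[-1] + a[-length(a)]) / 2)
  pts <- as.matrix(expand.grid(mids))
  lp <- apply(pts, 1, log_f)
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  lapply(seq_len(d), function(i) {
    marg <- tapply(w, factor(pts[, i], levels = mids[[i]]), sum)
    list(grid = mids[[i]], edges = axes[[i]][-1],
         cdf = cumsum(as.numeric(marg)))
  })
}

#' Kolmogorov-Smirnov distance of draws to grid marginals
#'
#' Largest absolute difference, over the grid's cell edges, between the
#' empirical CDF of the draws and a grid-normalized marginal CDF, per
#' dimension.
#'
#' @param draws n x d matrix of samples.
#' @param marginals Result of [grid_marginals()].
#' @return Numeric vector of per-dimension KS distances.
#' @export
ks_to_grid <- function(draws, marginals) {
  draws <- as.matrix(draws)
  vapply(seq_along(marginals), function(i) {
    mg <- marginals[[i]]
    emp <- vapply(mg$edges, function(e) mean(draws[, i] <= e), numeric(1))
    max(abs(emp - mg$cdf))
  }, numeric(1))
}
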