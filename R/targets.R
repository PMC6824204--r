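# Gaussian phoneme goal regions: auditory targets for the six vowels
# placed inside the plant's reachable formant region, and somatosensory
# targets derived as the image of the auditory regions under the
# model's own auditory-only planning.

#' The six vowel labels
#'
#' Tongue-only French vowels (fixed jaw and lips): /i/, /e/, the open-mid
#' front vowel, /a/, the mid front rounded vowel, and the open-mid back
#' vowel.
#'
#' @return Character vector of length 6 (UTF-8 IPA labels).
#' @export
vowel_labels <- function() c("i", "e", "\u025B", "a", "\u0153", "\u0254")

# Normalized (quantile) coordinates of each vowel in (F1, F2, F3):
# front vowels high F2 / low F1, open vowels high F1, back rounded low F2.
default_vowel_layout <- function() {
  data.frame(
    phoneme = vowel_labels(),
    q1 = c(0.08, 0.25, 0.45, 0.88, 0.50, 0.35),
    q2 = c(0.92, 0.82, 0.70, 0.45, 0.40, 0.12),
    q3 = c(0.55, 0.52, 0.50, 0.48, 0.45, 0.42),
    stringsAsFactors = FALSE
  )
}

#' Define auditory goal regions for the vowel inventory
#'
#' Places six well-separated Gaussian goal regions inside the plant's
#' reachable formant region. Each mean is the average of the corpus
#' points nearest (in range-normalized coordinates) to the vowel's
#' quantile anchor, which guarantees reachability; each covariance
#' combines the local corpus correlation structure with configured
#' per-formant standard deviations. Pairwise Mahalanobis separation of
#' at least `min_separation` (under either region's covariance) is
#' enforced.
#'
#' @param spec A `plant_spec`.
#' @param n_corpus Corpus size used to map the reachable region.
#' @param seed Integer seed for the corpus.
#' @param layout Data frame of per-vowel quantile anchors.
#' @param sds Length-3 per-formant target standard deviations (Hz).
#' @param k_local Number of nearest corpus points used per vowel.
#' @param min_separation Minimum pairwise Mahalanobis distance.
#' @param spread Shrink factor pulling the selected anchor points toward
#'   the reachable region's centroid (1 = none).
#' @return Named list (per phoneme) of `mu_A` / `Gamma_A` pairs.
#' @export
define_auditory_targets <- function(spec, n_corpus = 10000L, seed = 1L,
                                    layout = default_vowel_layout(),
                                    sds = c(24, 45, 60), k_local = 100L,
                                    min_separation = 2, spread = 0.7) {
  m <- sample_control_space(n_corpus, seed, spec)
  a <- plant_auditory(m, spec)
  qlo <- apply(a, 2, stats::quantile, 0.01)
  qhi <- apply(a, 2, stats::quantile, 0.99)
  an <- sweep(sweep(a, 2, qlo), 2, qhi - qlo, "/")

  # Anchor points on the reachable set. The reference vowel (the open-mid
  # back vowel, used in the perturbation experiments) is pinned at its
  # canonical quantile position -- mid F1, so that formant-shifted goals
  # stay reachable -- and the remaining five anchors are chosen by
  # farthest-point selection, pulled toward the centroid by `spread` so
  # all regions sit in the interior of the reachable set.
  ctr <- colMeans(an)
  ref <- which(layout$phoneme == "\u0254")[1]
  ref_anchor <- as.numeric(layout[ref, c("q1", "q2", "q3")])
  sel <- which.min(colSums((t(an) - ref_anchor)^2))
  for (k in 2:6) {
    d2min <- rep(Inf, nrow(an))
    for (s in sel) d2min <- pmin(d2min, colSums((t(an) - an[s, ])^2))
    sel <- c(sel, which.max(d2min))
  }
  anchors <- sweep(spread * sweep(an[sel, , drop = FALSE], 2, ctr), 2, ctr, "+")
  anchors[1, ] <- an[sel[1], ]  # reference anchor stays where pinned

  # Assign the other five labels: the permutation matching the anchors
  # to the canonical vowel-chart quantile layout with least total
  # squared error.
  want <- as.matrix(layout[-ref, c("q1", "q2", "q3")])
  perms <- as.matrix(expand.grid(rep(list(2:6), 5)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5L), ]
  cost <- apply(perms, 1, function(p) sum((anchors[p, ] - want)^2))
  ord_rest <- perms[which.min(cost), ]
  ord <- integer(6)
  ord[ref] <- 1L
  ord[setdiff(seq_len(6), ref)] <- ord_rest

  targets <- list()
  for (i in seq_len(nrow(layout))) {
    anchor <- anchors[ord[i], ]
    d2 <- colSums((t(an) - anchor)^2)
    idx <- order(d2)[seq_len(k_local)]
    mu <- colMeans(a[idx, , drop = FALSE])
    R <- stats::cor(a[idx, , drop = FALSE])
    R <- 0.6 * R + 0.4 * diag(3)  # shrink toward identity: guarantees SPD
    D <- diag(sds)
    Gamma <- D %*% R %*% D
    targets[[layout$phoneme[i]]] <- list(mu_A = mu, Gamma_A = Gamma)
  }
  ph <- names(targets)
  for (i in seq_along(ph)) for (j in seq_along(ph)) {
    if (i == j) next
    dm <- targets[[ph[i]]]$mu_A - targets[[ph[j]]]$mu_A
    md <- sqrt(sum(dm * solve(targets[[ph[i]]]$Gamma_A, dm)))
    if (md < min_separation) {
      stop(sprintf("targets %s and %s are under-separated (Mahalanobis %.2f)",
                   ph[i], ph[j], md))
    }
  }
  targets
}

# Query over the control box whose density is the auditory goal Gaussian
# evaluated at the auditory internal-model prediction (auditory-only
# planning for an explicit goal, used before an inventory exists).
auditory_goal_logf <- function(mu_a, Gamma_a, aud_map) {
  h <- map_handle(aud_map)
  L <- chol(as.matrix(Gamma_a))
  P <- chol2inv(L)
  function(m) {
    r <- map_predict1(h, m) - mu_a
    -0.5 * sum(r * (P %*% r))
  }
}

#' Derive a somatosensory goal region from an auditory one
#'
#' Somatosensory goals are learned as a consequence of achieving the
#' auditory goals: motor commands are sampled from the auditory-only
#' planning posterior for the given auditory region, pushed through the
#' somatosensory internal model, and the resulting cloud is
#' moment-matched by a Gaussian. Between-chain variability provides
#' Monte-Carlo standard errors of the mean.
#'
#' @param mu_a,Gamma_a Auditory goal mean (Hz) and covariance.
#' @param maps List with `auditory` and `somato` `sensory_map`s
#'   (unadapted).
#' @param bounds 6 x 2 control bounds.
#' @param n_draws Total retained posterior draws (default 5000).
#' @param chains Number of chains (draws are split evenly).
#' @param burn Burn-in per chain.
#' @param seed Integer seed.
#' @return List with `mu_S`, `Gamma_S`, `mu_S_se` (between-chain SE) and
#'   the pushed-forward samples.
#' @export
derive_somato_target <- function(mu_a, Gamma_a, maps, bounds,
                                 n_draws = 5000L, chains = 10L,
                                 burn = 500L, seed = 1L) {
  keep <- ceiling(n_draws / chains)
  ps <- mh_sample(auditory_goal_logf(mu_a, Gamma_a, maps$auditory),
                  lower = bounds[, 1], upper = bounds[, 2],
                  chains = chains, burn = burn, keep = keep, seed = seed)
  s <- predict(maps$somato, ps$draws)
  Gamma_S <- stats::cov(s)
  ev <- eigen(Gamma_S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("degenerate pushed-forward cloud: somatosensory covariance not SPD")
  }
  ch_means <- apply(s, 2, function(col) tapply(col, ps$chain, mean))
  list(mu_S = colMeans(s), Gamma_S = Gamma_S,
       mu_S_se = apply(ch_means, 2, stats::sd) / sqrt(chains),
       samples = s)
}

#' Build the phoneme inventory
#'
#' Auditory goal regions for the six vowels plus derived somatosensory
#' regions, with provenance (plant seed, derivation sizes).
#'
#' @param spec A `plant_spec`.
#' @param maps Unadapted internal models (`auditory`, `somato`).
#' @param seed Master seed; per-phoneme derivation seeds are spawned
#'   from it.
#' @param n_corpus Corpus size for target placement.
#' @param n_draws,chains,burn Derivation sampler sizes, see
#'   [derive_somato_target()].
#' @param ... Passed to [define_auditory_targets()].
#' @return An object of class `phoneme_inventory` with `targets` (named
#'   list of `mu_A`, `Gamma_A`, `mu_S`, `Gamma_S`), `bounds` and
#'   `provenance`.
#' @export
build_inventory <- function(spec, maps, seed = 1L, n_corpus = 10000L,
                            n_draws = 5000L, chains = 10L, burn = 500L, ...) {
  seeds <- spawn_seeds(seed, 7L)
  aud <- define_auditory_targets(spec, n_corpus = n_corpus, seed = seeds[1], ...)
  targets <- list()
  for (i in seq_along(aud)) {
    ph <- names(aud)[i]
    der <- derive_somato_target(aud[[i]]$mu_A, aud[[i]]$Gamma_A, maps,
                                bounds = spec$bounds, n_draws = n_draws,
                                chains = chains, burn = burn,
                                seed = seeds[i + 1])
    targets[[ph]] <- list(mu_A = aud[[i]]$mu_A, Gamma_A = aud[[i]]$Gamma_A,
                          mu_S = der$mu_S, Gamma_S = der$Gamma_S,
                          mu_S_se = der$mu_S_se)
  }
  structure(list(
    targets = targets,
    bounds = spec$bounds,
    provenance = list(plant_seed = spec$seed, seed = seed,
                      n_corpus = n_corpus, n_draws = n_draws,
                      chains = chains, burn = burn)
  ), class = "phoneme_inventory")
}

#' Goal-region log density
#'
#' Exact multivariate normal log density of a sensory point under a
#' phoneme's goal region in the requested modality, with the covariance
#' modulated by the preference parameters.
#'
#' @param target A single inventory entry (`mu_A`, `Gamma_A`, `mu_S`,
#'   `Gamma_S`).
#' @param modality `"auditory"` or `"somatosensory"`.
#' @param x Sensory point (length 3).
#' @param prefs A `preference_params`.
#' @return Log density value.
#' @export
target_log_density <- function(target, modality = c("auditory", "somatosensory"),
                               x, prefs = preference_params("none")) {
  modality <- match.arg(modality)
  mu <- if (modality == "auditory") target$mu_A else target$mu_S
  Gamma <- if (modality == "auditory") target$Gamma_A else target$Gamma_S
  logdmvnorm(x, mu, effective_covariance(Gamma, prefs, modality))
}

#' @export
print.phoneme_inventory <- function(x, ...) {
  cat("<phoneme_inventory>", length(x$targets), "phonemes:",
      paste(names(x$targets), collapse = " "), "\n")
  for (ph in names(x$targets)) {
    cat(sprintf("  /%s/ mu_A = (%s) Hz\n", ph,
                paste(round(x$targets[[ph]]$mu_A), collapse = ", ")))
  }
  invisible(x)
}
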