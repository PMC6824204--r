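# Experiment pipeline: asset construction, the three perturbation/
# adaptation conditions, the compensation metric, preference sweeps and
# figure rendering.

#' Build all simulation assets
#'
#' One call constructs the full stack: plant, training corpus, auditory
#' and somatosensory internal models, and the phoneme inventory. All
#' stochastic steps use seeds spawned deterministically from `seed`
#' (spawning order: plant build, corpus, auditory fit, somatosensory
#' fit, inventory).
#'
#' @param seed Master integer seed driving all stochastic steps
#'   (corpus sampling, map fits, target derivation).
#' @param plant_seed Seed of the reference plant definition. The plant's
#'   weights play the role of a fixed biomechanical model, so this is a
#'   model constant, kept separate from the run seed.
#' @param n_corpus Internal-model training corpus size (default 50000).
#' @param n_centers RBF centers per map.
#' @param n_pca Contours used to fit the somatosensory PCA.
#' @param target_corpus Corpus size for target placement.
#' @param target_draws Posterior draws per derived somatosensory target.
#' @param target_chains,target_burn Derivation sampler sizes.
#' @return List of class `speechplan_assets` with `plant`, `maps`
#'   (`auditory`, `somato`), `inventory` and `seeds`.
#' @export
build_assets <- function(seed = 1L, plant_seed = 20L, n_corpus = 50000L,
                         n_centers = 800L, n_pca = 5000L,
                         target_corpus = 10000L, target_draws = 5000L,
                         target_chains = 10L, target_burn = 500L) {
  seeds <- spawn_seeds(seed, 5L)
  plant <- build_plant(seed = plant_seed, n_pca = n_pca)
  m <- sample_control_space(n_corpus, seed = seeds[2], spec = plant)
  a <- plant_auditory(m, plant)
  s <- plant_somato(m, plant)
  maps <- list(
    auditory = fit_sensory_map(m, a, "auditory", n_centers = n_centers,
                               seed = seeds[3]),
    somato = fit_sensory_map(m, s, "somatosensory", n_centers = n_centers,
                             seed = seeds[4])
  )
  inventory <- build_inventory(plant, maps, seed = seeds[5],
                               n_corpus = target_corpus,
                               n_draws = target_draws,
                               chains = target_chains, burn = target_burn)
  structure(list(plant = plant, maps = maps, inventory = inventory,
                 seeds = seeds, master_seed = seed, plant_seed = plant_seed),
            class = "speechplan_assets")
}

mode_flags <- function(mode) {
  switch(mode,
         auditory = c(TRUE, FALSE),
         somatosensory = c(FALSE, TRUE),
         fusion = c(TRUE, TRUE),
         stop("unknown planning mode: ", mode))
}

#' Run one experimental condition
#'
#' Samples the planning posterior for one phoneme under one condition:
#' `unperturbed` (baseline maps, no perturbation), `pre_adaptation`
#' (plans with the baseline maps -- no re-planning occurs before
#' adaptation -- while the perceived auditory outcome is shifted by
#' `delta`), or `post_adaptation` (plans with the adapted auditory map;
#' perceived outcome still shifted). Produced sensory outcomes are the
#' ground-truth plant outputs of the draws; perceived auditory outcomes
#' add `delta` in perturbed conditions.
#'
#' @param assets A `speechplan_assets`.
#' @param condition `"unperturbed"`, `"pre_adaptation"` or
#'   `"post_adaptation"`.
#' @param mode `"auditory"`, `"somatosensory"` or `"fusion"`.
#' @param prefs A `preference_params`.
#' @param phoneme Phoneme label (default: open-mid back vowel).
#' @param delta Length-3 auditory perturbation (Hz).
#' @param chains,burn,keep,seed Sampler settings.
#' @param keep_samples Attach the full `posterior_samples`?
#' @return A `compensation_result`: condition, mode, preference, draw
#'   summaries (means, between-chain standard errors), order-2
#'   dispersion ellipses in the (F2, F1) and (pc1, pc2) planes.
#' @export
run_condition <- function(assets, condition = c("unperturbed", "pre_adaptation",
                                                "post_adaptation"),
                          mode = c("fusion", "auditory", "somatosensory"),
                          prefs = preference_params("none"),
                          phoneme = "\u0254", delta = c(-100, 0, 0),
                          chains = 20L, burn = 1000L, keep = 1000L,
                          seed = 1L, keep_samples = FALSE) {
  condition <- match.arg(condition)
  mode <- match.arg(mode)
  maps <- assets$maps
  if (condition == "post_adaptation") {
    maps$auditory <- adapt_auditory(maps$auditory, delta)
  }
  fl <- mode_flags(mode)
  query <- planning_query(phoneme, assets$inventory, maps,
                          c_a = fl[1], c_s = fl[2], prefs = prefs)
  ps <- mcmc_sample(query, chains = chains, burn = burn, keep = keep,
                    seed = seed)
  produced_aud <- plant_auditory(ps$draws, assets$plant)
  produced_som <- plant_somato(ps$draws, assets$plant)
  perceived_aud <- if (condition == "unperturbed") produced_aud else
    apply_perturbation(produced_aud, delta)

  chain_se <- function(x) {
    cm <- apply(x, 2, function(col) tapply(col, ps$chain, mean))
    apply(cm, 2, stats::sd) / sqrt(chains)
  }
  res <- structure(list(
    condition = condition, mode = mode, prefs = prefs, phoneme = phoneme,
    delta = delta,
    produced_aud_mean = colMeans(produced_aud),
    produced_aud_se = chain_se(produced_aud),
    perceived_aud_mean = colMeans(perceived_aud),
    somato_mean = colMeans(produced_som),
    somato_se = chain_se(produced_som),
    ellipse_aud = dispersion_ellipse(perceived_aud[, c(2, 1)], order = 2),
    ellipse_som = dispersion_ellipse(produced_som[, 1:2], order = 2),
    acceptance = ps$acceptance
  ), class = "compensation_result")
  if (keep_samples) res$samples <- ps
  res
}

#' Compensation ratio
#'
#' Scalar compensation metric: the displacement of the produced
#' (ground-truth, unshifted) auditory mean relative to an unperturbed
#' baseline, projected on the direction opposite to the perturbation and
#' normalized by the perturbation magnitude. 1 is full compensation
#' (production shifted by exactly `-delta`), 0 is none.
#'
#' @param post A `compensation_result` (typically post-adaptation).
#' @param baseline The unperturbed `compensation_result` of the same
#'   phoneme and mode lineage.
#' @param delta Length-3 perturbation (Hz), non-zero.
#' @return Dimensionless scalar.
#' @export
compensation_ratio <- function(post, baseline, delta) {
  nd <- sqrt(sum(delta^2))
  if (nd == 0) stop("perturbation delta must be non-zero")
  u <- -delta / nd
  sum((post$produced_aud_mean - baseline$produced_aud_mean) * u) / nd
}

#' Preference parameter sweep
#'
#' Runs the post-adaptation fusion planning over a grid of one
#' preference parameter, holding everything else (including seeds, for
#' variance reduction) fixed, and reports the compensation ratio at
#' each grid value. `kappa_*` sweeps use the target-based mechanism;
#' `eta_*` sweeps the comparison-based one, with grid values expressed
#' as multiples of the corresponding sensory space's corpus standard
#' deviation (converted to raw units internally).
#'
#' @param assets A `speechplan_assets`.
#' @param param One of `"kappa_a"`, `"kappa_s"`, `"eta_a"`, `"eta_s"`.
#' @param grid Increasing positive grid; defaults to a 6-point
#'   geometric series spanning the transition from fusion-like to
#'   single-modality planning (`kappa`: 1..32; `eta`: 0.018..5.6 corpus
#'   SDs).
#' @param baseline Unperturbed fusion result used as the compensation
#'   reference; computed internally when `NULL`.
#' @param phoneme,delta,chains,burn,keep,seed As in [run_condition()].
#' @return A long-format data.frame: `param`, `value` (raw units),
#'   `grid_value`, `ratio`, produced F1..F3 means.
#' @export
sweep_preference <- function(assets, param = c("kappa_a", "kappa_s",
                                               "eta_a", "eta_s"),
                             grid = NULL, baseline = NULL,
                             phoneme = "\u0254", delta = c(-100, 0, 0),
                             chains = 10L, burn = 500L, keep = 500L,
                             seed = 1L) {
  param <- match.arg(param)
  is_kappa <- startsWith(param, "kappa")
  if (is.null(grid)) {
    grid <- if (is_kappa) 2^(0:5) else 10^seq(-1.75, 0.75, length.out = 6)
  }
  scale <- if (grepl("_a$", param)) mean(assets$plant$scales$auditory_sd) else
    mean(assets$plant$scales$somato_sd)
  if (is.null(baseline)) {
    baseline <- run_condition(assets, "unperturbed", "fusion",
                              phoneme = phoneme, delta = delta,
                              chains = chains, burn = burn, keep = keep,
                              seed = seed)
  }
  rows <- lapply(grid, function(g) {
    prefs <- if (is_kappa) {
      preference_params("target_based",
                        kappa_a = if (param == "kappa_a") g else 1,
                        kappa_s = if (param == "kappa_s") g else 1)
    } else {
      preference_params("comparison_based",
                        eta_a = if (param == "eta_a") g * scale else 0,
                        eta_s = if (param == "eta_s") g * scale else 0)
    }
    res <- run_condition(assets, "post_adaptation", "fusion", prefs = prefs,
                         phoneme = phoneme, delta = delta, chains = chains,
                         burn = burn, keep = keep, seed = seed)
    data.frame(param = param, grid_value = g,
               value = if (is_kappa) g else g * scale,
               ratio = compensation_ratio(res, baseline, delta),
               f1 = res$produced_aud_mean[1],
               f2 = res$produced_aud_mean[2],
               f3 = res$produced_aud_mean[3])
  })
  do.call(rbind, rows)
}

#' Plot condition results as dispersion ellipses
#'
#' Order-2 dispersion ellipses of the perceived auditory outcomes in
#' the (F2, F1) plane (F1 increasing downward, the conventional vowel
#' orientation) and of the somatosensory outcomes in the (pc1, pc2)
#' plane, one panel per space, colored by planning mode and styled by
#' condition.
#'
#' @param results List of `compensation_result`s.
#' @param inventory Optional `phoneme_inventory`; when given, target
#'   regions are drawn as dashed 2-SD ellipses.
#' @param file Optional path; when given the figure is written there.
#' @return A list of two ggplot objects (`auditory`, `somato`).
#' @importFrom rlang .data
#' @export
render_figures <- function(results, inventory = NULL, file = NULL) {
  lay <- function(res, which) {
    el <- if (which == "aud") res$ellipse_aud else res$ellipse_som
    cbind(ellipse_path(el), mode = res$mode, condition = res$condition)
  }
  aud <- do.call(rbind, lapply(results, lay, which = "aud"))
  som <- do.call(rbind, lapply(results, lay, which = "som"))
  gauss_ellipse <- function(mu, Gamma, ix, iy) {
    e <- eigen(Gamma[c(ix, iy), c(ix, iy)], symmetric = TRUE)
    v <- e$vectors[, 1]
    ang <- atan2(v[2], v[1]) * 180 / pi
    ellipse_path(list(center = mu[c(ix, iy)], axes = 2 * sqrt(e$values),
                      angle = ang))
  }
  p_aud <- ggplot2::ggplot(aud, ggplot2::aes(x = .data$x, y = .data$y,
                                             colour = .data$mode,
                                             linetype = .data$condition)) +
    ggplot2::geom_path() +
    ggplot2::scale_y_reverse() + ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "F2 (Hz)", y = "F1 (Hz)", title = "Auditory outcomes") +
    ggplot2::theme_minimal()
  p_som <- ggplot2::ggplot(som, ggplot2::aes(x = .data$x, y = .data$y,
                                             colour = .data$mode,
                                             linetype = .data$condition)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "pc1", y = "pc2", title = "Somatosensory outcomes") +
    ggplot2::theme_minimal()
  if (!is.null(inventory)) {
    ph <- results[[1]]$phoneme
    tg <- inventory$targets[[ph]]
    ta <- gauss_ellipse(tg$mu_A[c(2, 1)], tg$Gamma_A[c(2, 1), c(2, 1)], 1, 2)
    p_aud <- p_aud + ggplot2::geom_path(data = cbind(ta, mode = "target",
                                                     condition = "target"),
                                        colour = "grey30", linetype = "dashed")
    ts <- gauss_ellipse(tg$mu_S, tg$Gamma_S, 1, 2)
    p_som <- p_som + ggplot2::geom_path(data = cbind(ts, mode = "target",
                                                     condition = "target"),
                                        colour = "grey30", linetype = "dashed")
  }
  if (!is.null(file)) {
    ggplot2::ggsave(file, p_aud, width = 6, height = 5)
  }
  list(auditory = p_aud, somato = p_som)
}

#' Plot a preference sweep
#'
#' Compensation ratio against the preference parameter (log scale),
#' with optional pure-mode reference ratios.
#'
#' @param sweep Data frame from [sweep_preference()].
#' @param ref Optional named numeric vector of reference ratios (e.g.
#'   `c(auditory = 1, somatosensory = 0)`) drawn as horizontal lines.
#' @return A ggplot object.
#' @export
render_sweep <- function(sweep, ref = NULL) {
  p <- ggplot2::ggplot(sweep, ggplot2::aes(x = .data$grid_value,
                                           y = .data$ratio)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = unique(sweep$param), y = "compensation ratio") +
    ggplot2::theme_minimal()
  if (!is.null(ref)) {
    p <- p + ggplot2::geom_hline(yintercept = unname(ref),
                                 linetype = "dotted", colour = "grey40")
  }
  p
}

#' @export
print.compensation_result <- function(x, ...) {
  cat(sprintf("<compensation_result> /%s/ %s, %s planning (preference: %s)\n",
              x$phoneme, x$condition, x$mode, x$prefs$mode))
  cat(sprintf("  produced F1-F3 mean: %s Hz\n",
              paste(round(x$produced_aud_mean, 1), collapse = ", ")))
  cat(sprintf("  perceived F1-F3 mean: %s Hz\n",
              paste(round(x$perceived_aud_mean, 1), collapse = ", ")))
  invisible(x)
}
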