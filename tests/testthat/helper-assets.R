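# Shared fixtures: one reduced-scale asset stack per test session, plus
# exactly-affine sensory maps used as closed-form oracles.

.test_cache <- new.env(parent = emptyenv())

# Reduced problem sizes keep the suite fast while leaving the internal
# models accurate enough for the planning properties to hold.
test_assets <- function() {
  if (is.null(.test_cache$assets)) {
    .test_cache$assets <- build_assets(
      seed = 1L, n_corpus = 20000L, n_centers = 600L, n_pca = 4000L,
      target_corpus = 8000L, target_draws = 4000L, target_chains = 8L,
      target_burn = 400L)
  }
  .test_cache$assets
}

# Planning runs for the reference vowel shared by several test files:
# unperturbed baselines and post-adaptation runs for each mode.
test_condition_runs <- function() {
  if (is.null(.test_cache$runs)) {
    assets <- test_assets()
    runs <- list()
    for (md in c("auditory", "somatosensory", "fusion")) {
      runs[[md]] <- list(
        base = run_condition(assets, "unperturbed", md, chains = 10L,
                             burn = 500L, keep = 500L, seed = 101L,
                             keep_samples = TRUE),
        post = run_condition(assets, "post_adaptation", md, chains = 10L,
                             burn = 500L, keep = 500L, seed = 101L,
                             keep_samples = TRUE))
    }
    .test_cache$runs <- runs
  }
  .test_cache$runs
}

# A sensory_map whose prediction is exactly W m + b (kernel weights 0).
affine_sensory_map <- function(W, b, modality) {
  structure(list(
    modality = modality,
    centers = matrix(0, 2, ncol(W)),
    bandwidth = 1,
    weights = rbind(b, t(W), matrix(0, 2, nrow(W))),
    adaptation_offset = rep(0, nrow(W)),
    rmse = rep(0, nrow(W)), rmse_rel = rep(0, nrow(W)),
    d = ncol(W)
  ), class = "sensory_map")
}

mahal2 <- function(x, mu, Gamma) {
  d <- sweep(as.matrix(x), 2, mu)
  rowSums((d %*% solve(Gamma)) * d)
}
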