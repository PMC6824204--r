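test_that("soft matching has the Gaussian kernel's exact shape and limits", {
  x <- c(1, 2, 3)
  expect_equal(soft_match_prob(x, x, 0.5), 1)
  eta <- 0.8
  y <- x + c(eta * sqrt(2 * log(2)), 0, 0)
  expect_equal(soft_match_prob(x, y, eta), 0.5, tolerance = 1e-12)
  # eta -> Inf removes the constraint entirely
  expect_equal(soft_match_prob(x, x + 10, 1e9), 1, tolerance = 1e-12)
  expect_identical(soft_match_prob(x, y, eta), soft_match_prob(y, x, eta))
  expect_gt(soft_match_prob(x, x + 0.1, eta), soft_match_prob(x, x + 0.2, eta))
})

test_that("effective covariances implement the two preference mechanisms", {
  G <- matrix(c(4, 0, 0, 0, 1, 0, 0, 0, 1), 3)
  none <- preference_params("none")
  expect_identical(effective_covariance(G, none, "auditory"), G)

  tb <- preference_params("target_based", kappa_a = 3, kappa_s = 5)
  expect_equal(effective_covariance(G, tb, "auditory"), 3 * G)
  expect_equal(effective_covariance(G, tb, "somatosensory"), 5 * G)

  cb <- preference_params("comparison_based", eta_a = sqrt(3))
  expect_equal(effective_covariance(G, cb, "auditory"), diag(c(7, 4, 4)))
  expect_equal(effective_covariance(G, cb, "somatosensory"), G)  # eta_s = 0

  expect_error(effective_covariance(diag(c(-1, 1, 1)), none, "auditory"),
               "positive-definite")
  expect_error(preference_params("target_based", kappa_a = 0))
  # mode none forces neutral parameters
  forced <- preference_params("none", kappa_a = 7, eta_s = 2)
  expect_equal(forced$kappa_a, 1)
  expect_equal(forced$eta_s, 0)
})

test_that("additive inflation keeps eigenvectors but erodes anisotropy", {
  set.seed(11)
  A <- matrix(rnorm(9), 3)
  G <- crossprod(A) + diag(3) * 0.1
  ev_G <- eigen(G, symmetric = TRUE)
  ev_I <- eigen(G + 2^2 * diag(3), symmetric = TRUE)
  # same eigenvectors (up to sign), eigenvalues shifted by eta^2
  expect_equal(abs(diag(crossprod(ev_G$vectors, ev_I$vectors))), rep(1, 3),
               tolerance = 1e-8)
  expect_equal(ev_I$values, ev_G$values + 4, tolerance = 1e-8)

  expect_equal(anisotropy(diag(3))$condition, 1)
  expect_equal(anisotropy(5 * G)$condition, anisotropy(G)$condition)
  etas <- c(0, 0.5, 1, 2, 5, 20)
  conds <- vapply(etas, function(e) anisotropy(G + e^2 * diag(3))$condition,
                  numeric(1))
  expect_true(all(diff(conds) < 0))
  expect_lt(conds[length(conds)] - 1, 0.05)
})

test_that("the 1-D correspondence kappa = 1 + eta^2/Gamma is exact", {
  expect_equal(kappa_equivalent_1d(1, 1), 2)
  expect_equal(kappa_equivalent_1d(4, 0), 1)
  expect_error(kappa_equivalent_1d(0, 1), "positive")

  Gam <- 2.3; eta <- 0.7; mu <- 0.4
  kap <- kappa_equivalent_1d(Gam, eta)
  x <- seq(-8, 8, length.out = 2001)
  d1 <- dnorm(x, mu, sqrt(Gam + eta^2))
  d2 <- dnorm(x, mu, sqrt(kap * Gam))
  expect_lt(max(abs(d1 - d2)), 1e-12)
})

test_that("in 3-D the two mechanisms differ for anisotropic regions", {
  G <- diag(c(9, 1, 1))
  eta <- 2
  kap <- 1 + eta^2 / G[1, 1]  # any scalar choice
  add <- G + eta^2 * diag(3)
  mult <- kap * G
  expect_gt(max(abs(add - mult)), 1)
  # but for isotropic G they coincide
  Gi <- 2 * diag(3)
  expect_equal(Gi + eta^2 * diag(3), (1 + eta^2 / 2) * Gi, tolerance = 1e-12)
})

test_that("vanishing soft-match width recovers the unpreferenced densities", {
  assets <- test_assets()
  scale_a <- mean(assets$plant$scales$auditory_sd)
  scale_s <- mean(assets$plant$scales$somato_sd)
  q0 <- planning_query("a", assets$inventory, assets$maps, TRUE, TRUE,
                       preference_params("none"))
  sup_dev <- function(frac) {
    prefs <- preference_params("comparison_based",
                               eta_a = frac * scale_a, eta_s = frac * scale_s)
    q1 <- planning_query("a", assets$inventory, assets$maps, TRUE, TRUE, prefs)
    set.seed(13)
    max(vapply(1:50, function(i) {
      m <- runif(6, -1, 1)
      abs(log_posterior(m, q0) - log_posterior(m, q1))
    }, numeric(1)))
  }
  # the sup-norm shrinks like eta^2, vanishing in the limit; even deep in
  # the Gaussian tails (quadratic forms of order 1e3) it is already tiny
  # at eta = 1e-3 of the sensory scale
  d3 <- sup_dev(1e-3)
  d5 <- sup_dev(1e-5)
  expect_lt(d3, 0.05)
  expect_lt(d5, 1e-5)
  expect_lt(d5, d3 / 100)
})

test_that("an extreme auditory preference shuts the auditory pathway off", {
  assets <- test_assets()
  scale_a <- mean(assets$plant$scales$auditory_sd)
  huge <- preference_params("comparison_based", eta_a = 1e3 * scale_a)
  qf <- planning_query("\u0254", assets$inventory, assets$maps, TRUE, TRUE, huge)
  qs <- planning_query("\u0254", assets$inventory, assets$maps, FALSE, TRUE)
  sample_q <- function(q) mcmc_sample(q, chains = 6, burn = 400, keep = 500,
                                      seed = 19)$draws
  df <- sample_q(qf); ds <- sample_q(qs)
  for (j in 1:6) {
    ks <- suppressWarnings(stats::ks.test(df[, j], ds[, j]))$statistic
    expect_lt(unname(ks), 0.05)
  }
})
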