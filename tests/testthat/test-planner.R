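test_that("fusion log density factorizes into the two single-modality terms", {
  assets <- test_assets()
  qf <- planning_query("a", assets$inventory, assets$maps, TRUE, TRUE)
  qa <- planning_query("a", assets$inventory, assets$maps, TRUE, FALSE)
  qs <- planning_query("a", assets$inventory, assets$maps, FALSE, TRUE)
  set.seed(6)
  for (i in 1:100) {
    m <- runif(6, -1, 1)
    expect_lt(abs(log_posterior(m, qf) -
                    (log_posterior(m, qa) + log_posterior(m, qs))), 1e-12)
  }
})

test_that("auditory-only planning ignores the somatosensory map entirely", {
  assets <- test_assets()
  other <- assets$maps
  other$somato$weights <- 2 * other$somato$weights
  qa1 <- planning_query("e", assets$inventory, assets$maps, TRUE, FALSE)
  qa2 <- planning_query("e", assets$inventory, other, TRUE, FALSE)
  set.seed(7)
  for (i in 1:20) {
    m <- runif(6, -1, 1)
    expect_identical(log_posterior(m, qa1), log_posterior(m, qa2))
  }
})

test_that("a query with both coherence flags off is rejected", {
  assets <- test_assets()
  expect_error(planning_query("a", assets$inventory, assets$maps, FALSE, FALSE),
               "uniform prior")
  expect_error(planning_query("zz", assets$inventory, assets$maps), "unknown phoneme")
})

test_that("strict matching is an all-or-nothing switch and the eta->0 limit", {
  x <- c(1, 2, 3)
  expect_identical(strict_match(x, x), 1L)
  expect_identical(strict_match(x, x + c(1e-9, 0, 0)), 0L)
  expect_equal(soft_match_prob(x, x + c(0.1, 0, 0), 1e-12), 0)
})

test_that("the sampler recovers a known 2-D Gaussian", {
  logf <- function(m) -0.5 * sum(m^2)
  ps <- mh_sample(logf, c(-6, -6), c(6, 6), chains = 10, burn = 500,
                  keep = 2000, seed = 12)
  cm <- apply(ps$draws, 2, function(col) tapply(col, ps$chain, mean))
  se <- apply(cm, 2, sd) / sqrt(10)
  expect_true(all(abs(colMeans(ps$draws)) <= 3 * se))
  S <- cov(ps$draws)
  expect_equal(diag(S), c(1, 1), tolerance = 0.05)
  expect_lt(abs(S[1, 2]), 0.05)
})

test_that("sampling is bit-reproducible and respects bounds and counts", {
  logf <- function(m) -0.5 * sum((m - 0.2)^2) / 0.1
  p1 <- mh_sample(logf, rep(-1, 3), rep(1, 3), chains = 4, burn = 100,
                  keep = 150, seed = 77)
  p2 <- mh_sample(logf, rep(-1, 3), rep(1, 3), chains = 4, burn = 100,
                  keep = 150, seed = 77)
  expect_identical(p1$draws, p2$draws)
  expect_equal(nrow(p1$draws), 4L * 150L)
  expect_true(all(p1$draws >= -1 & p1$draws <= 1))
  # the default protocol retains 20 chains x 1000 draws
  f <- formals(mcmc_sample)
  expect_equal(eval(f$chains) * eval(f$keep), 2e4)
  expect_equal(eval(f$burn), 1000L)
})

test_that("MCMC marginals match an exhaustive grid normalization in 2-D", {
  rho <- function(m) c(tanh(1.3 * m[1] + 0.4 * m[2]),
                       tanh(0.5 * m[1] - 1.1 * m[2]) + 0.3 * m[1]^2)
  mu <- c(0.3, -0.2)
  P <- solve(matrix(c(0.04, 0.01, 0.01, 0.09), 2))
  logf <- function(m) { r <- rho(m) - mu; -0.5 * sum(r * (P %*% r)) }
  gm <- grid_marginals(logf, c(-1, -1), c(1, 1), 201)
  ps <- mh_sample(logf, c(-1, -1), c(1, 1), chains = 20, burn = 1000,
                  keep = 1000, seed = 33)
  expect_lt(max(ks_to_grid(ps$draws, gm)), 0.05)
})

test_that("comparison-based fusion equals the explicit Gaussian convolution", {
  assets <- test_assets()
  tg <- assets$inventory$targets[["e"]]
  eta_a <- 35; eta_s <- 0.4
  prefs <- preference_params("comparison_based", eta_a = eta_a, eta_s = eta_s)
  q <- planning_query("e", assets$inventory, assets$maps, TRUE, TRUE, prefs)

  conv_quad <- function(mu, Gamma, center, eta) {
    # midpoint-rule integral of N(a; mu, Gamma) N(a; center, eta^2 I)
    sds <- sqrt(diag(Gamma))
    axes <- lapply(1:3, function(i) {
      lim <- 6 * sqrt(sds[i]^2 + eta^2)
      mid <- (mu[i] + center[i]) / 2
      seq(mid - lim, mid + lim, length.out = 51)
    })
    grid <- as.matrix(expand.grid(axes))
    h <- prod(vapply(axes, function(a) diff(a)[1], numeric(1)))
    v1 <- logdmvnorm(grid, mu, Gamma)
    v2 <- logdmvnorm(grid, center, eta^2 * diag(3))
    sum(exp(v1 + v2)) * h
  }

  set.seed(9)
  for (i in 1:20) {
    m <- runif(6, -0.5, 0.5)
    pa <- as.numeric(predict(assets$maps$auditory, m))
    psm <- as.numeric(predict(assets$maps$somato, m))
    expected <- log(conv_quad(tg$mu_A, tg$Gamma_A, pa, eta_a)) +
      log(conv_quad(tg$mu_S, tg$Gamma_S, psm, eta_s))
    expect_equal(log_posterior(m, q), expected, tolerance = 1e-4)
  }
})

test_that("every phoneme and planning mode reaches both goal regions unperturbed", {
  assets <- test_assets()
  for (ph in names(assets$inventory$targets)) {
    tg <- assets$inventory$targets[[ph]]
    for (md in c("auditory", "somatosensory", "fusion")) {
      r <- run_condition(assets, "unperturbed", md, phoneme = ph, chains = 6,
                         burn = 300, keep = 300, seed = 5, keep_samples = TRUE)
      cov_aud <- mean(mahal2(plant_auditory(r$samples$draws, assets$plant),
                             tg$mu_A, tg$Gamma_A) <= 9)
      cov_som <- mean(mahal2(plant_somato(r$samples$draws, assets$plant),
                             tg$mu_S, tg$Gamma_S) <= 9)
      expect_gte(cov_aud, 0.90)
      expect_gte(cov_som, 0.90)
    }
  }
})

test_that("dispersion ellipses summarize 2-D clouds correctly", {
  th <- seq(0, 2 * pi, length.out = 721)[-1]
  circ <- cbind(cos(th), sin(th))
  el <- dispersion_ellipse(circ, order = 2)
  expect_equal(el$axes, rep(2 * sqrt(0.5), 2), tolerance = 1e-2)
  expect_equal(el$center, c(0, 0), tolerance = 1e-10)

  shifted <- dispersion_ellipse(sweep(circ, 2, c(3, -4), "+"), order = 2)
  expect_equal(shifted$center, c(3, -4), tolerance = 1e-10)
  expect_equal(shifted$axes, el$axes)

  set.seed(2)
  iso <- matrix(rnorm(4000), 2000, 2)
  el_iso <- dispersion_ellipse(iso, order = 2)
  expect_lt(el_iso$axes[1] / el_iso$axes[2], 1.15)

  expect_error(dispersion_ellipse(cbind(1:5, 2 * (1:5))), "degenerate|collinear")
})
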