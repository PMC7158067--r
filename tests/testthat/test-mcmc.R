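test_that("RW1 log-density matches hand sums and the increment-form oracle", {
  expect_equal(rw1_log_density(c(2, 2, 2), 1) - rw1_log_density(c(0, 0, 0), 1),
               0)
  # penalty for (0,1,0) at tau = 1 is -(1/2)(1 + 1) = -1 beyond the constant
  expect_equal(rw1_log_density(c(0, 1, 0), 1) - rw1_log_density(c(0, 0, 0), 1),
               -1)
  set.seed(1)
  for (i in 1:10) {
    g <- rnorm(sample(2:12, 1))
    tau <- rexp(1) + 0.1
    expect_equal(rw1_log_density(g, tau),
                 sum(dnorm(diff(g), 0, 1 / sqrt(tau), log = TRUE)))
  }
  expect_error(rw1_log_density(c(1), 1), "length")
  expect_error(rw1_log_density(c(1, 2), -1), "positive")
})

test_that("Poisson panel log-likelihood matches closed forms and dpois", {
  p0 <- count_panel(matrix(0, 3, 2), matrix(1.5, 3, 2))
  expect_equal(poisson_loglik(p0, matrix(0, 3, 2)), -sum(p0$E))
  p1 <- count_panel(matrix(2, 1, 1), matrix(1, 1, 1))
  expect_equal(poisson_loglik(p1, matrix(0, 1, 1)), -1 - log(2))
  set.seed(2)
  for (i in 1:10) {
    n <- sample(2:6, 1); Tt <- sample(2:5, 1)
    E <- matrix(runif(n * Tt, 0.5, 20), n, Tt)
    lr <- matrix(rnorm(n * Tt, 0, 0.4), n, Tt)
    y <- matrix(rpois(n * Tt, E * exp(lr)), n, Tt)
    pan <- count_panel(y, E)
    expect_equal(poisson_loglik(pan, lr),
                 sum(dpois(y, E * exp(lr), log = TRUE)), tolerance = 1e-10)
  }
  expect_error(poisson_loglik(p1, matrix(0, 2, 2)), "shape")
})

test_that("chains are deterministic in the seed and thinning halves storage", {
  scen <- small_scenario(2)
  f1 <- fit_dm(scen$panel, scen$graph, micro_cfg(seed = 9, n_chains = 1))
  f2 <- fit_dm(scen$panel, scen$graph, micro_cfg(seed = 9, n_chains = 1))
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_dm(scen$panel, scen$graph, micro_cfg(seed = 10, n_chains = 1))
  expect_false(identical(f1$draws$alpha, f3$draws$alpha))

  f6 <- fit_dm(scen$panel, scen$graph,
               micro_cfg(seed = 9, n_chains = 1, thin = 6))
  expect_equal(nrow(f6$draws$alpha) * 2L, nrow(f1$draws$alpha))
  # caches stay coherent with a fresh recomputation all along the chain
  expect_lt(f1$audit, 1e-8)
})

test_that("the sampler's log-posterior equals likelihood plus priors built from public pieces", {
  scen <- small_scenario(4)
  cfg <- micro_cfg()
  st <- stsurveil:::.model_dm$init(scen$panel, scen$graph, cfg, list())
  for (i in 1:25) stsurveil:::.model_dm$sweep(st)
  lp <- stsurveil:::.model_dm$log_posterior(st)
  manual <- poisson_loglik(scen$panel, st$eta) -
    st$tau_theta / 2 * icar_quadratic_form(st$theta, scen$graph) +
    st$rankL / 2 * log(st$tau_theta) +
    sum(dnorm(st$phi, 0, 1 / sqrt(st$tau_phi), log = TRUE)) +
    rw1_log_density(st$gamma, st$tau_gamma) +
    sum(dnorm(st$psi, 0, 1 / sqrt(st$tau_psi), log = TRUE)) +
    sum(dgamma(c(st$tau_theta, st$tau_phi, st$tau_gamma, st$tau_psi),
               1, rate = 0.01, log = TRUE))
  expect_equal(lp, manual, tolerance = 1e-8)
})

test_that("conjugate precision Gibbs agrees with a Metropolis cross-check", {
  cfg <- scenario_config(n_areas = 16, n_times = 6, n_unusual = 0,
                         sd_spatial = 0.1, sd_temporal = 0.1,
                         sd_unstructured = 0.05, sd_interaction = 0.3,
                         expected_range = c(30, 30))
  scen <- make_scenario1(6, config = cfg,
                         graph = build_lattice_graph(4, 4))
  run <- function(how) fit_dm(scen$panel, scen$graph,
                              micro_cfg(seed = 2, n_iterations = 4000,
                                        burn_in = 1500, thin = 5),
                              opts = list(tau_update = how))
  tg <- mean(run("gibbs")$draws$tau_psi)
  tm <- mean(run("mh")$draws$tau_psi)
  expect_lt(abs(log(tg) - log(tm)), 0.3)
})

test_that("spatial field recovery: posterior theta tracks the truth", {
  cfg <- scenario_config(n_areas = 100, n_times = 15, n_unusual = 0,
                         sd_spatial = 0.3, sd_temporal = 0.1,
                         sd_unstructured = 0.05, sd_interaction = 0.02,
                         expected_range = c(50, 50))
  g <- build_lattice_graph(10, 10)
  base <- generate_baseline(cfg, g, seed = 11)
  panel <- sample_counts(base, matrix(50, 100, 15), seed = 12)
  fit <- fit_dm(panel, g, mcmc_config(n_iterations = 3000, burn_in = 1500,
                                      thin = 5, n_chains = 2, seed = 3))
  theta_hat <- colMeans(fit$draws$theta)
  expect_gt(cor(theta_hat, base$theta), 0.7)
})

test_that("potential scale reduction behaves on known inputs", {
  mk <- function(ch1, ch2) {
    stsurveil:::new_posterior_samples(
      "dm", list(x = matrix(c(ch1, ch2), ncol = 1)),
      chain = rep(1:2, each = length(ch1)),
      acceptance = NULL, audit = 0, cfg = NULL, dims = NULL)
  }
  expect_equal(unname(gelman_rubin(mk(c(1, 2, 3), c(1, 2, 3)))["x"]), 1)
  expect_gt(unname(gelman_rubin(mk(rep(1, 4), rep(5, 4)))["x"]), 100)
  # hand-computed two-chain example: chains (1,2) and (3,4):
  # W = 0.5, B = 4, varhat = 0.25 + 2 = 2.25, psrf = sqrt(4.5)
  expect_equal(unname(gelman_rubin(mk(c(1, 2), c(3, 4)))["x"]), sqrt(4.5))
  one <- stsurveil:::new_posterior_samples(
    "dm", list(x = matrix(1:4, ncol = 1)), chain = rep(1L, 4),
    acceptance = NULL, audit = 0, cfg = NULL, dims = NULL)
  expect_error(gelman_rubin(one), "2 chains")
})

test_that("draw containers enforce their invariants", {
  expect_error(stsurveil:::new_posterior_samples(
    "dm", list(a = matrix(1, 2, 1), b = matrix(1, 3, 1)),
    chain = 1:2, acceptance = NULL, audit = 0, cfg = NULL, dims = NULL),
    "draw count")
  expect_error(stsurveil:::new_posterior_samples(
    "dm", list(tau_x = matrix(c(1, -1), 2, 1)),
    chain = 1:2, acceptance = NULL, audit = 0, cfg = NULL, dims = NULL),
    "positive")
  expect_error(stsurveil:::new_posterior_samples(
    "dm", list(z = matrix(c(0, 2), 2, 1)),
    chain = 1:2, acceptance = NULL, audit = 0, cfg = NULL, dims = NULL),
    "0/1")
  expect_error(mcmc_config(n_iterations = 100, burn_in = 100), "burn_in")
  expect_error(mcmc_config(thin = 0), "thin")
})
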