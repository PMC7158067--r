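# Model behaviour on small planted-truth datasets. MCMC settings here are
# deliberately short; assertions are coarse recovery/shrinkage properties,
# not sharp posterior quantities.

test_that("DM shrinks the interaction on null data and finds a planted area effect", {
  cfg <- scenario_config(n_areas = 36, n_times = 8, n_unusual = 0,
                         sd_spatial = 0, sd_temporal = 0,
                         sd_unstructured = 0, sd_interaction = 0,
                         expected_range = c(100, 100))
  g <- build_lattice_graph(6, 6)
  base <- generate_baseline(cfg, g, seed = 1)
  panel <- sample_counts(base, matrix(100, 36, 8), seed = 2)
  fit <- fit_dm(panel, g, micro_cfg(seed = 1))
  psi_hat <- matrix(colMeans(fit$draws$psi), 36, 8)
  expect_lt(mean(abs(psi_hat)), 0.05)
  expect_lt(max(abs(psi_hat)), 0.25)

  y4 <- panel$y
  y4[7, ] <- y4[7, ] * 4
  fit4 <- fit_dm(count_panel(y4, panel$E), g, micro_cfg(seed = 2))
  lvl <- colMeans(fit4$draws$theta) + colMeans(fit4$draws$phi)
  expect_equal(which.max(lvl), 7L)
})

test_that("DM exceedance probabilities are monotone in planted signal size", {
  cfg <- scenario_config(n_areas = 30, n_times = 10, n_unusual = 0,
                         sd_spatial = 0, sd_temporal = 0,
                         sd_unstructured = 0, sd_interaction = 0.05,
                         expected_range = c(50, 50))
  g <- build_random_planar_graph(30, 5)
  base <- generate_baseline(cfg, g, seed = 3)
  sizes <- c(0.25, 0.55, 0.9)
  groups <- list(1:3, 11:13, 21:23)
  psi <- base$psi
  for (k in 1:3) psi[groups[[k]], c(3, 7)] <- psi[groups[[k]], c(3, 7)] + sizes[k]
  surf <- stsurveil:::new_latent_surface(base$alpha, base$theta, base$phi,
                                         base$gamma, psi)
  panel <- sample_counts(surf, matrix(50, 30, 10), seed = 4)
  fit <- fit_dm(panel, g, micro_cfg(seed = 3))
  exc <- interaction_exceedance(fit)
  expect_true(all(exc >= 0 & exc <= 1))
  grp_score <- vapply(groups, function(ix) mean(apply(exc[ix, ], 1, max)), 0)
  expect_true(all(diff(grp_score) > 0))
  expect_gt(grp_score[3], mean(apply(exc[5:10, ], 1, max)))
})

test_that("STmix keeps the variance ordering and classifies planted interactions", {
  scen <- small_scenario(8, small_config(expected_range = c(60, 60)))
  fit <- fit_stmix(scen$panel, scen$graph, micro_cfg(seed = 4))
  expect_true(all(fit$draws$sigma2 >= fit$draws$sigma1))
  expect_true(all(fit$draws$p > 0 & fit$draws$p < 1))
  exc <- interaction_exceedance(fit)
  up_cells <- cbind(rep(scen$truth$unusual_areas, 2),
                    rep(scen$config$up_times,
                        each = length(scen$truth$unusual_areas)))
  common <- setdiff(seq_len(scen$panel$n_areas), scen$truth$unusual_areas)
  expect_gt(mean(exc[up_cells]), mean(exc[common, ]))
})

test_that("STmix concentrates the weight on the small component for homogeneous data", {
  cfg <- scenario_config(n_areas = 25, n_times = 8, n_unusual = 0,
                         sd_spatial = 0.1, sd_temporal = 0.1,
                         sd_unstructured = 0.03, sd_interaction = 0.04,
                         expected_range = c(40, 40))
  g <- build_lattice_graph(5, 5)
  base <- generate_baseline(cfg, g, seed = 9)
  panel <- sample_counts(base, matrix(40, 25, 8), seed = 10)
  fit <- fit_stmix(panel, g, micro_cfg(seed = 5))
  expect_gt(mean(fit$draws$p), 0.7)
})

test_that("DM and STmix agree on homogeneous interactions", {
  cfg <- scenario_config(n_areas = 25, n_times = 8, n_unusual = 0,
                         sd_spatial = 0.15, sd_temporal = 0.1,
                         sd_unstructured = 0.05, sd_interaction = 0.04,
                         expected_range = c(40, 40))
  g <- build_lattice_graph(5, 5)
  base <- generate_baseline(cfg, g, seed = 12)
  panel <- sample_counts(base, matrix(40, 25, 8), seed = 13)
  mc <- micro_cfg(seed = 6, n_iterations = 2000, burn_in = 1000)
  fd <- fit_dm(panel, g, mc)
  fs <- fit_stmix(panel, g, mc)
  fitted <- function(f) {
    matrix(colMeans(risk_exceedance(f)), 25, 8)  # exceedance summary
  }
  eta_d <- colMeans(fd$draws$psi) + rep(colMeans(fd$draws$theta) +
                                          colMeans(fd$draws$phi), 8)
  eta_s <- colMeans(fs$draws$psi) + rep(colMeans(fs$draws$theta) +
                                          colMeans(fs$draws$phi), 8)
  expect_gt(cor(eta_d, eta_s), 0.9)
  expect_lt(mean(abs(eta_d - eta_s)), 0.05)
})

test_that("FlexDetect trusts the common model on common-generated data", {
  cfg <- scenario_config(n_areas = 30, n_times = 10, n_unusual = 0,
                         sd_spatial = 0.2, sd_temporal = 0.15,
                         sd_unstructured = 0, sd_interaction = 0,
                         expected_range = c(40, 40))
  g <- build_random_planar_graph(30, 7)
  base <- generate_baseline(cfg, g, seed = 14)
  panel <- sample_counts(base, matrix(40, 30, 10), seed = 15)
  fit <- fit_flexdetect(panel, g, micro_cfg(seed = 7, n_iterations = 2000,
                                            burn_in = 1000))
  pm <- model_probabilities(fit)
  expect_true(all(pm >= 0 & pm <= 1))
  expect_gt(median(pm), 0.9)
  # the z-selected likelihood audit stays exact
  expect_lt(fit$audit, 1e-7)
})

test_that("FlexDetect separates planted areas from common ones on scenario data", {
  cfg <- small_config(n_areas = 40, n_times = 12, n_unusual = 4,
                      expected_range = c(40, 40))
  scen <- make_scenario1(16, config = cfg)
  fit <- fit_flexdetect(scen$panel, scen$graph,
                        micro_cfg(seed = 8, n_iterations = 2000,
                                  burn_in = 1000))
  pm <- model_probabilities(fit)
  plant <- scen$truth$unusual_areas
  expect_lt(mean(pm[plant]), mean(pm[-plant]))
})

test_that("model fits fail loudly on inconsistent inputs", {
  scen <- small_scenario(2)
  wrong <- build_lattice_graph(2, 3)
  expect_error(fit_dm(scen$panel, wrong, micro_cfg()), "disagree")
  expect_error(run_chain("nope", scen$panel, scen$graph, micro_cfg()),
               "unknown model")
})
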