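test_that("degenerate scales give a constant surface; seeds are reproducible", {
  cfg <- scenario_config(n_areas = 9, n_times = 5, n_unusual = 2,
                         alpha0 = 0.3, sd_spatial = 0, sd_temporal = 0,
                         sd_unstructured = 0, sd_interaction = 0)
  g <- build_lattice_graph(3, 3)
  s <- generate_baseline(cfg, g, seed = 5)
  expect_true(all(s$log_rr == 0.3))

  cfg2 <- scenario_config(n_areas = 9, n_times = 5, n_unusual = 2)
  s1 <- generate_baseline(cfg2, g, seed = 7)
  s2 <- generate_baseline(cfg2, g, seed = 7)
  expect_identical(s1$log_rr, s2$log_rr)
  s3 <- generate_baseline(cfg2, g, seed = 8)
  expect_false(identical(s1$log_rr, s3$log_rr))
  # structured components are gauge-fixed to sum to zero
  expect_equal(sum(s1$theta), 0, tolerance = 1e-10)
  expect_equal(sum(s1$gamma), 0, tolerance = 1e-10)
  expect_equal(s1$log_rr,
               s1$alpha + outer(s1$theta + s1$phi, rep(1, 5)) +
                 outer(rep(1, 9), s1$gamma) + s1$psi)
})

test_that("random-walk trend increments have the configured variance", {
  set.seed(3)
  incs <- replicate(1000, diff(stsurveil:::r_rw1(10, 0.15)))
  v <- var(as.vector(incs))
  se <- 0.15^2 * sqrt(2 / length(incs))
  expect_lt(abs(v - 0.15^2), 4 * se)
})

test_that("signal injection doubles/halves risk at the scheduled times only", {
  cfg <- small_config()
  g <- build_random_planar_graph(cfg$n_areas, 2)
  base <- generate_baseline(cfg, g, seed = 2)
  sig <- inject_signals(base, cfg, seed = 3)
  u <- sig$truth$unusual_areas[1]
  expect_length(sig$truth$unusual_areas, cfg$n_unusual)
  expect_equal(exp(sig$surface$log_rr[u, 3] - base$log_rr[u, 3]), 2)
  expect_equal(exp(sig$surface$log_rr[u, 4] - base$log_rr[u, 4]), 0.5)
  common <- setdiff(seq_len(cfg$n_areas), sig$truth$unusual_areas)
  expect_true(all(sig$truth$per_unit_offset[common, ] == 0))
  unsched <- setdiff(seq_len(cfg$n_times), c(cfg$up_times, cfg$down_times))
  expect_true(all(sig$truth$per_unit_offset[, unsched] == 0))
  # zero magnitude: areas still labelled but the data are null
  cfg0 <- small_config(signal_magnitude = 0)
  sig0 <- inject_signals(base, cfg0, seed = 3)
  expect_length(sig0$truth$unusual_areas, cfg0$n_unusual)
  expect_true(all(sig0$truth$per_unit_offset == 0))
  expect_identical(sig0$surface$log_rr, base$log_rr)
})

test_that("sampled counts behave like Poisson draws", {
  cfg <- scenario_config(n_areas = 5, n_times = 3, n_unusual = 0,
                         sd_spatial = 0, sd_temporal = 0,
                         sd_unstructured = 0, sd_interaction = 0)
  g <- build_lattice_graph(1, 5)
  s <- generate_baseline(cfg, g, seed = 1)
  E <- matrix(10, 5, 3)
  ys <- vapply(1:8000, function(i) sample_counts(s, E, seed = i)$y[1, 1], 0)
  expect_lt(abs(mean(ys) - 10), 3 * sqrt(10 / length(ys)))
  # variance tracks the mean (equidispersion)
  expect_lt(abs(var(ys) / mean(ys) - 1), 0.1)
  # vanishing expected counts give all-zero panels
  tiny <- sample_counts(s, matrix(1e-8, 5, 3), seed = 1)
  expect_true(all(tiny$y == 0))
  expect_error(sample_counts(s, matrix(0, 5, 3), seed = 1), "positive")
})

test_that("flagged-area counts at up-times average twice their baseline", {
  cfg <- small_config(expected_range = c(40, 40))
  g <- build_random_planar_graph(cfg$n_areas, 4)
  base <- generate_baseline(cfg, g, seed = 4)
  sig <- inject_signals(base, cfg, seed = 5)
  E <- matrix(40, cfg$n_areas, cfg$n_times)
  mu0 <- E * exp(base$log_rr)           # expectation without the signal
  up <- as.matrix(expand.grid(sig$truth$unusual_areas, cfg$up_times))
  ratios <- vapply(1:300, function(i) {
    y <- sample_counts(sig$surface, E, seed = 1000 + i)$y
    mean(y[up] / mu0[up])
  }, 0)
  expect_lt(abs(mean(ratios) - 2), 0.05)
})

test_that("benchmark replicates have the documented shape and vary by seed", {
  scen <- make_scenario1(1)
  expect_equal(dim(scen$panel$y), c(211L, 15L))
  expect_length(scen$truth$unusual_areas, 15L)
  sched <- scen$truth$signal_schedule
  expect_equal(which(sched != 0), c(3L, 6L, 10L, 12L, 15L),
               ignore_attr = TRUE)
  expect_equal(unname(sched[c(3, 10)]), rep(log(2), 2))
  expect_equal(unname(sched[c(6, 12, 15)]), rep(-log(2), 3))
  expect_true(all(scen$panel$E >= 20 & scen$panel$E <= 60))
  # E is drawn once per area and held constant over time
  expect_equal(scen$panel$E, scen$panel$E[, c(1, 1:14)], ignore_attr = TRUE)

  g <- scen$graph
  keys <- vapply(1:50, function(s) {
    sc <- make_scenario1(s, graph = g)
    paste(sum(sc$panel$y), paste(sc$truth$unusual_areas, collapse = ","))
  }, "")
  expect_equal(length(unique(keys)), 50L)
})

test_that("scenario configurations round-trip through YAML", {
  skip_if_not_installed("yaml")
  cfg <- small_config(n_areas = 31L)
  f <- tempfile(fileext = ".yml")
  write_scenario_config(cfg, f)
  cfg2 <- read_scenario_config(f)
  expect_equal(unclass(cfg2), unclass(cfg))
  writeLines("bogus_key: 1", f)
  expect_error(read_scenario_config(f), "unknown config keys")
})

test_that("panels and truth labels round-trip through CSV", {
  scen <- small_scenario(3)
  f <- tempfile(fileext = ".csv")
  write_count_panel(scen$panel, f)
  p2 <- read_count_panel(f)
  expect_equal(p2$y, scen$panel$y, ignore_attr = TRUE)
  expect_equal(p2$E, scen$panel$E, tolerance = 1e-12, ignore_attr = TRUE)

  ft <- tempfile(fileext = ".csv")
  write_scenario_truth(scen$truth, ft)
  t2 <- read_scenario_truth(ft)
  expect_equal(t2$unusual_areas, scen$truth$unusual_areas)
  expect_equal(t2$per_unit_offset, scen$truth$per_unit_offset,
               tolerance = 1e-12)
})
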