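test_that("confusion counts partition the areas and match hand cases", {
  truth <- structure(list(unusual_areas = c(2L, 5L),
                          signal_schedule = stats::setNames(numeric(4), 1:4),
                          per_unit_offset = matrix(0, 6, 4),
                          n_areas = 6L, n_times = 4L),
                     class = "scenario_truth")
  exact <- confusion_counts(c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE), truth)
  expect_equal(unlist(exact), c(TP = 2L, FP = 0L, TN = 4L, FN = 0L))
  none <- confusion_counts(rep(FALSE, 6), truth)
  expect_equal(unlist(none), c(TP = 0L, FP = 0L, TN = 4L, FN = 2L))
  set.seed(5)
  for (i in 1:10) {
    fl <- runif(6) > 0.5
    cc <- confusion_counts(fl, truth)
    expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 6L)
  }
  expect_error(confusion_counts(c(TRUE, FALSE), truth), "length")
})

test_that("metrics follow their formulas with the 0/0-gives-0 convention", {
  cc <- function(TP, FP, TN, FN)
    structure(list(TP = TP, FP = FP, TN = TN, FN = FN),
              class = "confusion_counts")
  m <- performance_metrics(cc(3, 1, 10, 2))
  expect_equal(unname(m["sensitivity"]), 0.6)
  expect_equal(unname(m["fdr"]), 0.25)
  expect_equal(unname(m["specificity"]), 10 / 11)
  expect_equal(unname(m["for"]), 2 / 12)
  empty <- performance_metrics(cc(0, 0, 10, 0))
  expect_equal(unname(empty["fdr"]), 0)
  expect_equal(unname(empty["sensitivity"]), 0)
  expect_true(all(m >= 0 & m <= 1))
})

test_that("the replicate benchmark emits a full table and reproduces bit-identically", {
  cfg <- small_config(n_areas = 20L, n_times = 8L, n_unusual = 3L)
  mc <- micro_cfg(n_chains = 1L, n_iterations = 700L, burn_in = 350L,
                  thin = 5L)
  res <- run_study(config = cfg, n_replicates = 2L, cfg = mc, seed = 31L)
  expect_s3_class(res, "study_result")
  expect_equal(res$table$rule, c("DM1", "DM2", "STmix1", "STmix2", "FlexDetect"))
  for (mn in c("sensitivity", "specificity", "fdr", "for")) {
    expect_true(all(res$table[[mn]] >= res$table[[paste0(mn, "_lo")]] - 1e-12))
    expect_true(all(res$table[[mn]] <= res$table[[paste0(mn, "_hi")]] + 1e-12))
    expect_true(all(res$table[[mn]] >= 0 & res$table[[mn]] <= 1))
  }
  expect_equal(nrow(res$per_replicate), 10L)
  expect_true(all(res$per_replicate$TP + res$per_replicate$FP +
                    res$per_replicate$TN + res$per_replicate$FN == 20L))
  # intervals are across-replicate percentiles; pooled counts kept alongside
  expect_equal(nrow(res$pooled), 5L)

  res2 <- run_study(config = cfg, n_replicates = 2L, cfg = mc, seed = 31L)
  expect_identical(res$table, res2$table)
  expect_identical(res$per_replicate, res2$per_replicate)

  out <- file.path(tempdir(), "bench-out")
  run_study(config = cfg, n_replicates = 1L, cfg = mc, seed = 5L,
            rules = c("DM1", "FlexDetect"), out_dir = out)
  expect_true(file.exists(file.path(out, "table1.csv")))
  expect_true(file.exists(file.path(out, "per_replicate_metrics.csv")))
  expect_error(run_study(rules = "Nope", n_replicates = 1L), "unknown rule")
})

test_that("the CLI simulate subcommand writes a readable replicate", {
  skip_if_not_installed("optparse")
  out <- file.path(tempdir(), "cli-out")
  stsurveil_cli(c("simulate", "--n-areas", "25", "--n-times", "6",
                  "--n-unusual", "3", "--seed", "3", "--out-dir", out))
  panel <- read_count_panel(file.path(out, "panel.csv"))
  expect_equal(c(panel$n_areas, panel$n_times), c(25L, 6L))
  truth <- read_scenario_truth(file.path(out, "truth.csv"))
  expect_length(truth$unusual_areas, 3L)
  graph <- read_adjacency(file.path(out, "edges.csv"), n_areas = 25)
  expect_equal(graph$n_areas, 25L)
  expect_equal(stsurveil_cli(character(0)), 1L, ignore_attr = TRUE)
})

test_that("posterior draws serialise to a columnar file", {
  scen <- small_scenario(2)
  fit <- fit_dm(scen$panel, scen$graph,
                micro_cfg(n_chains = 2L, n_iterations = 400L,
                          burn_in = 200L, thin = 10L))
  f <- tempfile(fileext = ".csv")
  write_posterior_draws(fit, f, blocks = c("alpha", "tau_psi", "gamma"))
  d <- read.csv(f)
  expect_equal(nrow(d), fit$n_draws)
  expect_true(all(c("chain", "draw", "alpha", "tau_psi", "gamma.1") %in%
                    names(d)))
  expect_equal(d$alpha, as.vector(fit$draws$alpha))
})
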