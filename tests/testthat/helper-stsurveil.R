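# Shared fixtures: everything is generated in code at test time.

# tiny MCMC settings for unit tests (not for inference quality)
micro_cfg <- function(seed = 1L, n_chains = 2L, n_iterations = 1200L,
                      burn_in = 600L, thin = 3L) {
  mcmc_config(n_iterations = n_iterations, burn_in = burn_in, thin = thin,
              n_chains = n_chains, seed = seed)
}

# small scenario with non-default dimensions for quick model runs
small_config <- function(n_areas = 24L, n_times = 8L, n_unusual = 3L,
                         expected_range = c(30, 50), ...) {
  scenario_config(n_areas = n_areas, n_times = n_times, n_unusual = n_unusual,
                  up_times = c(3L, 6L), down_times = c(4L, 8L),
                  expected_range = expected_range, ...)
}

small_scenario <- function(seed = 1L, config = small_config()) {
  make_scenario1(seed, config = config)
}

# dense-Laplacian quadratic form, the independent oracle for the edge sum
laplacian_quadratic_form <- function(values, graph) {
  n <- graph$n_areas
  W <- matrix(0, n, n)
  if (nrow(graph$edges)) {
    W[graph$edges] <- 1
    W[graph$edges[, c(2, 1), drop = FALSE]] <- 1
  }
  D <- diag(rowSums(W), n)
  as.numeric(t(values) %*% (D - W) %*% values)
}

random_graph <- function(n, p_edge = 0.3) {
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p_edge
  # sparse random graphs are often disconnected / have isolates: fine here
  suppressWarnings(area_graph(n, pairs[keep, , drop = FALSE]))
}
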