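# Synthetic surveillance scenarios: a smooth spatiotemporal Poisson baseline
# with a known set of "unusual" areas whose log relative risk is shifted by
# +-log(2) at scheduled time points. These replicate datasets drive the
# detection benchmark and all calibration tests.

#' Scenario configuration
#'
#' Parameters of the synthetic scenario generator. The defaults describe the
#' benchmark scenario: 211 areas observed over 15 time points with 15 unusual
#' areas whose log relative risk is raised by `log(2)` at time points 3 and 10
#' and lowered by `log(2)` at time points 6, 12 and 15 (time indices are
#' 1-based). Baseline surface scales: spatial (ICAR pairwise-difference) sd
#' 0.2, temporal random-walk increment sd 0.15, unstructured and interaction
#' sd 0.05; per-area expected counts drawn uniformly on \[20, 60\] and held
#' constant over time, plausible for monthly small-area admission counts.
#'
#' @param n_areas,n_times Grid dimensions.
#' @param n_unusual Number of areas carrying the anomaly signal.
#' @param signal_magnitude Absolute log-relative-risk shift (default `log(2)`).
#' @param up_times,down_times 1-based time points at which unusual areas are
#'   shifted up / down. Must be disjoint and within `1..n_times`; when left
#'   at their defaults they are restricted to the panel's time range
#'   automatically (short panels simply use the scheduled points that fit).
#' @param alpha0 Baseline log relative risk (intercept).
#' @param sd_spatial,sd_temporal,sd_unstructured,sd_interaction Standard
#'   deviations of the structured spatial effect (ICAR difference scale), the
#'   RW1 trend increments, the exchangeable area effect and the space-time
#'   interaction noise.
#' @param expected_range Length-2 range for per-area expected counts.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(n_areas = 211L, n_times = 15L, n_unusual = 15L,
                            signal_magnitude = log(2),
                            up_times = c(3L, 10L), down_times = c(6L, 12L, 15L),
                            alpha0 = 0, sd_spatial = 0.2, sd_temporal = 0.15,
                            sd_unstructured = 0.05, sd_interaction = 0.05,
                            expected_range = c(20, 60)) {
  if (missing(up_times)) up_times <- up_times[up_times <= n_times]
  if (missing(down_times)) down_times <- down_times[down_times <= n_times]
  cfg <- list(n_areas = as.integer(n_areas), n_times = as.integer(n_times),
              n_unusual = as.integer(n_unusual),
              signal_magnitude = signal_magnitude,
              up_times = as.integer(up_times),
              down_times = as.integer(down_times),
              alpha0 = alpha0, sd_spatial = sd_spatial,
              sd_temporal = sd_temporal, sd_unstructured = sd_unstructured,
              sd_interaction = sd_interaction,
              expected_range = as.numeric(expected_range))
  if (cfg$n_areas < 1L || cfg$n_times < 1L) stop("grid dimensions must be positive")
  if (cfg$n_unusual < 0L || cfg$n_unusual > cfg$n_areas)
    stop("n_unusual must lie in 0..n_areas")
  if (length(intersect(cfg$up_times, cfg$down_times)))
    stop("up_times and down_times must be disjoint")
  sched <- c(cfg$up_times, cfg$down_times)
  if (length(sched) && (any(sched < 1L) || any(sched > cfg$n_times)))
    stop("scheduled time points must lie in 1..n_times")
  if (cfg$signal_magnitude < 0) stop("signal_magnitude must be >= 0")
  if (length(cfg$expected_range) != 2L || any(cfg$expected_range <= 0) ||
      diff(cfg$expected_range) < 0)
    stop("expected_range must be a positive increasing pair")
  structure(cfg, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("scenario_config:", x$n_areas, "areas x", x$n_times, "times;",
      x$n_unusual, "unusual areas, signal +-", round(x$signal_magnitude, 3),
      "at t = {", paste(x$up_times, collapse = ","), "} up / {",
      paste(x$down_times, collapse = ","), "} down\n")
  invisible(x)
}

# Draw from the sum-to-zero-constrained intrinsic CAR: N(0, sigma^2 L^+) on
# the subspace orthogonal to each component's constant vector, via the
# Laplacian eigendecomposition (done per connected component). Isolated areas
# get 0. `sigma` is the pairwise-difference scale (tau = 1/sigma^2).
r_icar <- function(graph, sigma) {
  n <- graph$n_areas
  if (sigma == 0) return(numeric(n))
  theta <- numeric(n)
  for (k in seq_len(graph$n_components)) {
    idx <- which(graph$components == k)
    m <- length(idx)
    if (m < 2L) next
    sub <- graph$edges[graph$components[graph$edges[, 1L]] == k, , drop = FALSE]
    pos <- match(sub, idx)
    dim(pos) <- dim(sub)
    L <- matrix(0, m, m)
    for (r in seq_len(nrow(pos))) {
      i <- pos[r, 1L]; j <- pos[r, 2L]
      L[i, j] <- L[i, j] - 1
      L[j, i] <- L[j, i] - 1
      L[i, i] <- L[i, i] + 1
      L[j, j] <- L[j, j] + 1
    }
    eg <- eigen(L, symmetric = TRUE)
    lam <- eg$values[-m]              # drop the null eigenvalue
    V <- eg$vectors[, -m, drop = FALSE]
    z <- stats::rnorm(m - 1L)
    theta[idx] <- as.vector(V %*% (sigma * z / sqrt(lam)))
  }
  theta
}

# Sum-to-zero first-order random walk: iid N(0, sigma^2) increments, pinned
# then centred. Centring removes exactly the flat direction, so the result is
# the intrinsic RW1 under the sum-to-zero constraint and the increments keep
# their marginal distribution.
r_rw1 <- function(n_times, sigma) {
  if (sigma == 0) return(numeric(n_times))
  g <- cumsum(c(0, stats::rnorm(n_times - 1L, 0, sigma)))
  g - mean(g)
}

#' Generate a baseline latent surface
#'
#' Draws the components of the additive log-relative-risk decomposition
#' `log rr = alpha + theta_i + phi_i + gamma_t + psi_it`: `theta` from the
#' sum-to-zero intrinsic CAR on `graph`, `gamma` from a sum-to-zero RW1,
#' `phi` and `psi` from zero-mean independent normals, at the scales in
#' `config`. Deterministic given `seed`.
#'
#' @param config A [scenario_config()].
#' @param graph An `area_graph` with `config$n_areas` areas.
#' @param seed Integer seed.
#' @return Object of class `latent_surface` with fields `alpha`, `theta`,
#'   `phi`, `gamma`, `psi` and `log_rr` (areas x times).
#' @export
generate_baseline <- function(config, graph, seed) {
  stopifnot(inherits(config, "scenario_config"), inherits(graph, "area_graph"))
  if (graph$n_areas != config$n_areas)
    stop("graph$n_areas must match config$n_areas")
  with_seed(seed, {
    n <- config$n_areas; Tt <- config$n_times
    theta <- r_icar(graph, config$sd_spatial)
    gamma <- r_rw1(Tt, config$sd_temporal)
    phi <- stats::rnorm(n, 0, config$sd_unstructured)
    psi <- matrix(stats::rnorm(n * Tt, 0, config$sd_interaction), n, Tt)
    new_latent_surface(config$alpha0, theta, phi, gamma, psi)
  })
}

new_latent_surface <- function(alpha, theta, phi, gamma, psi) {
  log_rr <- alpha + outer(theta + phi, rep(1, length(gamma))) +
    outer(rep(1, length(theta)), gamma) + psi
  structure(list(alpha = alpha, theta = theta, phi = phi, gamma = gamma,
                 psi = psi, log_rr = log_rr),
            class = "latent_surface")
}

#' @export
print.latent_surface <- function(x, ...) {
  cat("latent_surface:", length(x$theta), "areas x", length(x$gamma),
      "times; log rr range [", round(min(x$log_rr), 3), ",",
      round(max(x$log_rr), 3), "]\n")
  invisible(x)
}

#' Inject anomaly signals into a latent surface
#'
#' Chooses `config$n_unusual` areas uniformly at random (seeded) and shifts
#' their log relative risk by `+signal_magnitude` at `up_times` and
#' `-signal_magnitude` at `down_times`. The shift is carried on the
#' interaction component `psi`, preserving the additive decomposition. All
#' other units are untouched.
#'
#' @param surface A `latent_surface`.
#' @param config A [scenario_config()].
#' @param seed Integer seed.
#' @return List with elements `surface` (shifted `latent_surface`) and
#'   `truth` (a `scenario_truth`: `unusual_areas`, `signal_schedule` -- named
#'   vector, time index to signed offset -- and the full `per_unit_offset`
#'   matrix).
#' @export
inject_signals <- function(surface, config, seed) {
  stopifnot(inherits(surface, "latent_surface"),
            inherits(config, "scenario_config"))
  n <- length(surface$theta); Tt <- length(surface$gamma)
  if (n != config$n_areas || Tt != config$n_times)
    stop("surface dimensions must match config")
  with_seed(seed, {
    unusual <- sort(sample.int(n, config$n_unusual))
    sched <- numeric(Tt)
    sched[config$up_times] <- config$signal_magnitude
    sched[config$down_times] <- -config$signal_magnitude
    offset <- matrix(0, n, Tt)
    offset[unusual, ] <- rep(sched, each = length(unusual))
    shifted <- new_latent_surface(surface$alpha, surface$theta, surface$phi,
                                  surface$gamma, surface$psi + offset)
    truth <- structure(
      list(unusual_areas = unusual,
           signal_schedule = stats::setNames(sched, seq_len(Tt)),
           per_unit_offset = offset, n_areas = n, n_times = Tt),
      class = "scenario_truth")
    list(surface = shifted, truth = truth)
  })
}

#' @export
print.scenario_truth <- function(x, ...) {
  cat("scenario_truth:", length(x$unusual_areas), "unusual of", x$n_areas,
      "areas; nonzero schedule at t = {",
      paste(which(x$signal_schedule != 0), collapse = ","), "}\n")
  invisible(x)
}

#' Sample Poisson counts from a latent surface
#'
#' Independent draws `y_it ~ Poisson(E_it * exp(log_rr_it))`.
#'
#' @param surface A `latent_surface`.
#' @param E Strictly positive expected-count matrix (areas x times).
#' @param seed Integer seed.
#' @return A [count_panel()].
#' @export
sample_counts <- function(surface, E, seed) {
  stopifnot(inherits(surface, "latent_surface"))
  E <- as.matrix(E)
  if (!all(dim(E) == dim(surface$log_rr)))
    stop("E must match the surface dimensions")
  if (any(E <= 0)) stop("all expected counts must be positive")
  with_seed(seed, {
    mu <- E * exp(surface$log_rr)
    y <- matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
    count_panel(y, E)
  })
}

#' Generate one benchmark replicate dataset
#'
#' One replicate of the benchmark scenario: builds (or reuses) an irregular
#' adjacency graph, draws the baseline surface, injects the `+-log(2)` signal
#' into `n_unusual` randomly chosen areas, draws per-area expected counts once
#' (constant over time) and samples Poisson counts. All randomness is driven
#' by sub-seeds spawned from `seed`.
#'
#' @param seed Integer master seed.
#' @param config A [scenario_config()]; defaults to the benchmark defaults.
#' @param graph Optional `area_graph` to reuse (e.g. across replicates, the
#'   way one fixed administrative map underlies every replicate of a real
#'   study); if `NULL`, a [build_random_planar_graph()] is drawn from `seed`.
#' @return List with `panel` (`count_panel`), `truth` (`scenario_truth`),
#'   `graph`, `surface` and `config`.
#' @export
make_scenario1 <- function(seed, config = scenario_config(), graph = NULL) {
  seeds <- .spawn_seeds(seed, 5L)
  if (is.null(graph)) graph <- build_random_planar_graph(config$n_areas, seeds[1L])
  base <- generate_baseline(config, graph, seeds[2L])
  sig <- inject_signals(base, config, seeds[3L])
  E <- with_seed(seeds[4L],
    matrix(stats::runif(config$n_areas, config$expected_range[1L],
                        config$expected_range[2L]),
           config$n_areas, config$n_times))
  panel <- sample_counts(sig$surface, E, seeds[5L])
  list(panel = panel, truth = sig$truth, graph = graph,
       surface = sig$surface, config = config)
}

#' Read or write a scenario configuration file
#'
#' Key-value YAML mirroring the fields of [scenario_config()], the
#' interchange format used by the command-line interface. Requires the
#' `yaml` package.
#'
#' @param path File path.
#' @return `read_scenario_config` returns a `scenario_config`;
#'   `write_scenario_config` returns `path`, invisibly.
#' @export
read_scenario_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("config files require the 'yaml' package")
  vals <- yaml::read_yaml(path)
  known <- names(formals(scenario_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  do.call(scenario_config, vals)
}

#' @param config A [scenario_config()].
#' @rdname read_scenario_config
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("config files require the 'yaml' package")
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' Write scenario truth labels to CSV
#'
#' Long format: `area` (0-based), `time` (1-based), `offset` (signed
#' log-relative-risk shift at that unit) and `is_unusual` (area-level label).
#'
#' @param truth A `scenario_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario_truth <- function(truth, path) {
  stopifnot(inherits(truth, "scenario_truth"))
  d <- data.frame(
    area = rep(seq_len(truth$n_areas) - 1L, times = truth$n_times),
    time = rep(seq_len(truth$n_times), each = truth$n_areas),
    offset = as.vector(truth$per_unit_offset),
    is_unusual = rep(seq_len(truth$n_areas) %in% truth$unusual_areas,
                     times = truth$n_times))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read scenario truth labels from CSV
#'
#' @param path Path written by [write_scenario_truth()].
#' @return A `scenario_truth`.
#' @export
read_scenario_truth <- function(path) {
  d <- utils::read.csv(path)
  n <- max(d$area) + 1L
  Tt <- max(d$time)
  offset <- matrix(0, n, Tt)
  offset[cbind(d$area + 1L, d$time)] <- d$offset
  unusual <- sort(unique(d$area[d$is_unusual] + 1L))
  sched <- numeric(Tt)
  if (length(unusual)) sched <- offset[unusual[1L], ]
  structure(list(unusual_areas = unusual,
                 signal_schedule = stats::setNames(sched, seq_len(Tt)),
                 per_unit_offset = offset, n_areas = n, n_times = Tt),
            class = "scenario_truth")
}
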