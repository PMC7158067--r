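# Shared MCMC machinery: configuration, prior/likelihood log-densities, the
# chain driver with Robbins-Monro adaptation, draw storage, and convergence
# diagnostics. Latent fields are updated by vectorised single-site
# random-walk Metropolis (non-adjacent areas in one graph-colour class are
# conditionally independent and move as one block); precisions and the
# intercept have conjugate Gibbs updates.

#' MCMC configuration
#'
#' @param n_iterations Total sweeps per chain.
#' @param burn_in Sweeps discarded (and, when `adapt`, used for proposal-scale
#'   adaptation targeting 0.44 acceptance; adaptation stops at the end of
#'   burn-in so the retained chain is Markovian).
#' @param thin Keep every `thin`-th post-burn-in sweep.
#' @param n_chains Number of independent chains (>= 2 enables [gelman_rubin()]).
#' @param seed Integer seed; chain `c` runs under `seed + 7919 * (c - 1)`.
#' @param proposal_scales Optional named list overriding initial random-walk
#'   proposal standard deviations (names: `psi`, `phi`, `theta`, `gamma`,
#'   `delta`, `theta_pairs`, `gamma_pairs`).
#' @param adapt Adapt proposal scales during burn-in (default `TRUE`).
#' @return Object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iterations = 20000L, burn_in = 10000L, thin = 10L,
                        n_chains = 2L, seed = 1L, proposal_scales = NULL,
                        adapt = TRUE) {
  cfg <- list(n_iterations = as.integer(n_iterations),
              burn_in = as.integer(burn_in), thin = as.integer(thin),
              n_chains = as.integer(n_chains), seed = as.integer(seed),
              proposal_scales = proposal_scales, adapt = isTRUE(adapt))
  if (cfg$burn_in < 0L || cfg$burn_in >= cfg$n_iterations)
    stop("burn_in must satisfy 0 <= burn_in < n_iterations")
  if (cfg$thin < 1L) stop("thin must be >= 1")
  if (cfg$n_chains < 1L) stop("n_chains must be >= 1")
  structure(cfg, class = "mcmc_config")
}

#' Fast-mode MCMC configuration
#'
#' Short chains (2 x 5000 sweeps, 2500 burn-in, thin 5) for desk-scale runs
#' and replicate benchmarks; full-length defaults are in [mcmc_config()].
#'
#' @param ... Overrides passed to [mcmc_config()].
#' @return An `mcmc_config`.
#' @export
fast_mcmc_config <- function(...) {
  args <- list(...)
  defaults <- list(n_iterations = 5000L, burn_in = 2500L, thin = 5L,
                   n_chains = 2L)
  do.call(mcmc_config, utils::modifyList(defaults, args))
}

#' Intrinsic RW1 log-density
#'
#' Log-density of a first-order random-walk prior on a temporal sequence:
#' `-(tau/2) * sum_t (gamma_t - gamma_(t-1))^2` plus the Gaussian normalising
#' terms of the `length(gamma) - 1` increments (the constant gauge direction
#' carries no mass and is ignored).
#'
#' @param gamma Numeric vector of length >= 2.
#' @param tau Positive precision of the increments.
#' @return Scalar log-density.
#' @export
rw1_log_density <- function(gamma, tau) {
  if (length(gamma) < 2L) stop("gamma must have length >= 2")
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive")
  d <- diff(gamma)
  sum(stats::dnorm(d, 0, 1 / sqrt(tau), log = TRUE))
}

#' Poisson panel log-likelihood
#'
#' `sum_it [ y_it (log E_it + log_rr_it) - E_it exp(log_rr_it) - log(y_it!) ]`,
#' the log-likelihood of independent Poisson counts with means
#' `E_it * exp(log_rr_it)`.
#'
#' @param panel A [count_panel()].
#' @param log_rr Matrix of log relative risks, same shape as the panel.
#' @return Scalar log-likelihood.
#' @export
poisson_loglik <- function(panel, log_rr) {
  stopifnot(inherits(panel, "count_panel"))
  log_rr <- as.matrix(log_rr)
  if (!all(dim(log_rr) == dim(panel$y)))
    stop("log_rr must match the panel shape")
  sum(panel$y * (log(panel$E) + log_rr) - panel$E * exp(log_rr) -
        lgamma(panel$y + 1))
}

# ---------------------------------------------------------------------------
# Posterior draw container

new_posterior_samples <- function(model, draws, chain, acceptance, audit,
                                  cfg, dims, extra = list()) {
  nd <- unique(vapply(draws, nrow, 0L))
  if (length(nd) != 1L) stop("all blocks must share the draw count")
  for (nm in names(draws)) {
    x <- draws[[nm]]
    if (startsWith(nm, "tau") && any(x <= 0))
      stop("precision draws must be strictly positive (block ", nm, ")")
    if (nm %in% c("z", "c") && !all(x %in% c(0, 1)))
      stop("indicator draws must be 0/1 (block ", nm, ")")
    if (nm %in% c("p", "p_common") && (any(x < 0) || any(x > 1)))
      stop("probability draws must lie in [0,1] (block ", nm, ")")
  }
  structure(list(model = model, draws = draws, chain = chain,
                 n_draws = nd, acceptance = acceptance, audit = audit,
                 cfg = cfg, dims = dims, extra = extra),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("posterior_samples [", x$model, "]: ", x$n_draws, " draws (",
      length(unique(x$chain)), " chain(s)); blocks: ",
      paste(names(x$draws), collapse = ", "), "\n", sep = "")
  cat("  max cache drift audited:", format(x$audit, digits = 3), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Chain driver

.model_registry <- function(model) {
  reg <- list(dm = .model_dm, stmix = .model_stmix, flexdetect = .model_flex)
  if (!model %in% names(reg))
    stop("unknown model '", model, "'; registered: ",
         paste(names(reg), collapse = ", "))
  reg[[model]]
}

#' Run MCMC for a registered surveillance model
#'
#' Shared sampling backbone for the three models (`"dm"`, `"stmix"`,
#' `"flexdetect"`). Runs `cfg$n_chains` chains, each deterministic given
#' `cfg$seed`; proposal scales adapt during burn-in only; sum-to-zero gauge
#' freedom of the intrinsic fields is re-imposed every sweep by recentring
#' with the removed mean absorbed into the (flat-prior) intercept; internal
#' caches are audited against a fresh recomputation every 100 sweeps.
#'
#' @param model One of `"dm"`, `"stmix"`, `"flexdetect"`.
#' @param panel A [count_panel()].
#' @param graph An `area_graph` over the panel's areas.
#' @param cfg An [mcmc_config()].
#' @param opts Named list of model options (prior hyperparameters etc.); see
#'   the `fit_*` wrappers for the defaults of each model.
#' @return A `posterior_samples` object.
#' @export
run_chain <- function(model, panel, graph, cfg = mcmc_config(), opts = list()) {
  stopifnot(inherits(panel, "count_panel"), inherits(graph, "area_graph"),
            inherits(cfg, "mcmc_config"))
  if (graph$n_areas != panel$n_areas)
    stop("graph and panel disagree on the number of areas")
  spec <- .model_registry(model)
  n_store <- (cfg$n_iterations - cfg$burn_in) %/% cfg$thin
  if (n_store < 1L) stop("no draws would be retained; adjust iterations/thin")

  all_draws <- NULL
  chain_id <- integer(0)
  acc_rows <- list()
  audit <- 0
  for (ch in seq_len(cfg$n_chains)) {
    res <- with_seed(cfg$seed + 7919L * (ch - 1L),
                     .run_one_chain(spec, panel, graph, cfg, opts, n_store))
    if (is.null(all_draws)) {
      all_draws <- res$store
    } else {
      for (nm in names(all_draws))
        all_draws[[nm]] <- rbind(all_draws[[nm]], res$store[[nm]])
    }
    chain_id <- c(chain_id, rep(ch, n_store))
    acc_rows[[ch]] <- data.frame(chain = ch, block = names(res$acc),
                                 rate = unname(res$acc))
    audit <- max(audit, res$audit)
  }
  new_posterior_samples(spec$name, all_draws, chain_id,
                        do.call(rbind, acc_rows), audit, cfg,
                        dims = list(n_areas = panel$n_areas,
                                    n_times = panel$n_times))
}

.run_one_chain <- function(spec, panel, graph, cfg, opts, n_store) {
  st <- spec$init(panel, graph, cfg, opts)
  lp0 <- spec$log_posterior(st)
  if (!is.finite(lp0))
    stop("non-finite log-posterior at initialization (", lp0, "); state: ",
         paste(utils::capture.output(utils::str(spec$collect(st),
                                                max.level = 1)),
               collapse = " "))
  dims <- vapply(spec$collect(st), length, 0L)
  store <- lapply(dims, function(d) matrix(NA_real_, n_store, d))
  acc_sum <- NULL
  acc_n <- 0L
  batch_sum <- NULL
  batch_n <- 0L
  batch_idx <- 0L
  audit <- 0
  kept <- 0L
  for (it in seq_len(cfg$n_iterations)) {
    a <- spec$sweep(st)
    if (it <= cfg$burn_in) {
      if (cfg$adapt) {
        batch_sum <- if (is.null(batch_sum)) a else batch_sum + a
        batch_n <- batch_n + 1L
        if (batch_n == 50L) {
          batch_idx <- batch_idx + 1L
          rate <- batch_sum / batch_n
          for (nm in names(rate)) {
            if (is.null(st$scales[[nm]]) || !is.finite(rate[[nm]])) next
            st$scales[[nm]] <- min(10, max(1e-4,
              st$scales[[nm]] * exp((rate[[nm]] - 0.44) / sqrt(batch_idx))))
          }
          batch_sum <- NULL
          batch_n <- 0L
        }
      }
    } else {
      acc_sum <- if (is.null(acc_sum)) a else acc_sum + a
      acc_n <- acc_n + 1L
      if ((it - cfg$burn_in) %% cfg$thin == 0L && kept < n_store) {
        kept <- kept + 1L
        vals <- spec$collect(st)
        for (nm in names(vals)) store[[nm]][kept, ] <- vals[[nm]]
      }
    }
    if (it %% 100L == 0L) audit <- max(audit, spec$audit(st))
  }
  list(store = store, acc = acc_sum / max(acc_n, 1L), audit = audit)
}

# ---------------------------------------------------------------------------
# Convergence diagnostics

.psrf <- function(x, chain) {
  xs <- split(x, chain)
  nn <- min(lengths(xs))
  xs <- lapply(xs, function(v) v[seq_len(nn)])
  means <- vapply(xs, mean, 0)
  vars <- vapply(xs, stats::var, 0)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(max(1, ((nn - 1) / nn * W + B / nn) / W))
}

#' Gelman-Rubin potential scale reduction
#'
#' Between/within-chain variance ratio per scalar, summarised per latent
#' block by the worst (largest) value. Values near 1 indicate the chains are
#' sampling the same distribution; the statistic is floored at 1 (values
#' below 1 are estimation noise by construction). Mixture models are the
#' usual suspects for large values.
#'
#' @param samples A `posterior_samples` object with at least 2 chains.
#' @param blocks Optional character vector restricting the blocks examined.
#' @return Named numeric vector, max potential scale reduction per block,
#'   with the per-scalar values in attribute `"per_scalar"`.
#' @export
gelman_rubin <- function(samples, blocks = NULL) {
  stopifnot(inherits(samples, "posterior_samples"))
  if (length(unique(samples$chain)) < 2L)
    stop("diagnostic unavailable: need at least 2 chains")
  nms <- blocks %||% names(samples$draws)
  detail <- lapply(nms, function(nm) {
    m <- samples$draws[[nm]]
    apply(m, 2L, .psrf, chain = samples$chain)
  })
  names(detail) <- nms
  out <- vapply(detail, max, 0)
  attr(out, "per_scalar") <- detail
  out
}
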