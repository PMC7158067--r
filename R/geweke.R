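# Joint-distribution validation of the sampler (successive-conditional
# simulation). Two streams target the same joint distribution of (latents,
# precisions, data): one draws from the prior directly, the other alternates
# one MCMC sweep given y with a fresh draw of y given the latents. If the
# transition kernels are exactly invariant, all marginal moments agree.
#
# The check runs the disease-mapping blocks with the intercept fixed at 0 and
# the intrinsic fields (theta, gamma) moved by the sum-preserving pairwise
# kernels, which are invariant for the *constrained* intrinsic priors without
# the flat-intercept gauge argument; proper Gamma priors on the precisions
# make the joint prior proper. All density code, the iid-field Metropolis
# kernels and the conjugate precision updates are the production code paths.

.geweke_functionals <- function(theta, phi, gamma, psi, taus) {
  c(theta1 = theta[1L], theta_ss = sum(theta^2),
    phi1 = phi[1L], phi_ss = sum(phi^2),
    gamma1 = gamma[1L], gamma_ss = sum(gamma^2),
    psi11 = psi[1L, 1L], psi_ss = sum(psi^2),
    tau_theta = taus[1L], tau_phi = taus[2L],
    tau_gamma = taus[3L], tau_psi = taus[4L])
}

.geweke_prior_draw <- function(graph, Tt, tau_a, tau_b) {
  taus <- stats::rgamma(4L, tau_a, rate = tau_b)
  n <- graph$n_areas
  list(theta = r_icar(graph, 1 / sqrt(taus[1L])),
       phi = stats::rnorm(n, 0, 1 / sqrt(taus[2L])),
       gamma = r_rw1(Tt, 1 / sqrt(taus[3L])),
       psi = matrix(stats::rnorm(n * Tt, 0, 1 / sqrt(taus[4L])), n, Tt),
       taus = taus)
}

# Runs both streams and returns per-functional z-scores (difference of means
# over a standard error combining the iid prior stream with batch-means SEs
# for the autocorrelated successive-conditional stream).
.geweke_check <- function(n_rows = 2L, n_cols = 3L, n_times = 4L, E0 = 5,
                          tau_a = 20, tau_b = 2, n_prior = 4000L,
                          n_sc = 20000L, seed = 1L, n_batch = 100L) {
  graph <- build_lattice_graph(n_rows, n_cols)
  n <- graph$n_areas
  Tt <- n_times
  Em <- matrix(E0, n, Tt)
  with_seed(seed, {
    prior <- matrix(NA_real_, n_prior, 12L)
    for (i in seq_len(n_prior)) {
      d <- .geweke_prior_draw(graph, Tt, tau_a, tau_b)
      prior[i, ] <- .geweke_functionals(d$theta, d$phi, d$gamma, d$psi, d$taus)
    }
    colnames(prior) <- names(.geweke_functionals(
      numeric(n), numeric(n), numeric(Tt), matrix(0, n, Tt), numeric(4L)))

    d <- .geweke_prior_draw(graph, Tt, tau_a, tau_b)
    y <- matrix(stats::rpois(n * Tt, Em * exp(d$theta + d$phi +
                                                rep(d$gamma, each = n) +
                                                d$psi)), n, Tt)
    panel <- count_panel(y, Em)
    cfg <- mcmc_config(n_iterations = 2L, burn_in = 1L, thin = 1L,
                       n_chains = 1L, seed = seed, adapt = FALSE)
    opts <- list(alpha_update = "fixed", alpha_value = 0, kernel = "pairs",
                 tau_a = tau_a, tau_b = tau_b,
                 init_state = list(alpha = 0, theta = d$theta, phi = d$phi,
                                   gamma = d$gamma, psi = d$psi,
                                   tau_theta = d$taus[1L],
                                   tau_phi = d$taus[2L],
                                   tau_gamma = d$taus[3L],
                                   tau_psi = d$taus[4L]))
    st <- .model_dm$init(panel, graph, cfg, opts)
    st$scales$theta_pairs <- 0.35
    st$scales$gamma_pairs <- 0.35
    st$scales$phi <- 0.35
    st$scales$psi <- 0.35
    sc <- matrix(NA_real_, n_sc, 12L)
    colnames(sc) <- colnames(prior)
    for (i in seq_len(n_sc)) {
      .model_dm$sweep(st)
      # refresh the data conditional on the current latents
      st$y <- matrix(stats::rpois(n * Tt, st$Eexp), n, Tt)
      st$ry <- rowSums(st$y)
      st$cy <- colSums(st$y)
      st$sy <- sum(st$y)
      sc[i, ] <- .geweke_functionals(st$theta, st$phi, st$gamma, st$psi,
                                     c(st$tau_theta, st$tau_phi,
                                       st$tau_gamma, st$tau_psi))
      if (i %% 500L == 0L) {
        .refresh_caches(st)
        # numerically exact re-projection of the constrained fields (the
        # pairwise kernels preserve the sums up to floating-point drift)
        st$theta <- st$theta - mean(st$theta)
        st$gamma <- st$gamma - mean(st$gamma)
      }
    }
    z <- vapply(seq_len(ncol(prior)), function(j) {
      m1 <- mean(prior[, j])
      se1 <- stats::sd(prior[, j]) / sqrt(nrow(prior))
      bm <- tapply(sc[, j], rep(seq_len(n_batch),
                                each = ceiling(n_sc / n_batch))[seq_len(n_sc)],
                   mean)
      m2 <- mean(sc[, j])
      se2 <- stats::sd(bm) / sqrt(length(bm))
      (m1 - m2) / sqrt(se1^2 + se2^2)
    }, 0)
    names(z) <- colnames(prior)
    list(z = z, prior_means = colMeans(prior), sc_means = colMeans(sc))
  })
}
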