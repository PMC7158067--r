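# The three surveillance model specifications, expressed against the shared
# kernel set in updates.R. Each spec provides init / sweep / collect /
# log_posterior / audit and is driven by run_chain().

.default_scales <- function(cfg) {
  sc <- new.env(parent = emptyenv())
  sc$psi <- 0.15
  sc$phi <- 0.1
  sc$theta <- 0.1
  sc$gamma <- 0.08
  sc$delta <- 0.15
  sc$theta_pairs <- 0.3
  sc$gamma_pairs <- 0.3
  for (nm in names(cfg$proposal_scales %||% list()))
    sc[[nm]] <- cfg$proposal_scales[[nm]]
  sc
}

.base_state <- function(panel, graph, cfg, opts) {
  st <- new.env(parent = emptyenv())
  st$y <- panel$y
  st$E <- panel$E
  st$n <- panel$n_areas
  st$Tt <- panel$n_times
  st$N <- st$n * st$Tt
  st$ry <- rowSums(st$y)
  st$cy <- colSums(st$y)
  st$sy <- sum(st$y)
  st$W <- .graph_sparse_w(graph)
  st$deg <- graph$neighbor_counts
  st$edges <- graph$edges
  st$colors <- .graph_coloring(graph)
  st$rankL <- graph$n_areas - graph$n_components
  st$scales <- .default_scales(cfg)
  st$tau_a <- opts$tau_a %||% 1
  st$tau_b <- opts$tau_b %||% 0.01
  st$tau_update <- opts$tau_update %||% "gibbs"
  st$fix_tau <- opts$fix_tau %||% character(0)
  st
}

.refresh_caches <- function(st) {
  # returns the max drift between incremental caches and a fresh recompute,
  # then installs the fresh values
  eta <- st$alpha + outer(st$theta + st$phi, rep(1, st$Tt)) +
    outer(rep(1, st$n), st$gamma) + st$psi
  Eexp <- st$E * exp(eta)
  drift <- max(abs(eta - st$eta)) +
    max(abs(Eexp - st$Eexp) / pmax(Eexp, 1e-12))
  st$eta <- eta
  st$Eexp <- Eexp
  drift
}

.panel_loglik_state <- function(st) {
  sum(st$y * (log(st$E) + st$eta) - st$Eexp - lgamma(st$y + 1))
}

.gamma_prior_ld <- function(tau, a, b) stats::dgamma(tau, a, rate = b, log = TRUE)

# ---------------------------------------------------------------------------
# Disease mapping: log rr = alpha + theta_i + phi_i + gamma_t + psi_it

.model_dm <- list(
  name = "dm",

  init = function(panel, graph, cfg, opts) {
    st <- .base_state(panel, graph, cfg, opts)
    st$alpha_update <- opts$alpha_update %||% "gibbs"
    st$kernel <- opts$kernel %||% "site"
    if (st$alpha_update == "gibbs" && st$sy == 0)
      stop("flat-prior intercept requires at least one observed count")
    init <- opts$init_state %||% list()
    st$alpha <- init$alpha %||%
      if (st$alpha_update == "fixed") (opts$alpha_value %||% 0)
      else log(st$sy / sum(st$E))
    st$theta <- init$theta %||% numeric(st$n)
    st$phi <- init$phi %||% numeric(st$n)
    st$gamma <- init$gamma %||% numeric(st$Tt)
    st$psi <- init$psi %||% matrix(0, st$n, st$Tt)
    ti <- opts$tau_init %||% 10
    st$tau_theta <- init$tau_theta %||% ti
    st$tau_phi <- init$tau_phi %||% ti
    st$tau_gamma <- init$tau_gamma %||% ti
    st$tau_psi <- init$tau_psi %||% ti
    st$eta <- matrix(0, st$n, st$Tt)
    st$Eexp <- st$E
    .refresh_caches(st)
    st
  },

  sweep = function(st) {
    a_psi <- .update_psi(st, st$tau_psi)
    a_phi <- .update_phi(st)
    if (st$kernel == "pairs") {
      a_th <- .update_theta_pairs(st)
      a_ga <- .update_gamma_pairs(st)
      acc <- c(theta_pairs = a_th, gamma_pairs = a_ga)
    } else {
      a_th <- .update_theta_site(st)
      a_ga <- .update_gamma_site(st)
      .recenter_theta(st)
      .recenter_gamma(st)
      acc <- c(theta = a_th, gamma = a_ga)
    }
    if (st$alpha_update == "gibbs") .update_alpha_gibbs(st)
    if (!"tau_theta" %in% st$fix_tau)
      st$tau_theta <- .draw_tau(st, st$tau_theta, st$rankL / 2,
                                sum((st$theta[st$edges[, 1L]] -
                                       st$theta[st$edges[, 2L]])^2))
    if (!"tau_phi" %in% st$fix_tau)
      st$tau_phi <- .draw_tau(st, st$tau_phi, st$n / 2, sum(st$phi^2))
    if (!"tau_gamma" %in% st$fix_tau)
      st$tau_gamma <- .draw_tau(st, st$tau_gamma, (st$Tt - 1) / 2,
                                sum(diff(st$gamma)^2))
    if (!"tau_psi" %in% st$fix_tau)
      st$tau_psi <- .draw_tau(st, st$tau_psi, st$N / 2, sum(st$psi^2))
    c(psi = a_psi, phi = a_phi, acc)
  },

  collect = function(st) {
    list(alpha = st$alpha, theta = st$theta, phi = st$phi, gamma = st$gamma,
         psi = as.vector(st$psi), tau_theta = st$tau_theta,
         tau_phi = st$tau_phi, tau_gamma = st$tau_gamma,
         tau_psi = st$tau_psi)
  },

  log_posterior = function(st) {
    ll <- .panel_loglik_state(st)
    pr <- -st$tau_theta / 2 * sum((st$theta[st$edges[, 1L]] -
                                     st$theta[st$edges[, 2L]])^2) +
      st$rankL / 2 * log(st$tau_theta) +
      sum(stats::dnorm(st$phi, 0, 1 / sqrt(st$tau_phi), log = TRUE)) +
      (if (st$Tt > 1) rw1_log_density(st$gamma, st$tau_gamma) else 0) +
      sum(stats::dnorm(st$psi, 0, 1 / sqrt(st$tau_psi), log = TRUE)) +
      .gamma_prior_ld(st$tau_theta, st$tau_a, st$tau_b) +
      .gamma_prior_ld(st$tau_phi, st$tau_a, st$tau_b) +
      .gamma_prior_ld(st$tau_gamma, st$tau_a, st$tau_b) +
      .gamma_prior_ld(st$tau_psi, st$tau_a, st$tau_b)
    ll + pr
  },

  audit = function(st) .refresh_caches(st)
)

# ---------------------------------------------------------------------------
# STmix: DM with the interaction prior replaced by a two-component zero-mean
# normal mixture with weight p and sds sigma1 <= sigma2; per-unit component
# indicators are Gibbs-sampled. Identification ("label switching") is handled
# by asymmetric informative priors on the two precisions combined with the
# ordering constraint, enforced by truncated-Gamma Gibbs draws.

.model_stmix <- list(
  name = "stmix",

  init = function(panel, graph, cfg, opts) {
    st <- .base_state(panel, graph, cfg, opts)
    st$alpha_update <- "gibbs"
    st$kernel <- "site"
    if (st$sy == 0)
      stop("flat-prior intercept requires at least one observed count")
    ident <- opts$identification %||% "informative_ordered"
    if (!ident %in% c("informative_ordered", "ordered"))
      stop("identification must be 'informative_ordered' or 'ordered'")
    st$ident <- ident
    if (ident == "informative_ordered") {
      # component 1: common wobble of a few percent; component 2: anomalies
      # of tens of percent on the risk scale
      st$sig1_a <- opts$sig1_a %||% 2
      st$sig1_b <- opts$sig1_b %||% 0.005
      st$sig2_a <- opts$sig2_a %||% 2
      st$sig2_b <- opts$sig2_b %||% 0.5
    } else {
      st$sig1_a <- opts$sig1_a %||% 1
      st$sig1_b <- opts$sig1_b %||% 0.01
      st$sig2_a <- opts$sig2_a %||% 1
      st$sig2_b <- opts$sig2_b %||% 0.01
    }
    st$p_a <- opts$p_a %||% 1
    st$p_b <- opts$p_b %||% 1
    st$alpha <- log(st$sy / sum(st$E))
    st$theta <- numeric(st$n)
    st$phi <- numeric(st$n)
    st$gamma <- numeric(st$Tt)
    st$psi <- matrix(0, st$n, st$Tt)
    st$tau_theta <- st$tau_phi <- st$tau_gamma <- 10
    st$tau1 <- st$sig1_a / st$sig1_b
    st$tau2 <- st$sig2_a / st$sig2_b
    if (st$tau2 > st$tau1) st$tau2 <- st$tau1
    st$cind <- matrix(1L, st$n, st$Tt)
    st$p <- 0.9
    st$eta <- matrix(0, st$n, st$Tt)
    st$Eexp <- st$E
    .refresh_caches(st)
    st
  },

  sweep = function(st) {
    prec <- st$tau1 * (st$cind == 1L) + st$tau2 * (st$cind == 2L)
    a_psi <- .update_psi(st, prec)
    a_phi <- .update_phi(st)
    a_th <- .update_theta_site(st)
    a_ga <- .update_gamma_site(st)
    .recenter_theta(st)
    .recenter_gamma(st)
    .update_alpha_gibbs(st)
    # component indicators: Bernoulli full conditionals
    l1 <- log(st$p) + 0.5 * log(st$tau1) - st$tau1 * st$psi^2 / 2
    l2 <- log1p(-st$p) + 0.5 * log(st$tau2) - st$tau2 * st$psi^2 / 2
    p1 <- 1 / (1 + exp(l2 - l1))
    st$cind <- 1L + (matrix(stats::runif(st$N), st$n, st$Tt) >= p1) * 1L
    n1 <- sum(st$cind == 1L)
    st$p <- stats::rbeta(1L, st$p_a + n1, st$p_b + st$N - n1)
    # ordered precisions (sigma2 >= sigma1 <=> tau2 <= tau1), truncated Gibbs
    S1 <- sum(st$psi[st$cind == 1L]^2)
    S2 <- sum(st$psi[st$cind == 2L]^2)
    sh1 <- st$sig1_a + n1 / 2
    rt1 <- st$sig1_b + S1 / 2
    lo <- stats::pgamma(st$tau2, sh1, rate = rt1)
    u <- stats::runif(1L, min(lo, 1 - 1e-10), 1 - 1e-12)
    st$tau1 <- stats::qgamma(u, sh1, rate = rt1)
    sh2 <- st$sig2_a + (st$N - n1) / 2
    rt2 <- st$sig2_b + S2 / 2
    hi <- stats::pgamma(st$tau1, sh2, rate = rt2)
    u2 <- stats::runif(1L, 0, max(hi, 1e-250))
    st$tau2 <- max(stats::qgamma(u2, sh2, rate = rt2), 1e-10)
    if (st$tau2 > st$tau1) st$tau2 <- st$tau1   # numeric belt-and-braces
    # structural precisions
    st$tau_theta <- .draw_tau(st, st$tau_theta, st$rankL / 2,
                              sum((st$theta[st$edges[, 1L]] -
                                     st$theta[st$edges[, 2L]])^2))
    st$tau_phi <- .draw_tau(st, st$tau_phi, st$n / 2, sum(st$phi^2))
    st$tau_gamma <- .draw_tau(st, st$tau_gamma, (st$Tt - 1) / 2,
                              sum(diff(st$gamma)^2))
    c(psi = a_psi, phi = a_phi, theta = a_th, gamma = a_ga)
  },

  collect = function(st) {
    list(alpha = st$alpha, theta = st$theta, phi = st$phi, gamma = st$gamma,
         psi = as.vector(st$psi), c = as.vector((st$cind == 2L) * 1),
         p = st$p, sigma1 = 1 / sqrt(st$tau1), sigma2 = 1 / sqrt(st$tau2),
         tau_theta = st$tau_theta, tau_phi = st$tau_phi,
         tau_gamma = st$tau_gamma)
  },

  log_posterior = function(st) {
    ll <- .panel_loglik_state(st)
    sd_cell <- 1 / sqrt(st$tau1 * (st$cind == 1L) + st$tau2 * (st$cind == 2L))
    pr <- -st$tau_theta / 2 * sum((st$theta[st$edges[, 1L]] -
                                     st$theta[st$edges[, 2L]])^2) +
      st$rankL / 2 * log(st$tau_theta) +
      sum(stats::dnorm(st$phi, 0, 1 / sqrt(st$tau_phi), log = TRUE)) +
      (if (st$Tt > 1) rw1_log_density(st$gamma, st$tau_gamma) else 0) +
      sum(stats::dnorm(st$psi, 0, sd_cell, log = TRUE)) +
      sum(ifelse(st$cind == 1L, log(st$p), log1p(-st$p))) +
      stats::dbeta(st$p, st$p_a, st$p_b, log = TRUE) +
      .gamma_prior_ld(st$tau1, st$sig1_a, st$sig1_b) +
      .gamma_prior_ld(st$tau2, st$sig2_a, st$sig2_b) +
      .gamma_prior_ld(st$tau_theta, st$tau_a, st$tau_b) +
      .gamma_prior_ld(st$tau_phi, st$tau_a, st$tau_b) +
      .gamma_prior_ld(st$tau_gamma, st$tau_a, st$tau_b)
    ll + pr
  },

  audit = function(st) .refresh_caches(st)
)

# ---------------------------------------------------------------------------
# FlexDetect core: per-area choice between a common-trend submodel
# (alpha + theta_i + gamma_t) and an area-specific-trend submodel
# (alpha_i + delta_it with a per-area RW1). Both submodels are fitted to the
# full data (feedback cut); the area indicators z_i are Gibbs-drawn from the
# at-draw likelihood ratio with a Beta(19, 1) prior on the probability of the
# common model.

.flex_sub_common <- function(panel, graph, cfg, opts) {
  st <- .base_state(panel, graph, cfg, opts)
  st$alpha <- log(st$sy / sum(st$E))
  st$theta <- numeric(st$n)
  st$gamma <- numeric(st$Tt)
  st$tau_theta <- st$tau_gamma <- st$tau_phi <- 10
  # The common submodel is the full standard spatiotemporal specification:
  # convolution (BYM) area effect plus iid interaction noise around the
  # global trend. Without them, ordinary area-level heterogeneity and
  # cell-level overdispersion masquerade as "unusual trends" and the
  # model-choice indicator flags areas for their level or wobble rather
  # than their trajectory. common_bym / common_overdispersion = FALSE give
  # the bare alpha + theta_i + gamma_t variant.
  st$bym <- !isFALSE(opts$common_bym)
  st$overdisp <- !isFALSE(opts$common_overdispersion)
  st$tau_psi <- 10
  st$phi <- numeric(st$n)
  st$psi <- matrix(0, st$n, st$Tt)
  st$eta <- matrix(0, st$n, st$Tt)
  st$Eexp <- st$E
  .refresh_caches(st)
  st
}

.model_flex <- list(
  name = "flexdetect",

  init = function(panel, graph, cfg, opts) {
    if (any(rowSums(panel$y) == 0))
      warning("areas with all-zero counts: area-level intercepts there ",
              "move by Metropolis fallback")
    st <- new.env(parent = emptyenv())
    st$common <- .flex_sub_common(panel, graph, cfg, opts)
    sp <- new.env(parent = emptyenv())
    sp$y <- panel$y
    sp$E <- panel$E
    sp$n <- panel$n_areas
    sp$Tt <- panel$n_times
    sp$N <- sp$n * sp$Tt
    sp$ry <- rowSums(sp$y)
    sp$scales <- st$common$scales    # shared environment: one adaptation set
    # informative smoothing prior on the per-area trend precisions (prior
    # mean 100, increment sd ~0.1): ordinary areas keep stiff, near-flat
    # trends so the area-specific submodel cannot chase Poisson noise, while
    # a genuinely anomalous area pulls its own precision down and frees its
    # trend. This is the informative-variance device the mixture needs for
    # identification.
    sp$td_a <- opts$tau_delta_a %||% 2
    sp$td_b <- opts$tau_delta_b %||% 0.02
    sp$a <- log((sp$ry + 0.5) / rowSums(sp$E))
    sp$delta <- matrix(0, sp$n, sp$Tt)
    sp$tau_delta <- rep(sp$td_a / sp$td_b, sp$n)
    sp$eta <- matrix(sp$a, sp$n, sp$Tt)
    sp$Eexp <- sp$E * exp(sp$eta)
    st$spec <- sp
    st$pi_a <- opts$pi_a %||% 19
    st$pi_b <- opts$pi_b %||% 1
    # The common-model probability is a design prior (anomalies are rare by
    # assumption): held at its prior mean unless update_pi = TRUE. Sampling
    # it lets the likelihood of 200+ areas swamp the Beta(19,1) prior and
    # admits a collapsed low-pi regime in which ordinary areas are absorbed
    # by the area-specific submodel en masse.
    st$update_pi <- isTRUE(opts$update_pi)
    st$ppi <- st$pi_a / (st$pi_a + st$pi_b)
    st$z <- integer(sp$n)            # 0 = common, 1 = area-specific
    st$scales <- st$common$scales
    st$z_audit <- 0
    st
  },

  sweep = function(st) {
    co <- st$common
    sp <- st$spec
    # common submodel
    a_ps <- if (co$overdisp) .update_psi(co, co$tau_psi) else NA_real_
    a_th <- .update_theta_site(co)
    a_ph <- if (co$bym) .update_phi(co) else NA_real_
    a_ga <- .update_gamma_site(co)
    .recenter_theta(co)
    .recenter_gamma(co)
    .update_alpha_gibbs(co)
    co$tau_theta <- .draw_tau(co, co$tau_theta, co$rankL / 2,
                              sum((co$theta[co$edges[, 1L]] -
                                     co$theta[co$edges[, 2L]])^2))
    if (co$bym)
      co$tau_phi <- .draw_tau(co, co$tau_phi, co$n / 2, sum(co$phi^2))
    if (co$overdisp)
      co$tau_psi <- .draw_tau(co, co$tau_psi, co$N / 2, sum(co$psi^2))
    co$tau_gamma <- .draw_tau(co, co$tau_gamma, (co$Tt - 1) / 2,
                              sum(diff(co$gamma)^2))
    # area-specific submodel
    a_de <- .update_delta(sp)
    .recenter_delta(sp)
    .update_area_intercepts(sp)
    sp$tau_delta <- stats::rgamma(sp$n, sp$td_a + (sp$Tt - 1) / 2,
                                  rate = sp$td_b +
                                    rowSums((sp$delta[, -1L, drop = FALSE] -
                                               sp$delta[, -sp$Tt, drop = FALSE])^2) / 2)
    # per-area model choice from the at-draw likelihood ratio
    lr0 <- rowSums(st$common$y * (co$eta - sp$eta) - (co$Eexp - sp$Eexp))
    p_common <- stats::plogis(log(st$ppi) - log1p(-st$ppi) + lr0)
    st$z <- as.integer(stats::runif(sp$n) >= p_common)
    if (st$update_pi) {
      n0 <- sum(st$z == 0L)
      st$ppi <- stats::rbeta(1L, st$pi_a + n0, st$pi_b + sp$n - n0)
    }
    c(psi = a_ps, theta = a_th, phi = a_ph, gamma = a_ga, delta = a_de)
  },

  collect = function(st) {
    co <- st$common
    sp <- st$spec
    list(alpha = co$alpha, theta = co$theta, phi = co$phi, gamma = co$gamma,
         psi = as.vector(co$psi), tau_theta = co$tau_theta,
         tau_phi = co$tau_phi, tau_gamma = co$tau_gamma,
         tau_psi = co$tau_psi,
         a = sp$a, delta = as.vector(sp$delta), tau_delta = sp$tau_delta,
         z = as.numeric(st$z), p_common = st$ppi)
  },

  log_posterior = function(st) {
    co <- st$common
    sp <- st$spec
    ll <- .panel_loglik_state(co) +
      sum(sp$y * (log(sp$E) + sp$eta) - sp$Eexp - lgamma(sp$y + 1))
    incr <- sp$delta[, -1L, drop = FALSE] - sp$delta[, -sp$Tt, drop = FALSE]
    pr <- -co$tau_theta / 2 * sum((co$theta[co$edges[, 1L]] -
                                     co$theta[co$edges[, 2L]])^2) +
      co$rankL / 2 * log(co$tau_theta) +
      (if (co$bym)
        sum(stats::dnorm(co$phi, 0, 1 / sqrt(co$tau_phi), log = TRUE)) +
          .gamma_prior_ld(co$tau_phi, co$tau_a, co$tau_b)
       else 0) +
      (if (co$overdisp)
        sum(stats::dnorm(co$psi, 0, 1 / sqrt(co$tau_psi), log = TRUE)) +
          .gamma_prior_ld(co$tau_psi, co$tau_a, co$tau_b)
       else 0) +
      (if (co$Tt > 1) rw1_log_density(co$gamma, co$tau_gamma) else 0) +
      sum(stats::dnorm(incr, 0, rep(1 / sqrt(sp$tau_delta), sp$Tt - 1L),
                       log = TRUE)) +
      sum(stats::dgamma(sp$tau_delta, sp$td_a, rate = sp$td_b, log = TRUE)) +
      .gamma_prior_ld(co$tau_theta, co$tau_a, co$tau_b) +
      .gamma_prior_ld(co$tau_gamma, co$tau_a, co$tau_b) +
      stats::dbeta(st$ppi, st$pi_a, st$pi_b, log = TRUE)
    ll + pr
  },

  audit = function(st) {
    co <- st$common
    sp <- st$spec
    eta_c <- co$alpha + outer(co$theta + co$phi, rep(1, co$Tt)) +
      outer(rep(1, co$n), co$gamma) + co$psi
    Eexp_c <- co$E * exp(eta_c)
    drift <- max(abs(eta_c - co$eta)) +
      max(abs(Eexp_c - co$Eexp) / pmax(Eexp_c, 1e-12))
    co$eta <- eta_c
    co$Eexp <- Eexp_c
    eta_s <- matrix(sp$a, sp$n, sp$Tt) + sp$delta
    Eexp_s <- sp$E * exp(eta_s)
    drift <- drift + max(abs(eta_s - sp$eta)) +
      max(abs(Eexp_s - sp$Eexp) / pmax(Eexp_s, 1e-12))
    sp$eta <- eta_s
    sp$Eexp <- Eexp_s
    # consistency of the mixture likelihood: the z-selected surface must give
    # exactly the Poisson log-likelihood of the z-selected log-risks
    mixed <- ifelse(matrix(st$z == 1L, sp$n, sp$Tt), eta_s, eta_c)
    l_sel <- sum(sp$y * (log(sp$E) + mixed) - sp$E * exp(mixed) -
                   lgamma(sp$y + 1))
    l_dir <- sum(ifelse(st$z == 1L,
                        rowSums(sp$y * (log(sp$E) + eta_s) - Eexp_s -
                                  lgamma(sp$y + 1)),
                        rowSums(sp$y * (log(sp$E) + eta_c) - Eexp_c -
                                  lgamma(sp$y + 1))))
    st$z_audit <- max(st$z_audit, abs(l_sel - l_dir))
    drift + abs(l_sel - l_dir)
  }
)

# -- area-specific submodel kernels -----------------------------------------

# per-area RW1 trends: odd/even time blocks are conditionally independent
# across all areas at once; per-area precisions recycle over rows.
.update_delta <- function(sp) {
  Tt <- sp$Tt
  n <- sp$n
  nacc <- 0L
  for (par in list(seq(1L, Tt, 2L), if (Tt > 1L) seq(2L, Tt, 2L))) {
    if (is.null(par) || !length(par)) next
    g <- sp$delta
    nb <- (par > 1L) + (par < Tt)
    nb_m <- matrix(nb, n, length(par), byrow = TRUE)
    # neighbour sums: left neighbour where it exists, plus right neighbour
    sN <- matrix(0, n, length(par))
    left <- par > 1L
    right <- par < Tt
    if (any(left)) sN[, left] <- sN[, left] + g[, par[left] - 1L, drop = FALSE]
    if (any(right)) sN[, right] <- sN[, right] + g[, par[right] + 1L, drop = FALSE]
    d <- matrix(stats::rnorm(n * length(par), 0, sp$scales$delta),
                n, length(par))
    cur <- g[, par, drop = FALSE]
    lr <- sp$y[, par, drop = FALSE] * d -
      sp$Eexp[, par, drop = FALSE] * expm1(d) -
      sp$tau_delta / 2 * (nb_m * (2 * cur * d + d^2) - 2 * sN * d)
    acc <- matrix(log(stats::runif(n * length(par))), n, length(par)) < lr
    if (any(acc)) {
      da <- d * acc
      sp$delta[, par] <- cur + da
      sp$eta[, par] <- sp$eta[, par] + da
      sp$Eexp[, par] <- sp$Eexp[, par] * exp(da)
      nacc <- nacc + sum(acc)
    }
  }
  nacc / sp$N
}

# per-row gauge move (flat per-area intercepts)
.recenter_delta <- function(sp) {
  rm0 <- rowMeans(sp$delta)
  sp$delta <- sp$delta - rm0
  sp$a <- sp$a + rm0
}

# flat-prior per-area intercepts: exp(a_i) ~ Gamma(row total, row offset);
# all-zero rows (Gamma shape 0) fall back to a likelihood-only Metropolis step
.update_area_intercepts <- function(sp) {
  re <- rowSums(sp$Eexp)
  pos <- sp$ry > 0
  d <- numeric(sp$n)
  if (any(pos)) {
    lam <- stats::rgamma(sum(pos), shape = sp$ry[pos],
                         rate = re[pos] / exp(sp$a[pos]))
    d[pos] <- log(lam) - sp$a[pos]
  }
  if (any(!pos)) {
    dd <- stats::rnorm(sum(!pos), 0, 0.5)
    ok <- log(stats::runif(sum(!pos))) < -re[!pos] * expm1(dd)
    d[!pos] <- dd * ok
  }
  sp$a <- sp$a + d
  sp$eta <- sp$eta + d
  sp$Eexp <- sp$Eexp * exp(d)
}
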