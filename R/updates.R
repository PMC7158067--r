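# Internal Metropolis / Gibbs update kernels. All kernels mutate a state
# environment `st` holding the data (y, E, ry, cy, sy), the graph machinery
# (W, deg, colors, edges, rankL), the latent fields, and two caches kept
# coherent across updates: eta (the log relative risk surface on the grid)
# and Eexp = E * exp(eta). Metropolis kernels return their acceptance rate.

# -- interaction / iid matrix effect ----------------------------------------
# prec may be a scalar (DM) or a per-cell matrix (mixture models).
.update_psi <- function(st, prec) {
  d <- matrix(stats::rnorm(st$N, 0, st$scales$psi), st$n, st$Tt)
  lr <- st$y * d - st$Eexp * expm1(d) - prec / 2 * (2 * st$psi * d + d^2)
  acc <- log(stats::runif(st$N)) < lr
  if (any(acc)) {
    da <- d * acc
    st$psi <- st$psi + da
    st$eta <- st$eta + da
    st$Eexp <- st$Eexp * exp(da)
  }
  mean(acc)
}

# -- exchangeable area effect -----------------------------------------------
.update_phi <- function(st) {
  d <- stats::rnorm(st$n, 0, st$scales$phi)
  re <- rowSums(st$Eexp)
  lr <- st$ry * d - re * expm1(d) - st$tau_phi / 2 * (2 * st$phi * d + d^2)
  acc <- log(stats::runif(st$n)) < lr
  if (any(acc)) {
    da <- d * acc
    st$phi <- st$phi + da
    st$eta <- st$eta + da            # recycles over rows
    st$Eexp <- st$Eexp * exp(da)
  }
  mean(acc)
}

# -- ICAR spatial effect, colour-class blocks --------------------------------
# Areas within one colour class share no edge, so given the other classes
# their full conditionals are independent and the class moves as one
# vectorised Metropolis block. Isolated areas carry no prior term (flat).
.update_theta_site <- function(st) {
  nacc <- 0L
  re <- rowSums(st$Eexp)
  for (cl in st$colors) {
    sN <- as.vector(st$W %*% st$theta)[cl]
    th <- st$theta[cl]
    d <- stats::rnorm(length(cl), 0, st$scales$theta)
    lr <- st$ry[cl] * d - re[cl] * expm1(d) -
      st$tau_theta / 2 * (st$deg[cl] * (2 * th * d + d^2) - 2 * sN * d)
    acc <- log(stats::runif(length(cl))) < lr
    if (any(acc)) {
      da <- d * acc
      st$theta[cl] <- th + da
      st$eta[cl, ] <- st$eta[cl, ] + da
      st$Eexp[cl, ] <- st$Eexp[cl, ] * exp(da)
      re[cl] <- re[cl] * exp(da)
      nacc <- nacc + sum(acc)
    }
  }
  nacc / st$n
}

# Gauge move: the ICAR prior is invariant to a constant shift of theta and
# the intercept has a flat prior, so moving the mean of theta into alpha is
# measure-preserving. Re-imposed every sweep.
.recenter_theta <- function(st) {
  c0 <- mean(st$theta)
  st$theta <- st$theta - c0
  st$alpha <- st$alpha + c0
}

# -- RW1 temporal trend, odd/even blocks -------------------------------------
.update_gamma_site <- function(st) {
  Tt <- st$Tt
  n <- st$n
  ce <- colSums(st$Eexp)
  nacc <- 0L
  for (par in list(seq(1L, Tt, 2L), if (Tt > 1L) seq(2L, Tt, 2L))) {
    if (is.null(par) || !length(par)) next
    g <- st$gamma
    nb <- (par > 1L) + (par < Tt)
    sN <- ifelse(par > 1L, g[pmax(par - 1L, 1L)], 0) +
      ifelse(par < Tt, g[pmin(par + 1L, Tt)], 0)
    d <- stats::rnorm(length(par), 0, st$scales$gamma)
    lr <- st$cy[par] * d - ce[par] * expm1(d) -
      st$tau_gamma / 2 * (nb * (2 * g[par] * d + d^2) - 2 * sN * d)
    acc <- log(stats::runif(length(par))) < lr
    if (any(acc)) {
      da <- d * acc
      st$gamma[par] <- g[par] + da
      st$eta[, par] <- st$eta[, par] + rep(da, each = n)
      st$Eexp[, par] <- st$Eexp[, par] * rep(exp(da), each = n)
      ce[par] <- ce[par] * exp(da)
      nacc <- nacc + sum(acc)
    }
  }
  nacc / Tt
}

.recenter_gamma <- function(st) {
  c0 <- mean(st$gamma)
  st$gamma <- st$gamma - c0
  st$alpha <- st$alpha + c0
}

# -- intercept ---------------------------------------------------------------
# Flat prior: exp(alpha) has a Gamma(sum y, sum E exp(eta - alpha)) full
# conditional, sampled exactly.
.update_alpha_gibbs <- function(st) {
  lam <- stats::rgamma(1L, shape = st$sy, rate = sum(st$Eexp) / exp(st$alpha))
  d <- log(lam) - st$alpha
  st$alpha <- st$alpha + d
  st$eta <- st$eta + d
  st$Eexp <- st$Eexp * exp(d)
}

# -- sum-preserving pairwise kernels for the intrinsic blocks ----------------
# Antisymmetric (+e, -e) moves on a random pairing stay on the sum-to-zero
# subspace exactly, giving an invariant kernel for the *constrained*
# intrinsic prior without relying on the flat-intercept gauge move. Used for
# small-problem validation runs; quadratic forms are recomputed in full.
.update_theta_pairs <- function(st) {
  n <- st$n
  perm <- sample.int(n)
  re <- rowSums(st$Eexp)
  e1 <- st$edges[, 1L]
  e2 <- st$edges[, 2L]
  nacc <- 0L
  npair <- n %/% 2L
  for (k in seq_len(npair)) {
    i <- perm[2L * k - 1L]
    j <- perm[2L * k]
    e <- stats::rnorm(1L, 0, st$scales$theta_pairs)
    th2 <- st$theta
    th2[i] <- th2[i] + e
    th2[j] <- th2[j] - e
    dQ <- sum((th2[e1] - th2[e2])^2) - sum((st$theta[e1] - st$theta[e2])^2)
    lr <- st$ry[i] * e - re[i] * expm1(e) -
      st$ry[j] * e - re[j] * expm1(-e) - st$tau_theta / 2 * dQ
    if (log(stats::runif(1L)) < lr) {
      st$theta <- th2
      st$eta[i, ] <- st$eta[i, ] + e
      st$eta[j, ] <- st$eta[j, ] - e
      st$Eexp[i, ] <- st$Eexp[i, ] * exp(e)
      st$Eexp[j, ] <- st$Eexp[j, ] * exp(-e)
      re[i] <- re[i] * exp(e)
      re[j] <- re[j] * exp(-e)
      nacc <- nacc + 1L
    }
  }
  nacc / max(npair, 1L)
}

.update_gamma_pairs <- function(st) {
  Tt <- st$Tt
  n <- st$n
  perm <- sample.int(Tt)
  ce <- colSums(st$Eexp)
  nacc <- 0L
  npair <- Tt %/% 2L
  for (k in seq_len(npair)) {
    i <- perm[2L * k - 1L]
    j <- perm[2L * k]
    e <- stats::rnorm(1L, 0, st$scales$gamma_pairs)
    g2 <- st$gamma
    g2[i] <- g2[i] + e
    g2[j] <- g2[j] - e
    dQ <- sum(diff(g2)^2) - sum(diff(st$gamma)^2)
    lr <- st$cy[i] * e - ce[i] * expm1(e) -
      st$cy[j] * e - ce[j] * expm1(-e) - st$tau_gamma / 2 * dQ
    if (log(stats::runif(1L)) < lr) {
      st$gamma <- g2
      st$eta[, i] <- st$eta[, i] + e
      st$eta[, j] <- st$eta[, j] - e
      st$Eexp[, i] <- st$Eexp[, i] * exp(e)
      st$Eexp[, j] <- st$Eexp[, j] * exp(-e)
      ce[i] <- ce[i] * exp(e)
      ce[j] <- ce[j] * exp(-e)
      nacc <- nacc + 1L
    }
  }
  nacc / max(npair, 1L)
}

# -- precisions --------------------------------------------------------------
# Conjugate Gamma full conditional; `shape_add` is half the rank of the
# Gaussian (quadratic) form, `S` the quadratic form itself. The `mh` variant
# is a random walk on log tau targeting the same full conditional, kept as an
# independent cross-check of the conjugate algebra.
.draw_tau <- function(st, tau, shape_add, S) {
  if (identical(st$tau_update, "mh")) {
    lt <- log(tau) + stats::rnorm(1L, 0, 0.6)
    t2 <- exp(lt)
    lr <- (st$tau_a + shape_add) * (lt - log(tau)) -
      (st$tau_b + S / 2) * (t2 - tau)
    if (log(stats::runif(1L)) < lr) t2 else tau
  } else {
    stats::rgamma(1L, shape = st$tau_a + shape_add, rate = st$tau_b + S / 2)
  }
}
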