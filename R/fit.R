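# User-facing fitting wrappers around run_chain(), plus posterior summaries
# derived from the retained draws.

#' Fit the spatiotemporal disease mapping model
#'
#' The standard convolution specification
#' `log rho_it = alpha + theta_i + phi_i + gamma_t + psi_it` with an intrinsic
#' CAR prior on `theta` (sum-to-zero per sweep), an exchangeable normal
#' `phi`, an RW1 trend `gamma`, exchangeable interaction noise `psi`, a flat
#' prior on `alpha` and Gamma(1, 0.01) priors on all precisions. Anomaly
#' detection reads exceedance probabilities off the interaction draws.
#'
#' @param panel A [count_panel()].
#' @param graph An `area_graph`.
#' @param cfg An [mcmc_config()].
#' @param opts Model options: `tau_a`, `tau_b` (precision prior), plus the
#'   internal switches documented in [run_chain()].
#' @return A `posterior_samples` object (model `"dm"`).
#' @export
fit_dm <- function(panel, graph, cfg = mcmc_config(), opts = list()) {
  run_chain("dm", panel, graph, cfg, opts)
}

#' Fit the interaction-mixture (STmix) model
#'
#' Disease mapping with the interaction prior replaced by a two-component
#' zero-mean normal mixture, `psi_it ~ p N(0, sigma1^2) + (1-p) N(0,
#' sigma2^2)` with `sigma1 <= sigma2`: the small-variance component carries
#' ordinary overdispersion, the large-variance component absorbs anomalous
#' space-time units. Component indicators are Gibbs-sampled; the variance
#' ordering holds in every retained draw (truncated-Gamma Gibbs), and the
#' default adds asymmetric informative priors on the two precisions
#' (`identification = "informative_ordered"`; `"ordered"` uses symmetric
#' vague priors with the constraint only).
#'
#' @inheritParams fit_dm
#' @param opts Options: `identification`, `sig1_a`, `sig1_b`, `sig2_a`,
#'   `sig2_b` (component precision priors), `p_a`, `p_b` (Beta prior on the
#'   weight).
#' @return A `posterior_samples` object (model `"stmix"`).
#' @export
fit_stmix <- function(panel, graph, cfg = mcmc_config(), opts = list()) {
  run_chain("stmix", panel, graph, cfg, opts)
}

#' Fit the common-trend vs area-specific-trend mixture (FlexDetect core)
#'
#' Each area follows either a common submodel
#' `log rho_it = alpha + theta_i + gamma_t` (ICAR spatial field, shared RW1
#' trend) or an area-specific submodel `log rho_it = alpha_i + delta_it` with
#' an independent RW1 trend per area (per-area smoothing precisions with an
#' informative Gamma prior, so specific trends stay smooth unless the data
#' insist otherwise). Both submodels are fitted to the full data with the
#' feedback between the area indicators and the submodel fits severed (the
#' model-choice "cut"); the per-area indicator `z_i` (0 = common, 1 =
#' unusual) is Gibbs-drawn each sweep from the at-draw likelihood ratio with
#' a Beta(19, 1) prior on the probability of the common model. The detection
#' score is the posterior model probability `p~_i = Pr(z_i = 0 | y)`.
#'
#' @inheritParams fit_dm
#' @param opts Options: `pi_a`, `pi_b` (Beta prior on the common-model
#'   probability), `tau_delta_a`, `tau_delta_b` (per-area trend precision
#'   prior).
#' @return A `posterior_samples` object (model `"flexdetect"`).
#' @export
fit_flexdetect <- function(panel, graph, cfg = mcmc_config(), opts = list()) {
  run_chain("flexdetect", panel, graph, cfg, opts)
}

#' Per-unit interaction exceedance probabilities
#'
#' `P(exp(psi_it) > 1 | y) = P(psi_it > 0 | y)`, estimated as the fraction of
#' retained draws strictly above zero, for models that carry an interaction
#' block (`dm`, `stmix`).
#'
#' @param samples A `posterior_samples` with a `psi` block.
#' @return Areas x times matrix of probabilities.
#' @export
interaction_exceedance <- function(samples) {
  stopifnot(inherits(samples, "posterior_samples"))
  if (is.null(samples$draws$psi)) stop("samples carry no interaction block")
  matrix(colMeans(samples$draws$psi > 0),
         samples$dims$n_areas, samples$dims$n_times)
}

#' Per-unit relative-risk exceedance probabilities
#'
#' `P(rho_it > 1 | y)`: the log relative risk surface is reconstructed draw
#' by draw from the stored blocks and compared against 1 on the risk scale.
#'
#' @param samples A `posterior_samples` from model `"dm"` or `"stmix"`.
#' @return Areas x times matrix of probabilities.
#' @export
risk_exceedance <- function(samples) {
  stopifnot(inherits(samples, "posterior_samples"))
  d <- samples$draws
  if (is.null(d$psi)) stop("samples carry no interaction block")
  n <- samples$dims$n_areas
  Tt <- samples$dims$n_times
  ai <- rep(seq_len(n), times = Tt)
  ti <- rep(seq_len(Tt), each = n)
  lr <- d$psi + as.vector(d$alpha) +
    d$theta[, ai, drop = FALSE] + d$gamma[, ti, drop = FALSE]
  if (!is.null(d$phi)) lr <- lr + d$phi[, ai, drop = FALSE]
  matrix(colMeans(lr > 0), n, Tt)
}

#' Posterior common-trend model probabilities
#'
#' For a FlexDetect fit: `p~_i = Pr(z_i = 0 | y)`, the draw frequency of the
#' common-trend submodel for each area. Low values signal unusual areas.
#'
#' @param samples A `posterior_samples` from model `"flexdetect"`.
#' @return Numeric vector of length `n_areas`, values in \[0, 1\].
#' @export
model_probabilities <- function(samples) {
  stopifnot(inherits(samples, "posterior_samples"))
  if (is.null(samples$draws$z)) stop("samples carry no model-choice block")
  colMeans(samples$draws$z == 0)
}

#' Write retained draws to a columnar file
#'
#' One row per retained draw with `chain` and `draw` columns followed by the
#' named scalars of the requested blocks (vector blocks expand to
#' `block.1, block.2, ...`).
#'
#' @param samples A `posterior_samples`.
#' @param path Output CSV path.
#' @param blocks Blocks to include (default: all).
#' @return `path`, invisibly.
#' @export
write_posterior_draws <- function(samples, path, blocks = NULL) {
  stopifnot(inherits(samples, "posterior_samples"))
  nms <- blocks %||% names(samples$draws)
  cols <- list(chain = samples$chain,
               draw = stats::ave(samples$chain, samples$chain,
                                 FUN = seq_along))
  for (nm in nms) {
    m <- samples$draws[[nm]]
    if (ncol(m) == 1L) {
      cols[[nm]] <- as.vector(m)
    } else {
      for (j in seq_len(ncol(m))) cols[[paste0(nm, ".", j)]] <- m[, j]
    }
  }
  utils::write.csv(as.data.frame(cols), path, row.names = FALSE)
  invisible(path)
}
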