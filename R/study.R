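# Replicate-level benchmark: run the detectors over simulated scenario
# replicates and score them by sensitivity, specificity, FDR and FOR.

#' Area-level confusion counts
#'
#' Compares per-area flags against the scenario truth: TP = unusual areas
#' flagged, FP = common areas flagged, TN = common areas not flagged, FN =
#' unusual areas missed. The four counts partition the areas.
#'
#' @param flags Logical vector of per-area flags (or a `detection_result`).
#' @param truth A `scenario_truth`.
#' @return Object of class `confusion_counts` (fields `TP`, `FP`, `TN`, `FN`).
#' @export
confusion_counts <- function(flags, truth) {
  if (inherits(flags, "detection_result")) flags <- flags$flags
  stopifnot(inherits(truth, "scenario_truth"))
  flags <- as.logical(flags)
  if (length(flags) != truth$n_areas)
    stop("flags length must equal the number of areas")
  unusual <- seq_len(truth$n_areas) %in% truth$unusual_areas
  structure(list(TP = sum(flags & unusual), FP = sum(flags & !unusual),
                 TN = sum(!flags & !unusual), FN = sum(!flags & unusual)),
            class = "confusion_counts")
}

#' Performance metrics from confusion counts
#'
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), fdr = FP/(TP+FP),
#' for = FN/(TN+FN). A metric whose denominator is zero is reported as 0 (so
#' a detector that flags nothing has FDR 0, matching the reporting convention
#' of benchmark tables where a rule with no detections scores FDR 0.000).
#'
#' @param counts A `confusion_counts`.
#' @return Named numeric vector `c(sensitivity, specificity, fdr, for)`.
#' @export
performance_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  safe <- function(num, den) if (den == 0) 0 else num / den
  c(sensitivity = safe(counts$TP, counts$TP + counts$FN),
    specificity = safe(counts$TN, counts$TN + counts$FP),
    fdr = safe(counts$FP, counts$TP + counts$FP),
    "for" = safe(counts$FN, counts$TN + counts$FN))
}

# Detector registry: which model each rule reads, and how it turns a fit
# into per-area flags.
.detector_registry <- function(fdr_alpha = 0.05, dm_exceedance = "interaction") {
  exc <- function(samples) {
    if (dm_exceedance == "relative_risk") risk_exceedance(samples)
    else interaction_exceedance(samples)
  }
  list(
    DM1 = list(model = "dm",
               apply = function(s) dm_rule(exc(s), 0.8, rule = "DM1")),
    DM2 = list(model = "dm",
               apply = function(s) dm_rule(exc(s), 0.9, rule = "DM2")),
    STmix1 = list(model = "stmix",
                  apply = function(s) stmix_rule1(interaction_exceedance(s))),
    STmix2 = list(model = "stmix",
                  apply = function(s) stmix_rule2(interaction_exceedance(s))),
    FlexDetect = list(model = "flexdetect",
                      apply = function(s)
                        bayes_fdr_flags(model_probabilities(s), fdr_alpha))
  )
}

#' Run the replicate detection benchmark
#'
#' For each replicate: generate a scenario dataset (one shared adjacency
#' graph across replicates, the way a single administrative map underlies a
#' real study), fit the models needed by the requested rules, apply each
#' rule, and score it against the truth. Metrics are aggregated across
#' replicates as the mean with empirical 2.5/97.5 percentile intervals
#' (pooled-count metrics are also computed and kept alongside). Replicates
#' whose fit fails are logged and excluded. Deterministic given `seed`.
#'
#' @param config A [scenario_config()].
#' @param rules Character vector of detectors among `DM1`, `DM2`, `STmix1`,
#'   `STmix2`, `FlexDetect`.
#' @param n_replicates Number of replicate datasets (>= 1).
#' @param cfg An [mcmc_config()] used for every fit (use
#'   [fast_mcmc_config()] for desk-scale runs).
#' @param seed Master seed; spawns per-replicate sub-seeds.
#' @param fdr_alpha FDR budget of the FlexDetect rule.
#' @param dm_exceedance `"interaction"` (default) thresholds
#'   `P(psi_it > 0 | y)`; `"relative_risk"` thresholds `P(rho_it > 1 | y)`.
#' @param out_dir Optional directory: writes `table1.csv` and
#'   `per_replicate_metrics.csv`.
#' @param verbose Log per-replicate timing to stderr.
#' @return Object of class `study_result`: `table` (one row per rule:
#'   mean and interval per metric), `per_replicate`, `pooled`, `n_excluded`.
#' @export
run_study <- function(config = scenario_config(),
                      rules = c("DM1", "DM2", "STmix1", "STmix2", "FlexDetect"),
                      n_replicates = 10L, cfg = fast_mcmc_config(),
                      seed = 1L, fdr_alpha = 0.05,
                      dm_exceedance = c("interaction", "relative_risk"),
                      out_dir = NULL, verbose = FALSE) {
  dm_exceedance <- match.arg(dm_exceedance)
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  registry <- .detector_registry(fdr_alpha, dm_exceedance)
  unknown <- setdiff(rules, names(registry))
  if (length(unknown)) stop("unknown rule(s): ", paste(unknown, collapse = ", "))
  models <- unique(vapply(registry[rules], `[[`, "", "model"))

  seeds <- .spawn_seeds(seed, n_replicates + 1L)
  graph <- build_random_planar_graph(config$n_areas, seeds[1L])

  rows <- list()
  confs <- list()
  n_excluded <- 0L
  for (r in seq_len(n_replicates)) {
    t0 <- Sys.time()
    res <- tryCatch({
      scen <- make_scenario1(seeds[r + 1L], config = config, graph = graph)
      fits <- list()
      for (m in models) {
        mcfg <- cfg
        mcfg$seed <- as.integer((seeds[r + 1L] + match(m, models)) %% .Machine$integer.max)
        fits[[m]] <- run_chain(m, scen$panel, graph, mcfg)
      }
      lapply(rules, function(rl) {
        det <- registry[[rl]]$apply(fits[[registry[[rl]]$model]])
        cc <- confusion_counts(det, scen$truth)
        list(rule = rl, counts = cc, metrics = performance_metrics(cc),
             n_flagged = sum(det$flags))
      })
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_excluded <- n_excluded + 1L
      warning("replicate ", r, " excluded: ", conditionMessage(res))
      next
    }
    for (x in res) {
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, rule = x$rule, TP = x$counts$TP, FP = x$counts$FP,
        TN = x$counts$TN, FN = x$counts$FN, n_flagged = x$n_flagged,
        sensitivity = x$metrics[["sensitivity"]],
        specificity = x$metrics[["specificity"]],
        fdr = x$metrics[["fdr"]], "for" = x$metrics[["for"]],
        check.names = FALSE)
    }
    if (verbose)
      message(sprintf("replicate %d/%d done in %.1fs", r, n_replicates,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  if (!length(rows)) stop("all replicates failed")
  per_rep <- do.call(rbind, rows)

  metric_names <- c("sensitivity", "specificity", "fdr", "for")
  tab <- do.call(rbind, lapply(rules, function(rl) {
    d <- per_rep[per_rep$rule == rl, , drop = FALSE]
    out <- data.frame(rule = rl)
    for (mn in metric_names) {
      v <- d[[mn]]
      out[[mn]] <- mean(v)
      qs <- stats::quantile(v, c(0.025, 0.975), names = FALSE, type = 7)
      out[[paste0(mn, "_lo")]] <- qs[1L]
      out[[paste0(mn, "_hi")]] <- qs[2L]
    }
    out
  }))
  pooled <- do.call(rbind, lapply(rules, function(rl) {
    d <- per_rep[per_rep$rule == rl, , drop = FALSE]
    cc <- structure(list(TP = sum(d$TP), FP = sum(d$FP), TN = sum(d$TN),
                         FN = sum(d$FN)), class = "confusion_counts")
    data.frame(rule = rl, t(performance_metrics(cc)), check.names = FALSE)
  }))
  out <- structure(list(table = tab, per_replicate = per_rep, pooled = pooled,
                        n_excluded = n_excluded, config = config, cfg = cfg,
                        seed = seed),
                   class = "study_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(out_dir, "table1.csv"), row.names = FALSE)
    utils::write.csv(per_rep, file.path(out_dir, "per_replicate_metrics.csv"),
                     row.names = FALSE)
  }
  out
}

#' @export
print.study_result <- function(x, ...) {
  cat("study_result:", length(unique(x$per_replicate$replicate)),
      "replicate(s),", x$n_excluded, "excluded\n")
  tab <- x$table
  for (mn in c("sensitivity", "specificity", "fdr", "for")) {
    tab[[mn]] <- sprintf("%.3f (%.3f, %.3f)", x$table[[mn]],
                         x$table[[paste0(mn, "_lo")]],
                         x$table[[paste0(mn, "_hi")]])
    tab[[paste0(mn, "_lo")]] <- NULL
    tab[[paste0(mn, "_hi")]] <- NULL
  }
  print(tab, row.names = FALSE)
  invisible(x)
}
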