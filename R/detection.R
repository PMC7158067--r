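# Detection rules: turn posterior summaries into per-area unusual/common
# flags. The exceedance rules threshold per-unit probabilities that the
# space-time interaction exceeds 1 on the risk scale; the Bayesian FDR rule
# flags the largest set of areas whose average posterior probability of
# following the common-trend model stays within the FDR budget.

new_detection_result <- function(flags, scores, rule, threshold,
                                 unit_flags = NULL) {
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0,1]")
  structure(list(flags = as.logical(flags), scores = as.numeric(scores),
                 rule = rule, threshold = threshold, unit_flags = unit_flags),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat("detection_result [", x$rule, "]: ", sum(x$flags), " of ",
      length(x$flags), " areas flagged (threshold ",
      paste(format(x$threshold, digits = 3), collapse = "/"), ")\n", sep = "")
  invisible(x)
}

#' Export a detection result to CSV
#'
#' Columns `area` (0-based), `score`, `flagged`, `rule`, `threshold`.
#'
#' @param result A `detection_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detection_result <- function(result, path) {
  stopifnot(inherits(result, "detection_result"))
  utils::write.csv(
    data.frame(area = seq_along(result$flags) - 1L, score = result$scores,
               flagged = result$flags, rule = result$rule,
               threshold = result$threshold[1L]),
    path, row.names = FALSE)
  invisible(path)
}

#' Exceedance probability of one unit's draws
#'
#' Fraction of retained draws strictly above a reference value (default 0,
#' i.e. relative risk above 1 on the log scale).
#'
#' @param draws Numeric vector of retained draws (length >= 1).
#' @param reference Reference value (default 0).
#' @return Scalar in \[0, 1\].
#' @export
exceedance_probability <- function(draws, reference = 0) {
  if (!length(draws)) stop("draws must be non-empty")
  mean(draws > reference)
}

.check_prob_matrix <- function(exceed) {
  exceed <- as.matrix(exceed)
  if (anyNA(exceed) || any(exceed < 0) || any(exceed > 1))
    stop("exceedance probabilities must lie in [0,1]")
  exceed
}

#' Disease-mapping exceedance rule (DM1 / DM2)
#'
#' Flags an area iff at least one time point's exceedance probability is
#' strictly greater than `threshold` (0.8 for the standard rule, 0.9 for the
#' conservative variant). The per-area score is the maximum probability over
#' time.
#'
#' @param exceed Areas x times matrix of exceedance probabilities.
#' @param threshold Scalar in (0, 1).
#' @param rule Rule label for bookkeeping.
#' @return A `detection_result`.
#' @export
dm_rule <- function(exceed, threshold, rule = sprintf("DM(%.2g)", threshold)) {
  exceed <- .check_prob_matrix(exceed)
  if (length(threshold) != 1L || threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0,1)")
  score <- apply(exceed, 1L, max)
  new_detection_result(score > threshold, score, rule, threshold,
                       unit_flags = exceed > threshold)
}

#' STmix rule 1: any single time point
#'
#' An area is declared unusual iff for at least one time point the space-time
#' interaction has probability greater than 0.8 of being above 1 -- identical
#' in form to [dm_rule()] at threshold 0.8, applied to the mixture model's
#' interaction exceedances.
#'
#' @param exceed Areas x times matrix of interaction exceedance probabilities.
#' @return A `detection_result`.
#' @export
stmix_rule1 <- function(exceed) {
  dm_rule(exceed, 0.8, rule = "STmix1")
}

#' STmix rule 2: three time points on average
#'
#' An area is declared unusual iff the average of its three largest per-time
#' interaction exceedance probabilities is greater than 0.8 ("for at least
#' three time points ... an average probability greater than 0.8"; the
#' alternative reading -- any three consecutive time points -- is available
#' via `consecutive = TRUE`).
#'
#' @param exceed Areas x times matrix with at least 3 time points.
#' @param consecutive If `TRUE`, use the best window of 3 consecutive time
#'   points instead of the top three overall.
#' @return A `detection_result`.
#' @export
stmix_rule2 <- function(exceed, consecutive = FALSE) {
  exceed <- .check_prob_matrix(exceed)
  if (ncol(exceed) < 3L) stop("stmix_rule2 needs at least 3 time points")
  score <- if (consecutive) {
    apply(exceed, 1L, function(p) {
      max(vapply(seq_len(length(p) - 2L),
                 function(t0) mean(p[t0:(t0 + 2L)]), 0))
    })
  } else {
    apply(exceed, 1L, function(p) mean(sort(p, decreasing = TRUE)[1:3]))
  }
  new_detection_result(score > 0.8, score, "STmix2", 0.8)
}

#' Bayesian FDR flags from posterior model probabilities
#'
#' The posterior-expected FDR of flagging a set A is the average over A of
#' the areas' posterior probabilities of following the common-trend model.
#' The rule sorts `model_probs` ascending and flags the largest prefix whose
#' running mean stays at or below `alpha`; areas tied with the last flagged
#' value are flagged together.
#'
#' @param model_probs Per-area posterior probabilities of the common model
#'   (`p~_i`), in \[0, 1\].
#' @param alpha FDR budget in (0, 1), default 0.05.
#' @return A `detection_result` with scores `1 - model_probs`.
#' @export
bayes_fdr_flags <- function(model_probs, alpha = 0.05) {
  if (anyNA(model_probs) || any(model_probs < 0) || any(model_probs > 1))
    stop("model probabilities must lie in [0,1]")
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0,1)")
  n <- length(model_probs)
  ord <- order(model_probs)
  run_mean <- cumsum(model_probs[ord]) / seq_len(n)
  k <- max(c(0L, which(run_mean <= alpha)))
  flags <- logical(n)
  if (k > 0L) flags <- model_probs <= model_probs[ord[k]]
  new_detection_result(flags, 1 - model_probs, "FlexDetect", alpha)
}
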