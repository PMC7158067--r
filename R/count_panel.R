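# Observed/expected count panels on the area x time grid.

#' Construct a count panel
#'
#' Holds observed counts `y` and expected counts `E` on the area-by-time grid.
#' `E[i, t]` is the count expected under reference rates (the Poisson offset);
#' the relative risk is the multiplicative deviation from it.
#'
#' @param y Integer matrix (areas x times) of non-negative observed counts.
#' @param E Numeric matrix of strictly positive expected counts, same shape.
#' @return Object of class `count_panel` with fields `y`, `E`, `n_areas`,
#'   `n_times`.
#' @export
count_panel <- function(y, E) {
  y <- as.matrix(y); E <- as.matrix(E)
  if (!all(dim(y) == dim(E))) stop("y and E must share shape")
  if (anyNA(y) || anyNA(E)) stop("y and E must not contain NA")
  if (any(y < 0) || any(y != round(y))) stop("y must be non-negative integers")
  if (any(E <= 0)) stop("all expected counts must be positive")
  storage.mode(y) <- "double"
  structure(list(y = y, E = E, n_areas = nrow(y), n_times = ncol(y)),
            class = "count_panel")
}

#' @export
print.count_panel <- function(x, ...) {
  cat("count_panel:", x$n_areas, "areas x", x$n_times, "times; total counts",
      sum(x$y), "(total expected", round(sum(x$E), 1), ")\n")
  invisible(x)
}

#' Read a count panel from long-format CSV
#'
#' Expects columns `area` (0-based index), `time` (1-based index), `observed`,
#' `expected` -- the package's interchange format for areal count panels.
#'
#' @param path CSV path.
#' @return A `count_panel`.
#' @export
read_count_panel <- function(path) {
  d <- utils::read.csv(path)
  need <- c("area", "time", "observed", "expected")
  if (!all(need %in% names(d))) stop("panel CSV needs columns ",
                                     paste(need, collapse = ", "))
  n <- max(d$area) + 1L
  Tt <- max(d$time)
  y <- matrix(NA_real_, n, Tt)
  E <- matrix(NA_real_, n, Tt)
  idx <- cbind(d$area + 1L, d$time)
  y[idx] <- d$observed
  E[idx] <- d$expected
  if (anyNA(y) || anyNA(E)) stop("panel CSV does not cover the full grid")
  count_panel(y, E)
}

#' Write a count panel to long-format CSV
#'
#' @param panel A `count_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_panel <- function(panel, path) {
  stopifnot(inherits(panel, "count_panel"))
  d <- data.frame(
    area = rep(seq_len(panel$n_areas) - 1L, times = panel$n_times),
    time = rep(seq_len(panel$n_times), each = panel$n_areas),
    observed = as.vector(panel$y),
    expected = as.vector(panel$E))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
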