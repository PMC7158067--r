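# Area adjacency structures and the intrinsic-CAR quadratic form.
#
# An `area_graph` stores the neighbourhood relation over administrative areas
# ("two areas are neighbours if they share a boundary" in real maps); it is the
# backbone of the ICAR spatial prior used by every model in the package.

#' Construct an area adjacency graph
#'
#' Builds a validated undirected graph over `n_areas` areas. Edges are stored
#' as unordered pairs of 1-based area indices; duplicates and reversed pairs
#' are collapsed. Self-loops are rejected.
#'
#' @param n_areas Positive integer, number of areas.
#' @param edges Two-column integer matrix of area-index pairs (1-based).
#' @param labels Optional character vector of area labels (length `n_areas`).
#' @return An object of class `area_graph` with fields `n_areas`, `edges`,
#'   `neighbor_counts`, `components` (per-area component id) and
#'   `n_components`. Isolated areas (no neighbours) trigger a warning: they
#'   receive no spatial smoothing.
#' @export
area_graph <- function(n_areas, edges, labels = NULL) {
  n_areas <- as.integer(n_areas)
  if (length(n_areas) != 1L || is.na(n_areas) || n_areas < 1L)
    stop("n_areas must be a positive integer")
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- matrix(as.integer(as.matrix(edges)), ncol = 2L)
  }
  if (nrow(edges)) {
    if (anyNA(edges)) stop("edges contain missing values")
    if (any(edges < 1L) || any(edges > n_areas))
      stop("edge indices must lie in 1..n_areas")
    if (any(edges[, 1L] == edges[, 2L]))
      stop("self-loops are not allowed")
    swap <- edges[, 1L] > edges[, 2L]
    edges[swap, ] <- edges[swap, c(2L, 1L), drop = FALSE]
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  deg <- tabulate(c(edges[, 1L], edges[, 2L]), nbins = n_areas)
  comp <- .graph_components(n_areas, edges)
  g <- structure(
    list(n_areas = n_areas, edges = edges, neighbor_counts = deg,
         components = comp$membership, n_components = comp$n,
         labels = labels),
    class = "area_graph")
  if (any(deg == 0L))
    warning(sum(deg == 0L), " isolated area(s): no spatial smoothing there")
  if (comp$n > 1L && all(deg > 0L))
    warning("graph is disconnected (", comp$n, " components)")
  g
}

#' @export
print.area_graph <- function(x, ...) {
  cat("area_graph:", x$n_areas, "areas,", nrow(x$edges), "edges,",
      x$n_components, "component(s); mean degree",
      round(mean(x$neighbor_counts), 2), "\n")
  invisible(x)
}

# Connected components by breadth-first search (vector queue; n is small).
.graph_components <- function(n, edges) {
  adj <- .adjacency_list(n, edges)
  memb <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (memb[s] > 0L) next
    k <- k + 1L
    queue <- s
    memb[s] <- k
    head <- 1L
    while (head <= length(queue)) {
      v <- queue[head]; head <- head + 1L
      nb <- adj[[v]]
      fresh <- nb[memb[nb] == 0L]
      if (length(fresh)) {
        memb[fresh] <- k
        queue <- c(queue, fresh)
      }
    }
  }
  list(membership = memb, n = k)
}

.adjacency_list <- function(n, edges) {
  adj <- rep(list(integer(0)), n)
  if (nrow(edges)) {
    from <- c(edges[, 1L], edges[, 2L])
    to <- c(edges[, 2L], edges[, 1L])
    sp <- split(to, factor(from, levels = seq_len(n)))
    adj <- lapply(sp, as.integer)
  }
  adj
}

# Greedy proper colouring (highest degree first). Areas in one colour class
# are pairwise non-adjacent, so their ICAR full conditionals are independent
# and can be Metropolis-updated as one vectorised block.
.graph_coloring <- function(graph) {
  n <- graph$n_areas
  adj <- .adjacency_list(n, graph$edges)
  col <- integer(n)
  for (v in order(graph$neighbor_counts, decreasing = TRUE)) {
    used <- col[adj[[v]]]
    k <- 1L
    while (k %in% used) k <- k + 1L
    col[v] <- k
  }
  unname(split(seq_len(n), col))
}

#' Validate an area graph
#'
#' Checks the structural invariants of an `area_graph`: symmetric unordered
#' edge set without self-loops, indices in range, and degree bookkeeping
#' consistent with the edge list. Intended both as an internal guard and for
#' auditing graphs assembled by hand.
#'
#' @param graph Object to validate.
#' @return `graph`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_area_graph <- function(graph) {
  if (!inherits(graph, "area_graph")) stop("not an area_graph")
  n <- graph$n_areas
  e <- graph$edges
  if (!is.matrix(e) || ncol(e) != 2L) stop("edges must be a 2-column matrix")
  if (nrow(e)) {
    if (any(e < 1L) || any(e > n)) stop("edge index out of range")
    if (any(e[, 1L] == e[, 2L])) stop("self-loop present")
    key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    if (anyDuplicated(key)) stop("duplicate edges present")
  }
  deg <- tabulate(c(e[, 1L], e[, 2L]), nbins = n)
  if (!identical(as.integer(deg), as.integer(graph$neighbor_counts)))
    stop("neighbor_counts inconsistent with edge list")
  invisible(graph)
}

#' Rook-adjacency lattice graph
#'
#' Regular `n_rows` by `n_cols` grid with horizontal and vertical adjacency, a
#' convenient stand-in for an administrative map in tests and examples.
#'
#' @param n_rows,n_cols Positive integers.
#' @return An `area_graph` with `n_rows * n_cols` areas.
#' @examples
#' build_lattice_graph(3, 3)
#' @export
build_lattice_graph <- function(n_rows, n_cols) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || n_rows < 1L || is.na(n_cols) || n_cols < 1L)
    stop("n_rows and n_cols must be positive integers")
  idx <- function(r, c) (r - 1L) * n_cols + c
  h <- v <- NULL
  if (n_cols > 1L) {
    r <- rep(seq_len(n_rows), each = n_cols - 1L)
    c <- rep(seq_len(n_cols - 1L), times = n_rows)
    h <- cbind(idx(r, c), idx(r, c + 1L))
  }
  if (n_rows > 1L) {
    r <- rep(seq_len(n_rows - 1L), each = n_cols)
    c <- rep(seq_len(n_cols), times = n_rows - 1L)
    v <- cbind(idx(r, c), idx(r + 1L, c))
  }
  area_graph(n_rows * n_cols, rbind(h, v))
}

#' Random irregular planar-style adjacency graph
#'
#' Emulates the adjacency structure of an irregular administrative map (such
#' as the 211 Clinical Commissioning Groups of England) when no boundary file
#' is available. Areas are random points in the unit square; the edge set is
#' the Gabriel graph (which contains the Euclidean minimum spanning tree, so
#' the result is always connected) unioned with each point's three nearest
#' neighbours, symmetrised. Typical mean degree is 4.5-5, in line with real
#' areal maps.
#'
#' @param n_areas Integer >= 3.
#' @param seed Integer seed; the graph is deterministic given `seed`.
#' @return A connected `area_graph`.
#' @export
build_random_planar_graph <- function(n_areas, seed) {
  n <- as.integer(n_areas)
  if (is.na(n) || n < 3L) stop("n_areas must be at least 3")
  with_seed(seed, {
    pts <- cbind(stats::runif(n), stats::runif(n))
    d2 <- as.matrix(stats::dist(pts))^2
    edges <- NULL
    # Gabriel: (i,j) is an edge iff no third point falls in the closed disc
    # with diameter ij, i.e. min_k d2[i,k] + d2[j,k] > d2[i,j].
    for (i in seq_len(n - 1L)) {
      m <- d2[, i] + d2          # m[k, j] = d2[i,k] + d2[j,k]
      m[i, ] <- Inf
      m[cbind(seq_len(n), seq_len(n))] <- Inf
      mins <- apply(m, 2L, min)
      js <- which(mins > d2[i, ] & seq_len(n) > i)
      if (length(js)) edges <- rbind(edges, cbind(i, js))
    }
    # union with symmetrised k-nearest-neighbour edges (k = 3, capped by n-1)
    k <- min(3L, n - 1L)
    dd <- d2
    diag(dd) <- Inf
    nn <- t(apply(dd, 1L, function(r) order(r)[seq_len(k)]))
    knn <- cbind(rep(seq_len(n), k), as.vector(nn))
    area_graph(n, rbind(edges, knn))
  })
}

#' Read an adjacency edge list
#'
#' Reads a CSV edge list with one `i,j` pair per line using 0-based area
#' indices (an optional header line is detected and skipped). Duplicate and
#' reversed pairs are collapsed; self-loops and out-of-range indices are
#' format errors.
#'
#' @param path Path to the edge-list file.
#' @param n_areas Declared number of areas; if `NULL`, inferred as the largest
#'   index plus one (isolated trailing areas then need an explicit value).
#' @param labels_path Optional sidecar CSV `index,label` (0-based index)
#'   mapping area indices to display labels.
#' @return An `area_graph`.
#' @export
read_adjacency <- function(path, n_areas = NULL, labels_path = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty adjacency file: ", path)
  first <- strsplit(lines[[1L]], ",")[[1L]]
  if (any(is.na(suppressWarnings(as.integer(first))))) lines <- lines[-1L]
  if (!length(lines)) stop("adjacency file has no edges: ", path)
  parts <- strsplit(lines, ",")
  if (any(lengths(parts) != 2L)) stop("malformed edge line in ", path)
  ij <- matrix(suppressWarnings(as.integer(unlist(parts))),
               ncol = 2L, byrow = TRUE)
  if (anyNA(ij)) stop("non-integer edge indices in ", path)
  if (any(ij < 0L)) stop("negative area index in ", path)
  if (any(ij[, 1L] == ij[, 2L])) stop("self-loop in ", path)
  if (is.null(n_areas)) n_areas <- max(ij) + 1L
  if (any(ij >= n_areas)) stop("area index >= declared n_areas in ", path)
  labels <- NULL
  if (!is.null(labels_path)) {
    lab <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
    labels <- character(n_areas)
    labels[lab[[1L]] + 1L] <- as.character(lab[[2L]])
  }
  area_graph(n_areas, ij + 1L, labels = labels)
}

#' Write an adjacency edge list
#'
#' Inverse of [read_adjacency()]: one `i,j` pair per line, 0-based, with a
#' header `area_i,area_j`.
#'
#' @param graph An `area_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(graph, path) {
  validate_area_graph(graph)
  e <- graph$edges - 1L
  writeLines(c("area_i,area_j", paste(e[, 1L], e[, 2L], sep = ",")), path)
  invisible(path)
}

#' ICAR pairwise-difference quadratic form
#'
#' Computes `sum over edges (i~j) of (values[i] - values[j])^2`, the quadratic
#' form of the intrinsic conditional autoregressive prior: the ICAR log-density
#' is `-(tau/2) * icar_quadratic_form(theta, graph)` up to constants. Equals
#' `t(v) %*% (D - W) %*% v` for the graph Laplacian, and is invariant to adding
#' a constant to all values (the gauge freedom fixed by sum-to-zero
#' constraints).
#'
#' @param values Numeric vector, one value per area.
#' @param graph An `area_graph`.
#' @return Non-negative scalar.
#' @export
icar_quadratic_form <- function(values, graph) {
  if (!inherits(graph, "area_graph")) stop("graph must be an area_graph")
  if (length(values) != graph$n_areas)
    stop("length(values) must equal graph$n_areas")
  e <- graph$edges
  if (!nrow(e)) return(0)
  sum((values[e[, 1L]] - values[e[, 2L]])^2)
}

# Sparse Laplacian pieces used by the samplers.
.graph_sparse_w <- function(graph) {
  e <- graph$edges
  n <- graph$n_areas
  if (!nrow(e)) return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                            x = numeric(0), dims = c(n, n)))
  Matrix::sparseMatrix(i = c(e[, 1L], e[, 2L]), j = c(e[, 2L], e[, 1L]),
                       x = 1, dims = c(n, n))
}
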