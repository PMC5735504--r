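#' Construct a marker path
#'
#' An ordered sequence of marker indices (a Hamiltonian path, the dummy
#' vertex already removed) together with the recombination fractions of its
#' adjacent edges and their sum.
#'
#' @param order integer vector of marker indices, each exactly once.
#' @param edge_rf numeric vector of length `length(order) - 1` of adjacent
#'   rf values.
#' @param marker_names optional marker names aligned with `order`.
#' @param solver label of the solver tier that produced the path.
#' @return an object of class `marker_path`.
#' @export
marker_path <- function(order, edge_rf = numeric(0), marker_names = NULL,
                        solver = "none") {
  order <- as.integer(order)
  if (anyDuplicated(order)) stop("order must visit each marker exactly once")
  if (length(order) >= 1 && length(edge_rf) != max(length(order) - 1, 0))
    stop("edge_rf must have length |order| - 1")
  structure(list(order = order, edge_rf = as.numeric(edge_rf),
                 cost = sum(edge_rf), marker_names = marker_names,
                 solver = solver),
            class = "marker_path")
}

#' @export
print.marker_path <- function(x, ...) {
  cat(sprintf("marker_path: %d markers, cost %.4f (solver: %s)\n",
              length(x$order), x$cost, x$solver))
  invisible(x)
}

#' Build an integer TSP weight matrix with a dummy vertex
#'
#' Maps a subset of the rf matrix to integer edge weights
#' (`round(scale * rf)`) and appends a dummy vertex with zero-weight edges
#' to every marker. A tour through the dummy corresponds to an open
#' Hamiltonian path over the markers: the solver can close the tour through
#' the dummy without paying the large rf between the path's two ends.
#'
#' @param r an [rf_matrix()].
#' @param subset integer indices of the markers to include (default: all).
#' @param scale integer multiplier from rf fractions to weights
#'   (default 1e5, i.e. rf resolution 1e-5).
#' @return an object of class `weight_matrix` with fields `weights`
#'   (`(s+1) x (s+1)` matrix), `dummy_index`, `scale`, `marker_idx`.
#' @export
build_weight_matrix <- function(r, subset = seq_len(nrow(r$rf)), scale = 1e5) {
  stopifnot(inherits(r, "rf_matrix"))
  subset <- as.integer(subset)
  if (length(subset) == 0) stop("subset must be non-empty")
  if (anyDuplicated(subset)) stop("subset contains duplicate indices")
  if (any(subset < 1 | subset > nrow(r$rf))) stop("subset index out of range")
  if (scale < 1) stop("scale must be >= 1")
  s <- length(subset)
  w <- matrix(0, s + 1, s + 1)
  w[seq_len(s), seq_len(s)] <- round(scale * r$rf[subset, subset, drop = FALSE])
  structure(list(weights = w, size = s + 1L, dummy_index = s + 1L,
                 scale = scale, marker_idx = subset,
                 marker_names = r$marker_names[subset]),
            class = "weight_matrix")
}

# turn a tour (1-based vertex sequence including the dummy) into a
# marker_path in the original rf index space
tour_to_path <- function(tour, w, solver) {
  dpos <- match(w$dummy_index, tour)
  if (length(tour) > 1) {
    tour <- c(tour[-seq_len(dpos)], tour[seq_len(dpos - 1)])
  } else {
    tour <- integer(0)
  }
  ord_local <- tour
  edge_rf <- if (length(ord_local) > 1) {
    w$weights[cbind(ord_local[-length(ord_local)], ord_local[-1])] / w$scale
  } else numeric(0)
  marker_path(w$marker_idx[ord_local], edge_rf,
              marker_names = w$marker_names[ord_local], solver = solver)
}

#' Heuristic Hamiltonian-path solver
#'
#' Multi-start local search in the Lin-Kernighan family: nearest-neighbour
#' construction followed by 2-opt and Or-opt moves over candidate
#' neighbour lists with don't-look bits, optionally chained with
#' double-bridge perturbations. The tour is solved through the dummy vertex
#' and cut there to yield an open path. Deterministic given `seed`.
#'
#' @param w a [build_weight_matrix()] result.
#' @param seed integer seed for the solver's internal random stream.
#' @param n_starts number of nearest-neighbour multi-starts (default 8).
#' @param n_perturb double-bridge perturbation rounds per start (default 0;
#'   the ordering stage uses a larger budget).
#' @param n_candidates candidate-list size (default 12).
#' @return a [marker_path()] whose cost is locally optimal under the move
#'   set.
#' @export
solve_heuristic <- function(w, seed = 0, n_starts = 8, n_perturb = 0,
                            n_candidates = 12) {
  stopifnot(inherits(w, "weight_matrix"))
  if (w$size <= 2) {
    return(tour_to_path(seq_len(w$size), w, solver = "heuristic"))
  }
  tour <- cpp_solve_tour(w$weights, as.integer(n_starts),
                         as.integer(n_perturb), as.numeric(seed),
                         as.integer(n_candidates))
  tour_to_path(tour, w, solver = "heuristic")
}

#' Exact small-instance Hamiltonian-path solver
#'
#' Held-Karp dynamic programming over vertex subsets, anchored at the dummy
#' vertex, guaranteeing the globally optimal path for instances of at most
#' `limit` vertices (markers + dummy). Among cost ties the lexicographically
#' smaller of the path and its reversal is returned.
#'
#' @param w a [build_weight_matrix()] result with `w$size <= limit`.
#' @param limit maximum vertex count (default 18).
#' @return a globally optimal [marker_path()].
#' @export
solve_exact_small <- function(w, limit = 18) {
  stopifnot(inherits(w, "weight_matrix"))
  if (w$size > limit)
    stop(sprintf(paste0("instance has %d vertices, above the exact-solver ",
                        "limit %d; use order_linkage_group() which falls ",
                        "back to the high-budget heuristic"), w$size, limit))
  tour <- cpp_held_karp(w$weights, w$dummy_index - 1L)
  p <- tour_to_path(tour, w, solver = "exact")
  lexico_min_orientation(p)
}

# pick the lexicographically smaller of a path and its reversal (by index)
lexico_min_orientation <- function(p) {
  if (length(p$order) < 2) return(p)
  fwd <- p$order; bwd <- rev(p$order)
  d <- which(fwd != bwd)
  if (length(d) && bwd[d[1]] < fwd[d[1]]) {
    marker_path(bwd, rev(p$edge_rf),
                marker_names = if (is.null(p$marker_names)) NULL else rev(p$marker_names),
                solver = p$solver)
  } else p
}

#' Cost of a marker path under an rf matrix
#'
#' @param p a [marker_path()].
#' @param r an [rf_matrix()].
#' @return sum of rf over adjacent pairs of `p$order`.
#' @export
path_cost <- function(p, r) {
  stopifnot(inherits(p, "marker_path"), inherits(r, "rf_matrix"))
  if (length(p$order) < 2) return(0)
  if (any(p$order < 1 | p$order > nrow(r$rf)))
    stop("path index out of range for rf matrix")
  sum(r$rf[cbind(p$order[-length(p$order)], p$order[-1])])
}

#' Write a weight matrix in TSPLIB format
#'
#' Emits a symmetric TSPLIB instance (`EDGE_WEIGHT_TYPE: EXPLICIT`,
#' `EDGE_WEIGHT_FORMAT: FULL_MATRIX`) so external solvers such as LKH or
#' Concorde can be run on the same instance if desired; nothing in the
#' package depends on them.
#'
#' @param w a [build_weight_matrix()] result.
#' @param path output file path.
#' @param name instance name for the header.
#' @export
write_tsplib <- function(w, path, name = "salesmap") {
  stopifnot(inherits(w, "weight_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("NAME: %s", name),
    "TYPE: TSP",
    sprintf("DIMENSION: %d", w$size),
    "EDGE_WEIGHT_TYPE: EXPLICIT",
    "EDGE_WEIGHT_FORMAT: FULL_MATRIX",
    "EDGE_WEIGHT_SECTION"), con)
  writeLines(apply(w$weights, 1, function(row)
    paste(format(row, scientific = FALSE, trim = TRUE), collapse = " ")), con)
  writeLines("EOF", con)
  invisible(path)
}
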