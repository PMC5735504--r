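#' Order the markers of one linkage group
#'
#' Uses the exact Held-Karp solver when the instance (markers + dummy) fits
#' within `params$hk_limit`, in which case the returned order is the proven
#' optimum; otherwise falls back to the heuristic solver with the larger
#' ordering budget (`order_n_starts` multi-starts, `order_n_perturb`
#' double-bridge chains), in which case the order is the best found under
#' that fixed, seeded budget. The dummy-vertex tour-to-path transformation
#' is applied in both cases.
#'
#' @param group integer vector of marker indices.
#' @param r an [rf_matrix()].
#' @param params a [pipeline_params()].
#' @param seed solver seed; defaults to `params$seed`.
#' @return a [marker_path()] with `solver` set to `"exact"` or
#'   `"heuristic"`.
#' @export
order_linkage_group <- function(group, r, params, seed = params$seed) {
  stopifnot(inherits(r, "rf_matrix"), inherits(params, "pipeline_params"))
  group <- as.integer(group)
  if (length(group) == 0) stop("group must be non-empty")
  w <- build_weight_matrix(r, sort(group), scale = params$scale)
  if (w$size <= params$hk_limit) {
    solve_exact_small(w, limit = params$hk_limit)
  } else {
    solve_heuristic(w, seed = seed, n_starts = params$order_n_starts,
                    n_perturb = params$order_n_perturb)
  }
}

#' Canonical orientation of a marker path
#'
#' Linkage-group orientation is biologically arbitrary; for reproducible
#' output a path is reversed when its last marker name precedes its first
#' lexicographically. Idempotent; cost-invariant.
#'
#' @param p a [marker_path()] with `marker_names` set.
#' @return the path or its reversal.
#' @export
canonical_orientation <- function(p) {
  stopifnot(inherits(p, "marker_path"))
  n <- length(p$order)
  if (n < 2 || is.null(p$marker_names)) return(p)
  if (p$marker_names[n] < p$marker_names[1]) {
    marker_path(rev(p$order), rev(p$edge_rf),
                marker_names = rev(p$marker_names), solver = p$solver)
  } else p
}

#' Cumulative map positions from adjacent recombination fractions
#'
#' Converts adjacent rf values to additive centimorgan distances and
#' accumulates them from 0. Distances: Haldane `-50 log(1 - 2r)`, Kosambi
#' `25 log((1+2r)/(1-2r))`, or `100 r` for a plain rf-sum map.
#'
#' @param p a [marker_path()].
#' @param map_function `"haldane"` (default), `"kosambi"`, or `"none"`.
#' @return numeric vector of non-decreasing positions, starting at 0.
#' @export
map_positions <- function(p, map_function = c("haldane", "kosambi", "none")) {
  stopifnot(inherits(p, "marker_path"))
  map_function <- match.arg(map_function)
  rf <- p$edge_rf
  if (map_function != "none" && any(rf >= 0.5))
    stop("adjacent rf of 0.5 gives infinite map distance; re-split the group")
  d <- switch(map_function,
              haldane = -50 * log(1 - 2 * rf),
              kosambi = 25 * log((1 + 2 * rf) / (1 - 2 * rf)),
              none = 100 * rf)
  cumsum(c(0, d))
}

#' Construct a linkage map
#'
#' The pipeline's final product: for each linkage group, the ordered marker
#' names, the rf of each marker to its predecessor, and cumulative cM
#' positions.
#'
#' @param groups list of [marker_path()] objects (with `marker_names`).
#' @param map_function mapping function passed to [map_positions()].
#' @return an object of class `linkage_map`: a data.frame with columns
#'   `group`, `order_index`, `marker`, `rf_to_prev`, `position_cM`, plus a
#'   `solvers` attribute recording each group's solver tier.
#' @export
linkage_map <- function(groups, map_function = "haldane") {
  rows <- lapply(seq_along(groups), function(gi) {
    p <- groups[[gi]]
    pos <- map_positions(p, map_function)
    data.frame(group = gi,
               order_index = seq_along(p$order),
               marker = p$marker_names,
               rf_to_prev = c(NA_real_, p$edge_rf),
               position_cM = pos,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (anyDuplicated(df$marker)) stop("a marker appears in more than one group")
  structure(df, class = c("linkage_map", "data.frame"),
            solvers = vapply(groups, function(p) p$solver, ""))
}

#' @export
print.linkage_map <- function(x, ...) {
  sizes <- table(x$group)
  spans <- tapply(x$position_cM, x$group, max)
  cat(sprintf("linkage_map: %d groups, %d markers\n",
              length(sizes), nrow(x)))
  for (g in names(sizes))
    cat(sprintf("  group %s: %d markers, %.1f cM\n", g, sizes[[g]], spans[[g]]))
  invisible(x)
}

#' Write a linkage map to CSV
#'
#' Columns `group`, `order_index`, `marker`, `rf_to_prev`, `position_cM`.
#'
#' @param map a [linkage_map()].
#' @param path output path.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "linkage_map"))
  utils::write.csv(as.data.frame(map), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Read a linkage map from CSV
#'
#' Validates the [write_map()] layout: required columns, and non-decreasing
#' positions starting at 0 within each group.
#'
#' @param path CSV path.
#' @return a `linkage_map` data.frame (solver provenance is not persisted).
#' @export
read_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "order_index", "marker", "rf_to_prev", "position_cM")
  if (!all(need %in% names(df)))
    stop("malformed map file: expected columns ", paste(need, collapse = ", "))
  for (g in unique(df$group)) {
    pos <- df$position_cM[df$group == g]
    if (length(pos) == 0 || abs(pos[1]) > 1e-9 || is.unsorted(pos))
      stop(sprintf("non-monotone or non-zero-based positions in group %s", g))
  }
  structure(df, class = c("linkage_map", "data.frame"))
}
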