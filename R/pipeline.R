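#' Build a linkage map end to end
#'
#' Runs the full pipeline: marker pre-filtering, recombination-frequency
#' estimation (skipped when an [rf_matrix()] is supplied), cutoff inflation,
#' MST decomposition into initial clusters, TSP-path-guided splitting,
#' three-stage merging, and within-group ordering with cM positions.
#'
#' @param genotypes a [genotype_matrix()], or `NULL` when `rf` is given.
#' @param rf an [rf_matrix()] estimated elsewhere, or `NULL`.
#' @param k expected number of linkage groups.
#' @param params a [pipeline_params()]; built from `k` and `...` if absent.
#' @param map_function mapping function for positions (default
#'   `"haldane"`).
#' @param similarity_threshold,max_het_fraction passed to
#'   [filter_markers()].
#' @param order_groups set `FALSE` to stop after merging (linkage-group
#'   identification only).
#' @param ... further arguments to [pipeline_params()].
#' @return list with `map` (a [linkage_map()], or `NULL` when
#'   `order_groups = FALSE`), `groups` (merged [cluster_set()]),
#'   `decisions` (merge log), `rf` (the inflated [rf_matrix()]),
#'   `filter_report`.
#' @export
build_linkage_map <- function(genotypes = NULL, rf = NULL, k,
                              params = NULL, map_function = "haldane",
                              similarity_threshold = 1.0,
                              max_het_fraction = 0.10,
                              order_groups = TRUE, ...) {
  if (is.null(genotypes) == is.null(rf))
    stop("supply exactly one of genotypes or rf")
  if (is.null(params)) params <- pipeline_params(k = k, ...)
  filter_report <- NULL
  if (!is.null(genotypes)) {
    fl <- filter_markers(genotypes, similarity_threshold, max_het_fraction)
    filter_report <- fl$report
    r <- estimate_rf(fl$genotypes)
  } else {
    r <- rf
  }
  r <- apply_cutoff(r, params$cutoff)

  cs <- initial_clusters(r, params)
  split_list <- list()
  for (ci in seq_along(cs$clusters)) {
    split_list <- c(split_list,
                    split_cluster_by_path(cs$clusters[[ci]], r,
                                          break_threshold = params$break_threshold,
                                          seed = params$seed * 7919L + ci,
                                          params = params))
  }
  cs_split <- cluster_set(split_list, stage = "split", n_markers = cs$n_markers)
  merged <- merge_clusters(cs_split, r, params)

  map <- NULL
  if (order_groups) {
    paths <- lapply(seq_along(merged$clusters$clusters), function(gi) {
      p <- order_linkage_group(merged$clusters$clusters[[gi]], r, params,
                               seed = params$seed * 104729L + gi)
      canonical_orientation(p)
    })
    map <- linkage_map(paths, map_function = map_function)
  }
  list(map = map, groups = merged$clusters, decisions = merged$decisions,
       rf = r, filter_report = filter_report)
}
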