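#' Pipeline parameters
#'
#' Collects the tunable knobs of the clustering/merging/ordering pipeline.
#'
#' @param k expected number of linkage groups (chromosomes); the pipeline
#'   is strongly biased toward this prior.
#' @param cutoff rf inflation threshold for [apply_cutoff()] (default 0.4).
#' @param cut_multiplier initial MST cut count is `ceiling(cut_multiplier * k)`
#'   (default 1.5).
#' @param break_threshold maximum rf tolerated between path-adjacent markers
#'   within one cluster (default 0.35); larger adjacencies split the
#'   cluster and block merges.
#' @param direct_threshold stage-1 merge threshold on the minimum
#'   inter-cluster rf (default 0.15).
#' @param scale integer weight scale for the TSP instances.
#' @param hk_limit exact-solver vertex limit (markers + dummy; default 18).
#' @param n_starts,n_perturb heuristic solver budget (multi-starts and
#'   double-bridge chains) used during clustering and merging; the
#'   perturbation rounds keep path flaws from inflating the merge
#'   statistic J.
#' @param order_n_starts,order_n_perturb heuristic solver budget for final
#'   ordering of groups above the exact limit.
#' @param seed integer seed fanned out to every stochastic step.
#' @return an object of class `pipeline_params`.
#' @export
pipeline_params <- function(k, cutoff = 0.4, cut_multiplier = 1.5,
                            break_threshold = 0.35, direct_threshold = 0.15,
                            scale = 1e5, hk_limit = 18,
                            n_starts = 8, n_perturb = 10,
                            order_n_starts = 12, order_n_perturb = 30,
                            seed = 0) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1)
    stop("k must be a positive integer")
  for (th in c(cutoff, break_threshold, direct_threshold))
    if (th <= 0 || th > 0.5) stop("thresholds must lie in (0, 0.5]")
  structure(list(k = as.integer(k), cutoff = cutoff,
                 cut_multiplier = cut_multiplier,
                 break_threshold = break_threshold,
                 direct_threshold = direct_threshold,
                 scale = scale, hk_limit = as.integer(hk_limit),
                 n_starts = as.integer(n_starts),
                 n_perturb = as.integer(n_perturb),
                 order_n_starts = as.integer(order_n_starts),
                 order_n_perturb = as.integer(order_n_perturb),
                 seed = as.integer(seed)),
            class = "pipeline_params")
}

#' Construct a cluster set
#'
#' A partition of marker indices into candidate linkage groups at some
#' pipeline stage.
#'
#' @param clusters list of pairwise-disjoint integer vectors.
#' @param stage one of `"initial"`, `"split"`, `"merged"`.
#' @param n_markers total marker count of the underlying rf matrix.
#' @return an object of class `cluster_set`.
#' @export
cluster_set <- function(clusters, stage = c("initial", "split", "merged"),
                        n_markers = NULL) {
  stage <- match.arg(stage)
  clusters <- lapply(clusters, function(x) sort(as.integer(x)))
  all_idx <- unlist(clusters)
  if (anyDuplicated(all_idx)) stop("clusters must be pairwise disjoint")
  structure(list(clusters = clusters, stage = stage,
                 n_markers = if (is.null(n_markers)) length(all_idx) else n_markers),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sz <- lengths(x$clusters)
  cat(sprintf("cluster_set (%s): %d clusters over %d markers; sizes: %s\n",
              x$stage, length(sz), sum(sz),
              paste(sort(sz, decreasing = TRUE), collapse = ", ")))
  invisible(x)
}

#' Minimum significant cluster size
#'
#' `s = m / (2k)`: a cluster is "significant" when it holds at least half
#' the average chromosome's share of markers, penalizing fragments while
#' allowing sizeable variation in chromosome size.
#'
#' @param m total marker count.
#' @param k expected linkage-group count.
#' @return the real value `m / (2 * k)`.
#' @export
min_cluster_size <- function(m, k) {
  if (k < 1) stop("k must be at least 1")
  if (m < 1) stop("m must be at least 1")
  m / (2 * k)
}

#' Minimum spanning tree of the marker graph
#'
#' Kruskal's algorithm on the complete rf graph with edges considered in
#' order (rf, smaller index, larger index), which fixes the tree
#' deterministically under ties.
#'
#' @param r an [rf_matrix()].
#' @return data.frame with columns `i`, `j` (1-based, `i < j`) and `rf`,
#'   exactly `m - 1` rows.
#' @export
build_mst <- function(r) {
  stopifnot(inherits(r, "rf_matrix"))
  m <- nrow(r$rf)
  if (m == 1) return(data.frame(i = integer(0), j = integer(0), rf = numeric(0)))
  res <- cpp_kruskal_mst(r$rf)
  data.frame(i = res$i, j = res$j, rf = res$rf)
}

# connected components among 1..m given an edge list; returns list of
# integer vectors ordered by smallest member
components_from_edges <- function(m, ei, ej) {
  parent <- seq_len(m)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_along(ei)) {
    a <- find(ei[e]); b <- find(ej[e])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(m), find, 1L)
  comps <- split(seq_len(m), roots)
  comps <- comps[order(vapply(comps, min, 1L))]
  unname(comps)
}

#' Initial clusters by cutting the MST
#'
#' Builds the minimum spanning tree, removes its `ceiling(cut_multiplier*k)`
#' largest-rf edges, and — while fewer than `k` components reach the
#' significant size `s = m/(2k)` — keeps removing the next-largest remaining
#' tree edge. Deliberately over-cuts: the merge stage later reassembles
#' fragments. All components, including sub-significant ones, are returned.
#'
#' @param r an [rf_matrix()] (after [apply_cutoff()]).
#' @param params a [pipeline_params()].
#' @return a [cluster_set()] with `stage = "initial"`.
#' @export
initial_clusters <- function(r, params) {
  stopifnot(inherits(r, "rf_matrix"), inherits(params, "pipeline_params"))
  m <- nrow(r$rf)
  k <- params$k
  if (m < k) stop("fewer markers than expected linkage groups")
  mst <- build_mst(r)
  if (nrow(mst) == 0)
    return(cluster_set(list(1L), stage = "initial", n_markers = 1L))
  if (all(mst$rf == 0))
    warning("all MST edges have rf 0; markers form a single degenerate cluster")
  s <- min_cluster_size(m, k)
  # order tree edges by decreasing rf, ties by (min index, max index)
  ord <- order(-mst$rf, mst$i, mst$j)
  n_cut <- min(ceiling(params$cut_multiplier * k), nrow(mst))
  best_sig <- -1L
  best_cut <- n_cut
  repeat {
    keep <- ord[-seq_len(n_cut)]
    comps <- components_from_edges(m, mst$i[keep], mst$j[keep])
    n_sig <- sum(lengths(comps) >= s)
    if (n_sig > best_sig) { best_sig <- n_sig; best_cut <- n_cut }
    if (n_sig >= k || n_cut >= nrow(mst)) break
    n_cut <- n_cut + 1
  }
  if (n_sig < k) {
    # additional cuts only fragmented further; fall back to the cut count
    # that produced the most significant clusters and let the merge stage
    # reassemble the rest
    warning(sprintf(
      "exhausted MST edges with only %d significant clusters (k = %d); reverting to %d cuts",
      best_sig, k, best_cut))
    keep <- ord[-seq_len(best_cut)]
    comps <- components_from_edges(m, mst$i[keep], mst$j[keep])
  }
  cluster_set(comps, stage = "initial", n_markers = m)
}

#' Split a cluster at large rf jumps along its TSP path
#'
#' Runs the heuristic Hamiltonian-path solver on the cluster and cuts the
#' path wherever two path-adjacent markers have rf above `break_threshold`:
#' a large jump in an otherwise smooth path indicates markers from more
#' than one linkage group. Returns the contiguous path segments
#' (singletons allowed).
#'
#' @param cluster integer vector of marker indices.
#' @param r an [rf_matrix()].
#' @param break_threshold rf above which the path is cut.
#' @param seed heuristic solver seed.
#' @param params optional [pipeline_params()] for solver budget.
#' @return list of integer vectors, each a sub-cluster.
#' @export
split_cluster_by_path <- function(cluster, r, break_threshold = 0.35,
                                  seed = 0, params = NULL) {
  cluster <- as.integer(cluster)
  if (length(cluster) == 0) stop("cluster must be non-empty")
  if (length(cluster) <= 2) {
    if (length(cluster) == 2 &&
        r$rf[cluster[1], cluster[2]] > break_threshold)
      return(list(cluster[1], cluster[2]))
    return(list(cluster))
  }
  n_starts <- if (is.null(params)) 8 else params$n_starts
  n_perturb <- if (is.null(params)) 10 else params$n_perturb
  w <- build_weight_matrix(r, cluster,
                           scale = if (is.null(params)) 1e5 else params$scale)
  p <- solve_heuristic(w, seed = seed, n_starts = n_starts,
                       n_perturb = n_perturb)
  jumps <- which(p$edge_rf > break_threshold)
  bounds <- c(0, jumps, length(p$order))
  lapply(seq_len(length(bounds) - 1), function(b)
    p$order[(bounds[b] + 1):bounds[b + 1]])
}
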