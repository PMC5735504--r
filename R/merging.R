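#' Merge split clusters into final linkage groups
#'
#' Three-stage merge, processing clusters smallest-first (ties by cluster
#' id), on the logic that a small fragment is the most likely candidate for
#' absorption into a larger group:
#'
#' * Stage 1 (direct): with `link(x, y)` the minimum rf over inter-cluster
#'   marker pairs, merge `x` into its best candidate `y*` when
#'   `link(x, y*) <= direct_threshold` and `link(x, y*)` is at most half
#'   the second-best link.
#' * Stage 2 (path): for each candidate `y`, solve the heuristic
#'   Hamiltonian path on `x` united with `y` and record `J(x, y)`, the
#'   maximum adjacent rf anywhere in that path; merge when the smallest
#'   `J` is less than half the second smallest.
#' * Stage 3 (reciprocal): if `x`'s best candidate by `J` is `y*` and
#'   running the same scan from `y*` returns `x` as its best candidate,
#'   merge.
#'
#' Every merge additionally requires the merged path to contain no adjacent
#' rf above `break_threshold` (the split criterion), so no merge can ever
#' recreate a cluster that the split stage would cut. A cluster passing no
#' stage is a complete linkage group. After every merge the cluster list
#' and size ordering are refreshed.
#'
#' @param cs a [cluster_set()] with `stage = "split"`.
#' @param r an [rf_matrix()].
#' @param params a [pipeline_params()].
#' @return list with `clusters` (a [cluster_set()], `stage = "merged"`) and
#'   `decisions` (data.frame log of every decision with its evidence).
#' @export
merge_clusters <- function(cs, r, params) {
  stopifnot(inherits(cs, "cluster_set"), inherits(r, "rf_matrix"),
            inherits(params, "pipeline_params"))
  clus <- cs$clusters
  ids <- seq_along(clus)
  next_id <- length(clus) + 1L
  processed <- logical(length(clus))
  decisions <- list()
  seed_counter <- 0L

  solve_union <- function(x_idx, y_idx) {
    seed_counter <<- seed_counter + 1L
    members <- c(clus[[x_idx]], clus[[y_idx]])
    if (length(members) == 2) {
      return(r$rf[members[1], members[2]])
    }
    w <- build_weight_matrix(r, sort(members), scale = params$scale)
    p <- solve_heuristic(w, seed = params$seed * 1000003L + seed_counter,
                         n_starts = params$n_starts,
                         n_perturb = params$n_perturb)
    max(p$edge_rf)
  }

  link_rf <- function(x_idx, y_idx)
    min(r$rf[clus[[x_idx]], clus[[y_idx]], drop = FALSE])

  # best candidate of x by the stage-2 J statistic; returns index and J values
  best_by_path <- function(x_idx) {
    cand <- setdiff(seq_along(clus), x_idx)
    J <- vapply(cand, function(y) solve_union(x_idx, y), 0)
    o <- order(J, ids[cand])
    list(cand = cand[o], J = J[o])
  }

  record <- function(source, target, stage, evidence) {
    decisions[[length(decisions) + 1L]] <<- data.frame(
      source_cluster = source,
      target_cluster = if (is.null(target)) NA_integer_ else target,
      stage = stage, evidence = evidence, stringsAsFactors = FALSE)
  }

  do_merge <- function(x_idx, y_idx) {
    merged <- sort(c(clus[[x_idx]], clus[[y_idx]]))
    clus[[y_idx]] <<- merged
    ids[y_idx] <<- next_id
    next_id <<- next_id + 1L
    processed[y_idx] <<- FALSE
    clus[x_idx] <<- NULL
    ids <<- ids[-x_idx]
    processed <<- processed[-x_idx]
  }

  repeat {
    todo <- which(!processed)
    if (length(todo) == 0) break
    if (length(clus) == 1) {
      record(ids[1], NULL, "standalone", "single cluster")
      processed[1] <- TRUE
      next
    }
    x <- todo[order(lengths(clus[todo]), ids[todo])][1]
    cand <- setdiff(seq_along(clus), x)
    links <- vapply(cand, function(y) link_rf(x, y), 0)
    lo <- order(links, ids[cand])
    y1 <- cand[lo[1]]; l1 <- links[lo[1]]
    l2 <- if (length(lo) > 1) links[lo[2]] else Inf

    merged_here <- FALSE
    # stage 1: direct merge on unambiguous small link rf
    if (l1 <= params$direct_threshold && l1 <= 0.5 * l2) {
      J1 <- solve_union(x, y1)
      if (J1 <= params$break_threshold) {
        record(ids[x], ids[y1], "direct",
               sprintf("link=%.4f second=%.4f Jmax=%.4f", l1, l2, J1))
        do_merge(x, y1)
        merged_here <- TRUE
      }
    }
    # stage 2: pairwise path merge on unambiguous J
    if (!merged_here) {
      bp <- best_by_path(x)
      Jbest <- bp$J[1]; ybest <- bp$cand[1]
      Jsecond <- if (length(bp$J) > 1) bp$J[2] else Inf
      if (Jbest <= params$break_threshold && Jbest < 0.5 * Jsecond) {
        record(ids[x], ids[ybest], "path",
               sprintf("Jbest=%.4f Jsecond=%.4f", Jbest, Jsecond))
        do_merge(x, ybest)
        merged_here <- TRUE
      } else if (Jbest <= params$break_threshold) {
        # stage 3: reciprocal best-candidate match
        bp_y <- best_by_path(ybest)
        if (bp_y$cand[1] == x) {
          record(ids[x], ids[ybest], "reciprocal",
                 sprintf("Jxy=%.4f Jyx=%.4f", Jbest, bp_y$J[1]))
          do_merge(x, ybest)
          merged_here <- TRUE
        }
      }
    }
    if (!merged_here) {
      record(ids[x], NULL, "standalone",
             sprintf("link=%.4f", l1))
      processed[x] <- TRUE
    }
  }

  out <- cluster_set(clus, stage = "merged", n_markers = cs$n_markers)
  list(clusters = out,
       decisions = do.call(rbind, decisions))
}

#' Number of linkage groups in a merged cluster set
#'
#' @param cs a [cluster_set()] with `stage = "merged"`.
#' @return the count of clusters, the pipeline's `c` statistic.
#' @export
count_groups <- function(cs) {
  stopifnot(inherits(cs, "cluster_set"))
  length(cs$clusters)
}
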