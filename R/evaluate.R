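#' Erroneous marker pairs between an estimated and the true order
#'
#' Counts the pairs of markers whose relative order in the estimated map
#' contradicts their true order — an inversion count of the true ranks read
#' in estimated order, computed by merge sort in O(n log n). Because
#' linkage-group orientation is arbitrary, the count is minimized over the
#' two orientations of the estimated order: a wholly reversed but
#' internally correct group scores 0.
#'
#' @param true_ranks named numeric vector: each marker's true position (or
#'   rank) within its chromosome.
#' @param est_order character vector of marker names in estimated order;
#'   all must be present in `true_ranks`.
#' @return inversion count (non-negative number).
#' @export
erroneous_pairs <- function(true_ranks, est_order) {
  missing <- setdiff(est_order, names(true_ranks))
  if (length(missing))
    stop("markers absent from truth: ", paste(utils::head(missing, 3), collapse = ", "))
  seq_ranks <- rank(unname(true_ranks[est_order]), ties.method = "first")
  fwd <- cpp_count_inversions(as.integer(seq_ranks))
  n <- length(seq_ranks)
  bwd <- n * (n - 1) / 2 - fwd  # reversal flips every discordant/concordant pair
  min(fwd, bwd)
}

#' Rank correlation between true and estimated marker order
#'
#' Absolute Spearman correlation between estimated rank and true rank,
#' computed within each linkage group and combined across groups weighted
#' by group size. The absolute value makes group orientation irrelevant.
#' Groups of fewer than two markers contribute nothing.
#'
#' @param true_positions named numeric vector of true positions.
#' @param est_orders either a character vector (one group) or a list of
#'   character vectors (marker names in estimated order, one per group).
#' @return weighted absolute Spearman coefficient in `[0, 1]` (`NA` if no
#'   group is scorable).
#' @export
order_correlation <- function(true_positions, est_orders) {
  if (!is.list(est_orders)) est_orders <- list(est_orders)
  num <- 0; den <- 0
  for (ord in est_orders) {
    if (length(ord) < 2) next
    tp <- true_positions[ord]
    if (anyNA(tp)) stop("markers absent from truth")
    rho <- stats::cor(seq_along(ord), tp, method = "spearman")
    num <- num + length(ord) * abs(rho)
    den <- den + length(ord)
  }
  if (den == 0) return(NA_real_)
  num / den
}

#' Score a linkage map against the simulated truth
#'
#' Each estimated group is assigned to the true chromosome contributing
#' the plurality of its markers. Markers from other chromosomes are
#' excluded from that group's inversion count (they are reported through
#' `group_purity` instead, keeping `E` a pure ordering statistic). Reports
#' the total and per-group erroneous pairs `E`, the linkage-group count
#' `c`, the size-weighted absolute Spearman correlation, and the fraction
#' of pure groups.
#'
#' @param map a [linkage_map()].
#' @param truth a [make_true_map()] result.
#' @return an object of class `eval_report`: list with `E`, `c`,
#'   `per_group_E`, `order_correlation`, `group_purity`.
#' @export
evaluate_solution <- function(map, truth) {
  stopifnot(inherits(map, "linkage_map"), inherits(truth, "true_map"))
  tt <- truth_table(truth)
  chrom_of <- stats::setNames(tt$chromosome, tt$marker)
  pos_of <- stats::setNames(tt$position_cM, tt$marker)
  missing <- setdiff(map$marker, tt$marker)
  if (length(missing))
    stop("map contains markers absent from truth: ",
         paste(utils::head(missing, 3), collapse = ", "))
  groups <- split(map$marker, map$group)
  per_E <- numeric(length(groups))
  pure <- logical(length(groups))
  cor_orders <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    ord <- groups[[gi]]
    chroms <- chrom_of[ord]
    plurality <- names(which.max(table(chroms)))
    own <- ord[chroms == plurality]
    pure[gi] <- all(chroms == plurality)
    per_E[gi] <- if (length(own) > 1)
      erroneous_pairs(pos_of[own], own) else 0
    cor_orders[[gi]] <- own
  }
  structure(list(
    E = sum(per_E),
    c = length(groups),
    per_group_E = per_E,
    order_correlation = order_correlation(pos_of, cor_orders),
    group_purity = mean(pure)), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: c = %d groups, E = %g erroneous pairs\n", x$c, x$E))
  cat(sprintf("  order correlation: %.5f  group purity: %.3f\n",
              x$order_correlation, x$group_purity))
  invisible(x)
}
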