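#' Construct a recombination-frequency matrix object
#'
#' The central object of the pipeline: a symmetric matrix of pairwise
#' recombination frequencies in `[0, 0.5]`, zero on the diagonal, together
#' with a `support` matrix counting the individuals that informed each entry.
#'
#' @param rf symmetric numeric matrix of recombination fractions.
#' @param marker_names marker names (defaults to rownames of `rf`).
#' @param support matrix of comparable-individual counts (optional).
#' @return an object of class `rf_matrix`.
#' @export
rf_matrix <- function(rf, marker_names = rownames(rf), support = NULL) {
  rf <- as.matrix(rf)
  if (nrow(rf) != ncol(rf)) stop("rf matrix must be square")
  if (is.null(marker_names)) marker_names <- paste0("M", seq_len(nrow(rf)))
  if (max(abs(rf - t(rf))) > 1e-9) stop("rf matrix must be symmetric")
  if (any(rf < 0 | rf > 0.5 + 1e-12)) stop("rf entries must lie in [0, 0.5]")
  if (any(abs(diag(rf)) > 1e-12)) stop("rf diagonal must be zero")
  diag(rf) <- 0
  rf <- (rf + t(rf)) / 2  # exact symmetry
  dimnames(rf) <- list(marker_names, marker_names)
  if (is.null(support)) support <- matrix(NA_real_, nrow(rf), ncol(rf))
  structure(list(rf = rf, support = support, marker_names = as.character(marker_names)),
            class = "rf_matrix")
}

#' @export
print.rf_matrix <- function(x, ...) {
  off <- x$rf[upper.tri(x$rf)]
  cat(sprintf("rf_matrix: %d markers; off-diagonal rf in [%.3f, %.3f], median %.3f\n",
              nrow(x$rf), min(off), max(off), stats::median(off)))
  invisible(x)
}

#' @export
dim.rf_matrix <- function(x) dim(x$rf)

# shared missing-midpoint estimator on a +/-1/0 encoding:
# val[i,j] = +1/-1 for the two states, 0 for missing. For each pair,
# c = both observed, d = disagreements among those, u = n - c individuals
# with at least one missing call. The attainable rf range is
# [d/(c+u), (d+u)/(c+u)]; its midpoint is (d + u/2)/(c+u) = (d + u/2)/n.
rf_from_signs <- function(val, marker_names) {
  n_ind <- ncol(val)
  if (n_ind < 1) stop("undefined rf: no individuals")
  obs <- (val != 0) * 1
  c_mat <- tcrossprod(obs)                 # both non-missing
  s_mat <- tcrossprod(val)                 # matches - mismatches
  d_mat <- (c_mat - s_mat) / 2
  u_mat <- n_ind - c_mat
  rf <- (d_mat + u_mat / 2) / n_ind
  rf <- pmin(rf, 0.5)
  diag(rf) <- 0
  rf_matrix(rf, marker_names, support = c_mat)
}

#' Recombination frequencies for homozygous designs
#'
#' Direct mismatch-count estimator for populations scored `A`/`B`
#' (recombinant inbred lines by selfing, doubled haploids), with the
#' missing-data midpoint adjustment: for a pair with `d` disagreements among
#' `c` mutually observed individuals and `u` individuals with a missing
#' call, the reported rf is the midpoint `(d + u/2)/(c + u)` of the
#' attainable range `[d/(c+u), (d+u)/(c+u)]`, clamped to at most 0.5. With
#' no missing data this is the plain fraction `d/c`. Note the rf of a RIL
#' population is the line-level recombinant fraction `R = 2r/(1+2r)`, not
#' the per-meiosis `r`.
#'
#' @param g a [genotype_matrix()] with calls in `{A, B}` (any residual `H`
#'   is recoded to missing with a warning).
#' @return an [rf_matrix()]; `support` holds the per-pair count of mutually
#'   observed individuals.
#' @export
rf_homozygous <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  calls <- g$calls
  if (any(calls == "H", na.rm = TRUE)) {
    warning("H calls present in a homozygous design; recoding to missing")
    calls[calls == "H"] <- NA_character_
  }
  val <- matrix(0, nrow(calls), ncol(calls))
  val[calls == "A"] <- 1
  val[calls == "B"] <- -1
  val[is.na(calls)] <- 0
  rf_from_signs(val, rownames(g$calls))
}

#' Recombination frequencies for a backcross
#'
#' In a backcross to parent A the offspring are `A` or `H` at every locus
#' and the recombinant fraction between two loci is estimated directly as
#' the fraction of individuals with discordant calls, with the same
#' missing-data midpoint adjustment as [rf_homozygous()].
#'
#' @param g a [genotype_matrix()] with calls in `{A, H}`.
#' @return an [rf_matrix()].
#' @export
rf_backcross <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  calls <- g$calls
  if (any(calls == "B", na.rm = TRUE))
    stop("backcross calls must be in {A, H}")
  val <- matrix(0, nrow(calls), ncol(calls))
  val[calls == "A"] <- 1
  val[calls == "H"] <- -1
  val[is.na(calls)] <- 0
  rf_from_signs(val, rownames(g$calls))
}

# F2 two-locus genotype probability table (rows/cols = AA,AB,BB at the two
# loci). Gamete haplotypes: parental (1-r)/2 each, recombinant r/2 each;
# an offspring is two independent gametes.
f2_table <- function(r) {
  p <- (1 - r) / 2; q <- r / 2
  # haplotype probs: AA=p, BB=p, AB=q, BA=q (locus1,locus2)
  # genotype = unordered pair of haplotypes
  tab <- matrix(0, 3, 3)
  hap <- rbind(c(1, 1, p), c(1, 2, q), c(2, 1, q), c(2, 2, p))
  for (i in 1:4) for (j in 1:4) {
    g1 <- hap[i, 1] + hap[j, 1] - 1  # 1=AA,2=AB,3=BB at locus 1
    g2 <- hap[i, 2] + hap[j, 2] - 1
    tab[g1, g2] <- tab[g1, g2] + hap[i, 3] * hap[j, 3]
  }
  tab
}

#' Recombination frequencies for an F2 intercross by EM
#'
#' Maximum-likelihood recombination fractions for codominant markers in an
#' F2, fitted pairwise by expectation-maximization on the 3x3 table of joint
#' genotype counts (individuals missing either call are dropped for that
#' pair). The only latent quantity is the recombinant-gamete count of the
#' double heterozygote class, whose expectation is `2r^2 / (r^2 + (1-r)^2)`.
#' The update is performed simultaneously for all marker pairs on the nine
#' count matrices, so cost is a few dense matrix products per iteration.
#'
#' @param g a [genotype_matrix()] with calls in `{A, H, B}`.
#' @param max_iter maximum EM iterations (default 100).
#' @param tol convergence tolerance on successive rf estimates (default 1e-6).
#' @return an [rf_matrix()]; `support` holds per-pair complete-observation
#'   counts.
#' @export
rf_f2_em <- function(g, max_iter = 100, tol = 1e-6) {
  stopifnot(inherits(g, "genotype_matrix"))
  calls <- g$calls
  m <- nrow(calls)
  ia <- (calls == "A") & !is.na(calls); storage.mode(ia) <- "double"
  ih <- (calls == "H") & !is.na(calls); storage.mode(ih) <- "double"
  ib <- (calls == "B") & !is.na(calls); storage.mode(ib) <- "double"
  n_aa <- tcrossprod(ia); n_ab <- ia %*% t(ib); n_ba <- ib %*% t(ia)
  n_ah <- ia %*% t(ih); n_ha <- ih %*% t(ia)
  n_bh <- ib %*% t(ih); n_hb <- ih %*% t(ib)
  n_hh <- tcrossprod(ih); n_bb <- tcrossprod(ib)
  N <- n_aa + n_ab + n_ba + n_ah + n_ha + n_bh + n_hb + n_hh + n_bb
  off <- row(N) != col(N)
  if (any(N[off] == 0))
    stop("undefined rf: a marker pair has no mutually observed individuals")
  k1 <- n_ah + n_ha + n_bh + n_hb          # one recombinant gamete
  k2 <- 2 * (n_ab + n_ba)                  # two recombinant gametes
  r <- matrix(0.25, m, m)
  denom <- pmax(2 * N, 1)
  for (it in seq_len(max_iter)) {
    e_hh <- 2 * r^2 / (r^2 + (1 - r)^2)    # E[recombinant gametes | H,H]
    r_new <- (k1 + k2 + n_hh * e_hh) / denom
    delta <- max(abs(r_new - r))
    r <- r_new
    if (delta < tol) break
  }
  r <- pmin(pmax(r, 0), 0.5)
  r <- (r + t(r)) / 2
  diag(r) <- 0
  rf_matrix(r, rownames(calls), support = N)
}

#' Estimate recombination frequencies for a genotype matrix
#'
#' Dispatches on `cross_type`: direct mismatch counting with the
#' missing-midpoint adjustment for `riself` ([rf_homozygous()]) and `bc`
#' ([rf_backcross()]), pairwise EM for `f2` ([rf_f2_em()]).
#'
#' @param g a [genotype_matrix()] with a known `cross_type`.
#' @param ... passed to the design-specific estimator.
#' @return an [rf_matrix()].
#' @export
estimate_rf <- function(g, ...) {
  stopifnot(inherits(g, "genotype_matrix"))
  switch(g$cross_type,
         riself = rf_homozygous(g),
         bc = rf_backcross(g),
         f2 = rf_f2_em(g, ...),
         stop("cannot estimate rf for cross_type 'unknown'; supply an rf matrix"))
}

#' Inflate uninformative rf values to 0.5
#'
#' Large recombination fractions carry no linkage information but slow the
#' TSP solvers; every off-diagonal entry strictly greater than `cutoff` is
#' inflated to exactly 0.5 so the solvers never spend effort optimizing
#' them. Idempotent and monotone.
#'
#' @param r an [rf_matrix()].
#' @param cutoff inflation threshold in `(0, 0.5]`; default 0.4.
#' @return an [rf_matrix()] with inflated entries.
#' @export
apply_cutoff <- function(r, cutoff = 0.4) {
  stopifnot(inherits(r, "rf_matrix"))
  if (!is.numeric(cutoff) || length(cutoff) != 1 || is.na(cutoff) ||
      cutoff <= 0 || cutoff > 0.5)
    stop("cutoff must lie in (0, 0.5]")
  rf <- r$rf
  inflate <- rf > cutoff
  diag(inflate) <- FALSE
  rf[inflate] <- 0.5
  rf_matrix(rf, r$marker_names, r$support)
}

#' Read a recombination-frequency matrix from CSV
#'
#' Expects a square matrix with marker names as both header row and first
#' column, entries in `[0, 0.5]`, symmetric to within 1e-9 (e.g. as exported
#' from R/qtl for designs whose estimation this package does not cover).
#'
#' @param path CSV path.
#' @return an [rf_matrix()].
#' @export
read_rf_matrix <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  mat <- as.matrix(tab)
  if (nrow(mat) != ncol(mat))
    stop(sprintf("rf matrix must be square; got %d x %d", nrow(mat), ncol(mat)))
  if (!is.numeric(mat)) stop("rf matrix entries must be numeric")
  if (any(is.na(mat))) stop("rf matrix contains missing entries")
  if (any(mat < 0 | mat > 0.5))
    stop("rf entries outside [0, 0.5]")
  if (max(abs(mat - t(mat))) > 1e-9)
    stop("asymmetric rf matrix")
  rf_matrix(mat, rownames(mat))
}

#' Write a recombination-frequency matrix to CSV
#'
#' @param r an [rf_matrix()].
#' @param path output CSV path.
#' @export
write_rf_matrix <- function(r, path) {
  stopifnot(inherits(r, "rf_matrix"))
  df <- as.data.frame(r$rf)
  utils::write.csv(cbind(marker = r$marker_names, df), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
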