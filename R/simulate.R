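#' Simulation parameters for a mapping population
#'
#' @param n number of individuals (lines).
#' @param m total marker count, split as evenly as possible over `k`
#'   chromosomes.
#' @param k chromosome count.
#' @param lengths chromosome lengths in cM (recycled to length `k`;
#'   default 100 cM each).
#' @param cross_type `"riself"` (recombinant inbred by selfing), `"f2"`, or
#'   `"bc"` (backcross).
#' @param eta genotyping-error rate: each call is replaced by a uniformly
#'   chosen different legal genotype with this probability.
#' @param gamma missing-data rate: each call is then set missing with this
#'   probability.
#' @param seed integer seed; the same parameters always produce the same
#'   population.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(n = 300, m = 1000, k = 5, lengths = 100,
                       cross_type = c("riself", "f2", "bc"),
                       eta = 0, gamma = 0, seed = 1) {
  cross_type <- match.arg(cross_type)
  if (n < 2) stop("need at least 2 individuals")
  if (m < k) stop("need at least one marker per chromosome")
  if (eta < 0 || eta >= 1 || gamma < 0 || gamma >= 1)
    stop("eta and gamma must lie in [0, 1)")
  lengths <- rep_len(lengths, k)
  structure(list(n = as.integer(n), m = as.integer(m), k = as.integer(k),
                 lengths = lengths, cross_type = cross_type,
                 eta = eta, gamma = gamma, seed = as.integer(seed)),
            class = "sim_params")
}

#' Construct the true map for a simulation
#'
#' Markers are divided as evenly as possible across the chromosomes (the
#' first `m %% k` chromosomes receive one extra) and spaced evenly from 0
#' to the chromosome length. Marker names encode chromosome and index
#' (`c01m0001`, ...), so the truth is recoverable by name.
#'
#' @param p a [sim_params()].
#' @return an object of class `true_map`: list of chromosomes, each with
#'   `name`, `length`, `markers`, `positions`.
#' @export
make_true_map <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  base <- p$m %/% p$k
  sizes <- rep(base, p$k) + c(rep(1, p$m %% p$k), rep(0, p$k - p$m %% p$k))
  chroms <- lapply(seq_len(p$k), function(ci) {
    sz <- sizes[ci]
    pos <- if (sz == 1) 0 else seq(0, p$lengths[ci], length.out = sz)
    list(name = sprintf("c%02d", ci),
         length = p$lengths[ci],
         markers = sprintf("c%02dm%04d", ci, seq_len(sz)),
         positions = pos)
  })
  structure(list(chromosomes = chroms), class = "true_map")
}

#' @export
print.true_map <- function(x, ...) {
  cat(sprintf("true_map: %d chromosomes, %d markers\n",
              length(x$chromosomes),
              sum(vapply(x$chromosomes, function(ch) length(ch$markers), 1L))))
  invisible(x)
}

# truth as a data.frame (marker, chromosome, position_cM)
truth_table <- function(tm) {
  do.call(rbind, lapply(tm$chromosomes, function(ch)
    data.frame(marker = ch$markers, chromosome = ch$name,
               position_cM = ch$positions, stringsAsFactors = FALSE)))
}

#' Write / read the true marker positions
#'
#' CSV with columns `marker`, `chromosome`, `position_cM`.
#'
#' @param tm a [make_true_map()] result.
#' @param path file path.
#' @export
write_truth <- function(tm, path) {
  utils::write.csv(truth_table(tm), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("marker", "chromosome", "position_cM")
  if (!all(need %in% names(df))) stop("malformed truth file")
  chroms <- lapply(split(df, df$chromosome), function(d) {
    d <- d[order(d$position_cM), ]
    list(name = d$chromosome[1], length = max(d$position_cM),
         markers = d$marker, positions = d$position_cM)
  })
  structure(list(chromosomes = unname(chroms)), class = "true_map")
}

# single-meiosis recombination fraction between adjacent markers from the
# Haldane inverse of their cM spacing
haldane_inv <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

# simulate one chromosome's calls for n individuals as a Markov chain along
# the ordered markers; returns a size x n character matrix
sim_chromosome <- function(positions, n, cross_type) {
  sz <- length(positions)
  r <- haldane_inv(diff(positions))
  if (cross_type == "riself") {
    # line-level recombinant fraction between fixed homozygous states
    pr <- 2 * r / (1 + 2 * r)
    state <- matrix(0L, sz, n)
    state[1, ] <- stats::rbinom(n, 1, 0.5)
    for (i in seq_len(sz - 1))
      state[i + 1, ] <- (state[i, ] + stats::rbinom(n, 1, pr[i])) %% 2L
    matrix(c("A", "B")[state + 1L], sz, n)
  } else if (cross_type == "bc") {
    state <- matrix(0L, sz, n)
    state[1, ] <- stats::rbinom(n, 1, 0.5)
    for (i in seq_len(sz - 1))
      state[i + 1, ] <- (state[i, ] + stats::rbinom(n, 1, r[i])) %% 2L
    matrix(c("A", "H")[state + 1L], sz, n)
  } else {
    # f2: two independent meioses, genotype = allele dosage
    dose <- matrix(0L, sz, n)
    for (gamete in 1:2) {
      chrom <- matrix(0L, sz, n)
      chrom[1, ] <- stats::rbinom(n, 1, 0.5)
      for (i in seq_len(sz - 1))
        chrom[i + 1, ] <- (chrom[i, ] + stats::rbinom(n, 1, r[i])) %% 2L
      dose <- dose + chrom
    }
    matrix(c("A", "H", "B")[dose + 1L], sz, n)
  }
}

#' Simulate a mapping population
#'
#' Genotypes are generated per individual and chromosome by a Markov chain
#' along the ordered markers with no crossover interference: the
#' adjacent-interval recombination probability is the Haldane inverse of
#' the cM spacing, used directly for a backcross, transformed to the
#' line-level `R = 2r/(1+2r)` for selfed RILs, and applied to two
#' independent meioses for an F2. Genotyping errors are then injected
#' (each call flipped to a uniformly chosen different legal genotype with
#' probability `eta`), followed by missing data (each call erased with
#' probability `gamma`).
#'
#' @param tm a [make_true_map()] result.
#' @param p the matching [sim_params()].
#' @return a [genotype_matrix()] with markers in true-map order.
#' @export
simulate_population <- function(tm, p) {
  stopifnot(inherits(tm, "true_map"), inherits(p, "sim_params"))
  set.seed(p$seed)
  calls <- do.call(rbind, lapply(tm$chromosomes, function(ch)
    sim_chromosome(ch$positions, p$n, p$cross_type)))
  legal <- switch(p$cross_type, riself = c("A", "B"), bc = c("A", "H"),
                  f2 = c("A", "H", "B"))
  if (p$eta > 0) {
    err <- matrix(stats::runif(length(calls)) < p$eta, nrow(calls))
    if (any(err)) {
      cur <- calls[err]
      pick <- vapply(cur, function(g) {
        alt <- legal[legal != g]
        alt[sample.int(length(alt), 1)]
      }, "")
      calls[err] <- pick
    }
  }
  if (p$gamma > 0) {
    miss <- matrix(stats::runif(length(calls)) < p$gamma, nrow(calls))
    calls[miss] <- NA_character_
  }
  rownames(calls) <- unlist(lapply(tm$chromosomes, `[[`, "markers"))
  colnames(calls) <- sprintf("ind%04d", seq_len(p$n))
  genotype_matrix(calls, cross_type = p$cross_type)
}

#' Randomize marker row order
#'
#' Real pipelines receive markers in arbitrary order; simulated inputs are
#' shuffled the same way before mapping, retaining the permutation so the
#' solution can be scored against the truth.
#'
#' @param g a [genotype_matrix()].
#' @param seed shuffle seed.
#' @return list with `genotypes` (rows permuted) and `permutation` such
#'   that `shuffled$calls == original$calls[permutation, ]`.
#' @export
shuffle_markers <- function(g, seed = 1) {
  stopifnot(inherits(g, "genotype_matrix"))
  set.seed(seed)
  perm <- sample.int(nrow(g$calls))
  list(genotypes = genotype_matrix(g$calls[perm, , drop = FALSE],
                                   cross_type = g$cross_type),
       permutation = perm)
}
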