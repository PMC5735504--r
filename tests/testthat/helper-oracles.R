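# Independent oracles used across the suite. These deliberately use brute
# force / enumeration, never the package's own algorithms.

# all permutations of 1..n as a matrix (rows)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out <- rbind(out, block)
  }
  out
}

# minimum Hamiltonian-path cost over markers of a weight matrix (no dummy)
brute_force_path_cost <- function(w) {
  n <- nrow(w)
  if (n == 1) return(0)
  p <- all_perms(n)
  costs <- rep(0, nrow(p))
  for (i in seq_len(n - 1))
    costs <- costs + w[cbind(p[, i], p[, i + 1])]
  min(costs)
}

# quadratic-time erroneous-pair count, minimized over orientation
quadratic_inversions <- function(true_ranks, est_order) {
  count <- function(ord) {
    v <- true_ranks[ord]
    n <- length(v)
    tot <- 0
    for (i in seq_len(n - 1))
      for (j in (i + 1):n)
        if (v[i] > v[j]) tot <- tot + 1
    tot
  }
  min(count(est_order), count(rev(est_order)))
}

# minimum spanning-tree weight by enumerating all trees via Pruefer
# sequences (n^(n-2) labelled trees)
prufer_min_tree_weight <- function(w) {
  n <- nrow(w)
  if (n == 2) return(w[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (s in seq_len(nrow(seqs))) {
    pr <- seqs[s, ]
    degree <- rep(1L, n)
    for (v in pr) degree[v] <- degree[v] + 1L
    total <- 0
    avail <- degree
    prseq <- pr
    for (v in prseq) {
      leaf <- which(avail == 1L)[1]
      total <- total + w[leaf, v]
      avail[leaf] <- 0L
      avail[v] <- avail[v] - 1L
    }
    ends <- which(avail == 1L)
    total <- total + w[ends[1], ends[2]]
    best <- min(best, total)
  }
  best
}

# F2 two-locus genotype probability table for the likelihood grid oracle
oracle_f2_table <- function(r) {
  hap <- rbind(c(1, 1, (1 - r) / 2), c(1, 2, r / 2),
               c(2, 1, r / 2), c(2, 2, (1 - r) / 2))
  tab <- matrix(0, 3, 3)
  for (i in 1:4) for (j in 1:4) {
    g1 <- hap[i, 1] + hap[j, 1] - 1
    g2 <- hap[i, 2] + hap[j, 2] - 1
    tab[g1, g2] <- tab[g1, g2] + hap[i, 3] * hap[j, 3]
  }
  tab
}

# maximum-likelihood rf for a 3x3 F2 joint count table by grid search
oracle_f2_grid_mle <- function(counts, grid = seq(0, 0.5, by = 0.001)) {
  ll <- vapply(grid, function(r) {
    tab <- oracle_f2_table(max(r, 1e-9))
    sum(counts * log(tab))
  }, 0)
  grid[which.max(ll)]
}

# small genotype matrix from a character vector spec, one string per marker
# e.g. geno_from_strings(c("AABB", "A-BB")), "-" = missing
geno_from_strings <- function(rows, cross_type = "riself",
                              markers = paste0("m", seq_along(rows))) {
  calls <- do.call(rbind, lapply(strsplit(rows, ""), function(x)
    ifelse(x == "-", NA_character_, x)))
  rownames(calls) <- markers
  colnames(calls) <- paste0("i", seq_len(ncol(calls)))
  genotype_matrix(calls, cross_type = cross_type)
}

# rf matrix directly from entries (upper triangle filled symmetrically)
rf_from_entries <- function(m, entries) {
  rf <- matrix(0, m, m)
  for (e in entries) rf[e[1], e[2]] <- rf[e[2], e[1]] <- e[3]
  rf_matrix(rf, paste0("m", seq_len(m)))
}

# deterministic random symmetric weight/rf matrices for property tests
random_rf <- function(m, seed) {
  set.seed(seed)
  rf <- matrix(0, m, m)
  vals <- runif(m * (m - 1) / 2, 0, 0.5)
  rf[upper.tri(rf)] <- vals
  rf <- rf + t(rf)
  rf_matrix(rf, paste0("m", seq_len(m)))
}
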