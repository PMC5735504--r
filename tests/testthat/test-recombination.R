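test_that("homozygous rf is the mismatch fraction when data are complete", {
  g <- geno_from_strings(c("AABB", "ABBB"))
  r <- rf_homozygous(g)
  expect_equal(r$rf[1, 2], 0.25)
  expect_equal(r$support[1, 2], 4)
  # identical markers -> rf 0
  g2 <- geno_from_strings(c("AABB", "AABB"))
  expect_equal(rf_homozygous(g2)$rf[1, 2], 0)
})

test_that("missing calls move rf to the midpoint of the attainable range", {
  # x=[A,A,B,B], y=[A,-,B,B]: d=0, c=3, u=1 -> range [0, 0.25], midpoint 0.125
  g <- geno_from_strings(c("AABB", "A-BB"))
  expect_equal(rf_homozygous(g)$rf[1, 2], 0.125)
})

test_that("midpoint formula matches enumeration of missing-call resolutions", {
  set.seed(7)
  for (trial in 1:25) {
    n <- sample(4:8, 1)
    x <- sample(c("A", "B"), n, TRUE)
    y <- sample(c("A", "B", NA), n, TRUE, prob = c(.4, .4, .2))
    g <- genotype_matrix(rbind(m1 = x, m2 = y), cross_type = "riself")
    miss <- which(is.na(y))
    u <- length(miss)
    resolutions <- if (u == 0) list(y) else {
      combos <- expand.grid(rep(list(c("A", "B")), u), stringsAsFactors = FALSE)
      lapply(seq_len(nrow(combos)), function(i) {
        yy <- y; yy[miss] <- unlist(combos[i, ]); yy
      })
    }
    rfs <- vapply(resolutions, function(yy) mean(yy != x), 0)
    expected <- (min(rfs) + max(rfs)) / 2
    got <- rf_homozygous(g)$rf[1, 2]
    expect_equal(got, min(expected, 0.5))
    if (u > 0 && min(rfs) < max(rfs) && expected < 0.5) {
      expect_gt(got, min(rfs)); expect_lt(got, max(rfs))
    }
  }
})

test_that("backcross rf counts recombinants and clamps at 0.5", {
  g <- geno_from_strings(c("AAHH", "AHHH"), cross_type = "bc")
  expect_equal(rf_backcross(g)$rf[1, 2], 0.25)
  g2 <- geno_from_strings(c("AH", "HA"), cross_type = "bc")
  expect_equal(rf_backcross(g2)$rf[1, 2], 0.5)  # raw 1.0, clamped
  expect_error(rf_backcross(geno_from_strings(c("AB", "AB"), cross_type = "bc")),
               "A, H")
})

test_that("F2 EM matches the grid-search likelihood oracle", {
  set.seed(21)
  for (trial in 1:8) {
    r_true <- runif(1, 0.02, 0.45)
    tab <- oracle_f2_table(r_true)
    counts <- matrix(stats::rmultinom(1, 200, as.vector(tab)), 3, 3)
    # build a genotype matrix realizing exactly these joint counts
    codes <- c("A", "H", "B")
    x <- character(0); y <- character(0)
    for (i in 1:3) for (j in 1:3) {
      x <- c(x, rep(codes[i], counts[i, j]))
      y <- c(y, rep(codes[j], counts[i, j]))
    }
    g <- genotype_matrix(rbind(m1 = x, m2 = y), cross_type = "f2")
    est <- rf_f2_em(g)$rf[1, 2]
    oracle <- oracle_f2_grid_mle(counts)
    expect_lt(abs(est - oracle), 0.0011)
  }
})

test_that("F2 EM recovers rf on simulated pairs and unlinked loci", {
  # perfectly cosegregating pair
  g <- geno_from_strings(c("AHBHA", "AHBHA"), cross_type = "f2")
  expect_lt(rf_f2_em(g)$rf[1, 2], 1e-4)
  # two independent loci, large n -> rf about 0.5
  set.seed(5)
  n <- 10000
  x <- sample(c("A", "H", "B"), n, TRUE, prob = c(.25, .5, .25))
  y <- sample(c("A", "H", "B"), n, TRUE, prob = c(.25, .5, .25))
  g2 <- genotype_matrix(rbind(m1 = x, m2 = y), cross_type = "f2")
  expect_lt(abs(rf_f2_em(g2)$rf[1, 2] - 0.5), 0.02)
})

test_that("F2 EM recovers the generating rf within 3 standard errors", {
  set.seed(31)
  n <- 1000
  for (r_true in c(0.05, 0.2, 0.4)) {
    tab <- oracle_f2_table(r_true)
    draw <- matrix(stats::rmultinom(1, n, as.vector(tab)), 3, 3)
    codes <- c("A", "H", "B")
    x <- character(0); y <- character(0)
    for (i in 1:3) for (j in 1:3) {
      x <- c(x, rep(codes[i], draw[i, j]))
      y <- c(y, rep(codes[j], draw[i, j]))
    }
    g <- genotype_matrix(rbind(m1 = x, m2 = y), cross_type = "f2")
    est <- rf_f2_em(g)$rf[1, 2]
    se <- sqrt(r_true * (1 - r_true) / (2 * n))  # 2n informative meioses
    expect_lt(abs(est - r_true), 3 * se)
  }
})

test_that("apply_cutoff inflates strictly-above-threshold entries only", {
  r <- rf_from_entries(3, list(c(1, 2, 0.45), c(1, 3, 0.40), c(2, 3, 0.10)))
  out <- apply_cutoff(r, 0.4)
  expect_equal(out$rf[1, 2], 0.5)   # above cutoff -> inflated
  expect_equal(out$rf[1, 3], 0.40)  # boundary: not strictly above
  expect_equal(out$rf[2, 3], 0.10)
  expect_error(apply_cutoff(r, 0), "cutoff")
  expect_error(apply_cutoff(r, 0.6), "cutoff")
})

test_that("apply_cutoff is idempotent and monotone", {
  for (seed in 1:5) {
    r <- random_rf(8, seed)
    once <- apply_cutoff(r, 0.4)
    twice <- apply_cutoff(once, 0.4)
    expect_identical(once$rf, twice$rf)
    expect_true(all(once$rf >= r$rf))
  }
})

test_that("rf matrix CSV round-trips and rejects bad input", {
  r <- random_rf(5, 99)
  path <- withr::local_tempfile(fileext = ".csv")
  write_rf_matrix(r, path)
  r2 <- read_rf_matrix(path)
  expect_lt(max(abs(r$rf - r2$rf)), 1e-12)
  expect_identical(rownames(r2$rf), rownames(r$rf))

  writeLines(c("marker,m1,m2,m3", "m1,0,0.1,0.2", "m2,0.1,0,0.3"), path)
  expect_error(read_rf_matrix(path), "square")
  writeLines(c("marker,m1,m2", "m1,0,0.7", "m2,0.7,0"), path)
  expect_error(read_rf_matrix(path), "0.5")
  writeLines(c("marker,m1,m2", "m1,0,0.1", "m2,0.2,0"), path)
  expect_error(read_rf_matrix(path), "symmetric|asymmetric")
})

test_that("rf estimation dispatches on cross type", {
  g <- geno_from_strings(c("AABB", "ABBB"))
  expect_equal(estimate_rf(g)$rf[1, 2], 0.25)
  gu <- geno_from_strings(c("AABB"), cross_type = "riself")
  gu$cross_type <- "unknown"
  expect_error(estimate_rf(gu), "unknown")
})
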