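test_that("weight matrix scales rf to integers and appends a zero dummy", {
  r <- rf_from_entries(3, list(c(1, 2, 0.25), c(1, 3, 0.4), c(2, 3, 0.1)))
  w <- build_weight_matrix(r, scale = 1e5)
  expect_equal(w$weights[1, 2], 25000)
  expect_equal(w$size, 4L)
  expect_equal(w$dummy_index, 4L)
  expect_true(all(w$weights[4, ] == 0) && all(w$weights[, 4] == 0))
  # degenerate single-marker subset
  w1 <- build_weight_matrix(r, subset = 2)
  expect_equal(w1$size, 2L)
  expect_true(all(w1$weights == 0))
  expect_error(build_weight_matrix(r, subset = c(1, 1)), "duplicate")
})

test_that("heuristic solver recovers line structure and is deterministic", {
  # rf proportional to index distance: unique optimum is the line order
  m <- 5
  rf <- outer(1:m, 1:m, function(a, b) pmin(abs(a - b) * 0.1, 0.5))
  r <- rf_matrix(rf, paste0("m", 1:m))
  w <- build_weight_matrix(r)
  p <- solve_heuristic(w, seed = 3)
  expect_true(identical(p$order, 1:5) || identical(p$order, 5:1))
  expect_equal(p$cost, sum(p$edge_rf))
  p2 <- solve_heuristic(w, seed = 3)
  expect_identical(p$order, p2$order)
  # single marker
  ps <- solve_heuristic(build_weight_matrix(r, subset = 1))
  expect_equal(ps$order, 1L)
  expect_equal(ps$cost, 0)
})

test_that("exact solver matches the stated 4-marker optimum", {
  # weights d(1,2)=1 d(1,3)=4 d(1,4)=6 d(2,3)=2 d(2,4)=5 d(3,4)=3
  # brute force over all 12 distinct paths gives 1-2-3-4, cost 6
  rf <- matrix(0, 4, 4)
  rf[1, 2] <- 1; rf[1, 3] <- 4; rf[1, 4] <- 6
  rf[2, 3] <- 2; rf[2, 4] <- 5; rf[3, 4] <- 3
  rf <- (rf + t(rf)) / 20  # scale into [0, 0.5]
  r <- rf_matrix(rf, paste0("m", 1:4))
  p <- solve_exact_small(build_weight_matrix(r))
  expect_equal(p$order, 1:4)
  expect_equal(p$cost, 6 / 20, tolerance = 1e-9)
})

test_that("exact solver equals permutation enumeration on random instances", {
  trials <- 0
  for (seed in 1:220) {
    n <- 3 + (seed %% 5)           # sizes 3..7
    if (seed > 210) n <- 8 + seed %% 2   # a few larger ones
    r <- random_rf(n, seed)
    w <- build_weight_matrix(r)
    p <- solve_exact_small(w)
    # enumerate the same integer-scaled instance the solver saw
    quantized <- w$weights[seq_len(n), seq_len(n)] / w$scale
    expect_equal(p$cost, brute_force_path_cost(quantized), tolerance = 1e-9)
    trials <- trials + 1
  }
  expect_gte(trials, 200)
})

test_that("heuristic cost never beats the exact optimum", {
  for (seed in 301:320) {
    n <- 4 + (seed %% 5)
    r <- random_rf(n, seed)
    w <- build_weight_matrix(r)
    ph <- solve_heuristic(w, seed = seed)
    pe <- solve_exact_small(w)
    expect_gte(ph$cost + 1e-9, pe$cost)
  }
})

test_that("two-marker instances and equal-weight tie-breaks behave", {
  r <- rf_from_entries(2, list(c(1, 2, 0.3)))
  p <- solve_exact_small(build_weight_matrix(r))
  expect_equal(sort(p$order), 1:2)
  expect_equal(p$cost, 0.3)
  # equal all-pairs weights: lexicographically smallest order
  rf <- matrix(0.2, 4, 4); diag(rf) <- 0
  re <- rf_matrix(rf, paste0("m", 1:4))
  pe <- solve_exact_small(build_weight_matrix(re))
  expect_equal(pe$order, 1:4)
})

test_that("the dummy vertex removes the closing-edge penalty", {
  # a line instance whose end-to-end rf is huge: the path must still be the
  # line, i.e. the tour cost excludes the closing edge
  m <- 6
  rf <- outer(1:m, 1:m, function(a, b) pmin(abs(a - b) * 0.08, 0.5))
  r <- rf_matrix(rf, paste0("m", 1:m))
  p <- solve_exact_small(build_weight_matrix(r))
  expect_true(identical(p$order, 1:6) || identical(p$order, 6:1))
  expect_equal(p$cost, 5 * 0.08, tolerance = 1e-6)
})

test_that("path_cost sums adjacent rf and is reversal-invariant", {
  r <- rf_from_entries(3, list(c(1, 2, 0.1), c(2, 3, 0.2), c(1, 3, 0.4)))
  p <- marker_path(c(1, 2, 3), c(0.1, 0.2))
  expect_equal(path_cost(p, r), 0.3)
  pr <- marker_path(c(3, 2, 1), c(0.2, 0.1))
  expect_equal(path_cost(pr, r), path_cost(p, r))
  expect_equal(path_cost(marker_path(2L), r), 0)
  expect_error(path_cost(marker_path(c(1L, 9L), 0.1), r), "range")
})

test_that("oversized instances are refused by the exact solver", {
  r <- random_rf(20, 1)
  expect_error(solve_exact_small(build_weight_matrix(r), limit = 18),
               "order_linkage_group")
})

test_that("TSPLIB export writes a well-formed full-matrix instance", {
  r <- random_rf(4, 2)
  w <- build_weight_matrix(r)
  path <- withr::local_tempfile(fileext = ".tsp")
  write_tsplib(w, path)
  lines <- readLines(path)
  expect_true(any(grepl("^DIMENSION: 5$", lines)))
  expect_true(any(grepl("FULL_MATRIX", lines)))
  body <- lines[(which(lines == "EDGE_WEIGHT_SECTION") + 1):(which(lines == "EOF") - 1)]
  expect_equal(length(body), 5)
  expect_equal(as.numeric(strsplit(body[1], " ")[[1]]), w$weights[1, ])
})
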