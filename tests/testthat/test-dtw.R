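test_that("the local cost is the absolute sample difference", {
  expect_equal(local_distance(5, 5), 0)
  expect_equal(local_distance(2, 5), 3)
  expect_equal(local_distance(5, 2), 3)
  expect_equal(local_distance(-1, 1), 2)
  expect_error(local_distance(Inf, 1), "finite")
  expect_error(local_distance(1, NA), "finite")
})

test_that("worked alignments give their known distances", {
  expect_equal(dtw(c(1, 2, 3), c(2, 3, 4))$distance, 2)
  expect_equal(dtw_brute_force(c(1, 2, 3), c(2, 3, 4)), 2)
  expect_equal(dtw(1, 7)$distance, 6)           # single cell: |1 - 7|
  expect_equal(dtw(c(0, 0), 1)$distance, 2)     # both samples must align to 1
  expect_equal(dtw_brute_force(c(0, 0), 1), 2)
})

test_that("identical sequences have zero distance and a diagonal path", {
  set.seed(3)
  x <- rnorm(20)
  res <- dtw(x, x)
  expect_equal(res$distance, 0)
  expect_equal(res$path, cbind(k = 1:20, l = 1:20))
})

test_that("the accumulated-cost matrix carries the sentinel boundary", {
  res <- dtw(c(1, 2), c(2, 4, 3))
  F <- res$matrix
  expect_equal(dim(F), c(3, 4))
  expect_equal(F[1, 1], 0)
  expect_true(all(is.infinite(F[1, -1])))
  expect_true(all(is.infinite(F[-1, 1])))
  expect_equal(res$distance, F[3, 4])
})

test_that("dtw agrees with exhaustive path enumeration on random pairs", {
  set.seed(42)
  for (i in 1:150) {
    r <- sample(0:9, sample(1:6, 1), replace = TRUE)
    t <- sample(0:9, sample(1:6, 1), replace = TRUE)
    expect_equal(dtw(r, t)$distance, dtw_brute_force(r, t))
  }
})

test_that("distance is symmetric, non-negative and bounded by the diagonal", {
  set.seed(9)
  for (i in 1:30) {
    n <- sample(2:40, 1)
    r <- rnorm(n)
    t <- rnorm(sample(2:40, 1))
    d <- dtw_distance(r, t)
    expect_gte(d, 0)
    expect_equal(dtw_distance(t, r), d)
    s <- rnorm(n)
    expect_lte(dtw_distance(r, s), sum(abs(r - s)))  # n = m diagonal bound
  }
})

test_that("duplicated equal samples add zero cost; stuttering never lowers the distance", {
  set.seed(21)
  for (i in 1:25) {
    r <- rnorm(sample(2:15, 1))
    t <- rnorm(sample(2:15, 1))
    d <- dtw_distance(r, t)
    j <- sample(length(t), 1)
    t_stut <- append(t, t[j], after = j)
    # the duplicate aligns to the same partner, adding that local cost once
    # more and never less, so the distance cannot drop
    expect_gte(dtw_distance(r, t_stut), d - 1e-12)
    # a stuttered copy of r itself stays at distance zero: sequences of
    # different lengths tracing the same curve compare as identical
    reps <- rep(seq_along(r), times = sample(1:3, length(r), replace = TRUE))
    expect_equal(dtw_distance(r, r[reps]), 0)
  }
})

test_that("the warping path is monotone, complete and costs the distance", {
  set.seed(5)
  for (i in 1:25) {
    r <- rnorm(sample(2:30, 1))
    t <- rnorm(sample(2:30, 1))
    res <- dtw(r, t)
    p <- res$path
    expect_equal(p[1, ], c(k = 1, l = 1))
    expect_equal(p[nrow(p), ], c(k = length(r), l = length(t)))
    steps <- diff(p)
    expect_true(all(steps >= 0 & steps <= 1))
    expect_true(all(rowSums(steps) >= 1))
    expect_equal(path_cost(r, t, p), res$distance, tolerance = 1e-9)
  }
})

test_that("tie-breaking is deterministic and prefers the diagonal", {
  res <- dtw(c(0, 0), c(0, 0))
  expect_equal(res$path, cbind(k = 1:2, l = 1:2))
  x <- c(3, 1, 4, 1, 5)
  expect_identical(dtw(x, rev(x))$path, dtw(x, rev(x))$path)
})

test_that("the memory-light distance variant matches the full matrix", {
  set.seed(14)
  for (i in 1:20) {
    r <- rnorm(sample(2:50, 1))
    t <- rnorm(sample(2:50, 1))
    expect_equal(dtw(r, t, keep_matrix = FALSE)$distance,
                 dtw(r, t)$distance)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(dtw(numeric(0), 1), "non-empty")
  expect_error(dtw(1, numeric(0)), "non-empty")
  expect_error(dtw(c(1, NA), 1), "finite")
  expect_error(dtw_brute_force(1:8, 1:3), "max_len")
})
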