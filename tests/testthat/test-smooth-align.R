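test_that("path_score matches hand-computed examples and rejects bad paths", {
  lin <- align_params(gap = -1, align_mode = "local")
  a <- matrix(c(1, -1, -1, 1), 2, 2)
  expect_equal(path_score(a, cbind(c(0, 1), c(0, 1)), lin), 2.0)
  expect_equal(path_score(a, cbind(integer(0), integer(0)), lin), 0.0)

  glob <- align_params(gap = -1, align_mode = "global")
  a32 <- matrix(0, 3, 2)
  expect_equal(path_score(a32, cbind(c(0, 2), c(0, 1)), glob), -1.0)

  expect_error(path_score(a, cbind(c(1, 0), c(0, 1)), lin), "increasing")
  expect_error(path_score(a, cbind(0, 5), lin), "outside")
})

test_that("affine path scores depend on the gap-streak interleaving", {
  aff <- align_params(gap_mode = "affine", open = -3, extend = -0.5,
                      align_mode = "global")
  a <- matrix(0, 3, 2)
  paths <- enumerate_paths(3, 2, aff)
  # the all-gap arrangements of 3 deletions and 2 insertions differ in how
  # many streaks they contain, hence in how many opens they are charged
  allgap <- Filter(function(p) nrow(p$matches) == 0, paths)
  sc <- vapply(allgap, function(p) path_score(a, p, aff), numeric(1))
  expect_gt(length(unique(round(sc, 9))), 1)
})

test_that("enumerate_paths counts tiny cases correctly", {
  loc <- align_params(align_mode = "local")
  expect_length(enumerate_paths(1, 1, loc), 2) # empty + single match

  # independent count of monotone global move sequences (Delannoy numbers)
  delannoy <- function(n, m) {
    D <- matrix(0, n + 1, m + 1)
    D[1, ] <- 1
    D[, 1] <- 1
    for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
      D[i, j] <- D[i - 1, j] + D[i, j - 1] + D[i - 1, j - 1]
    }
    D[n + 1, m + 1]
  }
  glob <- align_params(align_mode = "global")
  for (nm in list(c(2, 2), c(3, 2), c(3, 3))) {
    expect_length(enumerate_paths(nm[1], nm[2], glob),
                  delannoy(nm[1], nm[2]))
  }

  # 1x1 global: the single match plus the all-gap arrangements; with
  # restricted turns the deletion-then-insertion ordering is removed
  p11 <- enumerate_paths(1, 1, glob)
  expect_length(p11, 3)
  p11r <- enumerate_paths(1, 1, align_params(align_mode = "global",
                                             restrict_turns = TRUE))
  expect_length(p11r, 2)

  expect_error(enumerate_paths(8, 3, glob), "capped")
})

test_that("smooth_score matches closed forms on one-cell problems", {
  loc <- align_params(temperature = 1, align_mode = "local")
  expect_equal(smooth_score(matrix(0), loc), log(2), tolerance = 1e-12)
  for (s in c(-2, 0.5, 3)) {
    expect_equal(smooth_score(matrix(s), loc), log(1 + exp(s)),
                 tolerance = 1e-12)
    expect_equal(brute_force_smooth_score(matrix(s), loc), log(1 + exp(s)),
                 tolerance = 1e-12)
  }
})

test_that("smooth_score and posterior equal the enumeration oracle across all modes", {
  set.seed(101)
  for (params in all_mode_params()) {
    for (rep in 1:12) {
      n <- sample(1:4, 1)
      m <- sample(1:4, 1)
      a <- matrix(rnorm(n * m, sd = 2), n, m)
      paths <- cached_paths(n, m, params)
      expect_equal(smooth_score(a, params), oracle_smooth(a, params, paths),
                   tolerance = 1e-8)
      expect_equal(as.vector(smooth_posterior(a, params)),
                   as.vector(oracle_posterior(a, params, paths)),
                   tolerance = 1e-8)
      # the exported brute-force oracle agrees with the DP as well
      expect_equal(brute_force_smooth_score(a, params),
                   smooth_score(a, params), tolerance = 1e-8)
    }
  }
})

test_that("smooth_score is nondecreasing in temperature and bounded below by the hard score", {
  set.seed(7)
  for (rep in 1:10) {
    a <- matrix(rnorm(12, sd = 2), 3, 4)
    for (mode in c("local", "global")) {
      mk <- function(T) align_params(temperature = T, gap_mode = "affine",
                                     open = -2, extend = -0.5,
                                     align_mode = mode)
      s1 <- smooth_score(a, mk(1))
      s2 <- smooth_score(a, mk(2))
      hard <- hard_align(a, mk(1))$score
      expect_gte(s2, s1 - 1e-10)
      expect_gte(s1, hard - 1e-10)
    }
  }
})

test_that("temperature limit recovers the hard alignment score", {
  a <- matrix(c(3, -1, 0, -2, 2, 1), 2, 3) # integer scores, unique optimum
  for (mode in c("local", "global")) {
    cold <- align_params(temperature = 1e-3, gap = -1, align_mode = mode)
    expect_lt(abs(smooth_score(a, cold) - hard_align(a, cold)$score), 1e-3)
  }
})

test_that("numerical stability holds at small temperature and large scores", {
  set.seed(3)
  a <- matrix(runif(20, -1000, 1000), 4, 5)
  p <- align_params(temperature = 1e-2, gap_mode = "affine", open = -50,
                    extend = -5, align_mode = "global")
  s <- smooth_score(a, p)
  expect_true(is.finite(s))
  P <- smooth_posterior(a, p)
  expect_true(all(is.finite(P)))
  expect_error(smooth_score(matrix(c(1, NA), 1, 2), p), "finite")
})

test_that("posterior entries are probabilities with row/column sums at most one", {
  set.seed(11)
  for (params in all_mode_params()) {
    a <- matrix(rnorm(20, sd = 3), 4, 5)
    P <- smooth_posterior(a, params)
    expect_true(all(P >= -1e-10 & P <= 1 + 1e-8))
    expect_true(all(rowSums(P) <= 1 + 1e-8))
    expect_true(all(colSums(P) <= 1 + 1e-8))
  }
})

test_that("posterior equals the derivative of smooth_score (finite differences)", {
  set.seed(19)
  a <- matrix(rnorm(12), 3, 4)
  for (params in list(all_mode_params()[[2]], all_mode_params()[[7]])) {
    P <- smooth_posterior(a, params)
    for (idx in list(c(1, 1), c(2, 3), c(3, 4))) {
      ap <- a; ap[idx[1], idx[2]] <- ap[idx[1], idx[2]] + 1e-4
      am <- a; am[idx[1], idx[2]] <- am[idx[1], idx[2]] - 1e-4
      fd <- (smooth_score(ap, params) - smooth_score(am, params)) / 2e-4
      expect_equal(P[idx[1], idx[2]], fd, tolerance = 1e-4)
    }
  }
})

test_that("a dominant diagonal drives the global posterior to the identity", {
  a <- matrix(-10, 4, 4)
  diag(a) <- 10
  P <- smooth_posterior(a, align_params(align_mode = "global", gap = -1))
  expect_equal(as.vector(P), as.vector(diag(4)), tolerance = 1e-3)
})

test_that("increasing a match score strictly increases its posterior probability", {
  set.seed(23)
  for (rep in 1:5) {
    a <- matrix(rnorm(12), 3, 4)
    params <- align_params(gap_mode = "affine", open = -2, extend = -0.5,
                           align_mode = sample(c("local", "global"), 1))
    i <- sample(3, 1); j <- sample(4, 1)
    P0 <- smooth_posterior(a, params)[i, j]
    a[i, j] <- a[i, j] + 0.5
    P1 <- smooth_posterior(a, params)[i, j]
    expect_gt(P1, P0)
  }
})

test_that("affine mode with open == extend reproduces linear mode", {
  set.seed(31)
  for (mode in c("local", "global")) {
    a <- matrix(rnorm(20), 4, 5)
    lin <- align_params(temperature = 0.8, gap = -1.4, align_mode = mode)
    aff <- align_params(temperature = 0.8, gap_mode = "affine", open = -1.4,
                        extend = -1.4, align_mode = mode)
    expect_equal(smooth_score(a, lin), smooth_score(a, aff), tolerance = 1e-8)
    expect_equal(as.vector(smooth_posterior(a, lin)),
                 as.vector(smooth_posterior(a, aff)), tolerance = 1e-8)
  }
})

test_that("hard_align matches the enumeration maximum and its fixed conventions", {
  # perfect match toy
  loc <- align_params(gap = -1, align_mode = "local")
  a <- matrix(c(1, -1, -1, 1), 2, 2)
  h <- hard_align(a, loc)
  expect_equal(h$score, 2)
  expect_equal(unname(h$path), cbind(c(0, 1), c(0, 1)))

  # all-negative scores floor at the empty local alignment
  h0 <- hard_align(matrix(-1, 3, 3), loc)
  expect_equal(h0$score, 0)
  expect_equal(nrow(h0$path), 0)

  set.seed(41)
  for (params in all_mode_params()) {
    a <- matrix(rnorm(20, sd = 2), 4, 5)
    h <- hard_align(a, params)
    paths <- cached_paths(4, 5, params)
    expect_equal(h$score, max(oracle_scores(a, paths, params)),
                 tolerance = 1e-9)
    # the reported path attains the reported score (the traceback picks a
    # cheapest gap interleaving, which is what path_score assumes)
    if (nrow(h$path) > 0) {
      expect_equal(path_score(a, h$path, params), h$score, tolerance = 1e-9)
    }
  }
})

test_that("batched posterior is padding-invariant and matches item-wise calls", {
  set.seed(53)
  params <- align_params(gap_mode = "affine", open = -2, extend = -0.4,
                         align_mode = "global", restrict_turns = TRUE)
  a1 <- matrix(rnorm(20), 4, 5)
  a2 <- a1[1:3, 1:4]
  pad <- function(a, n, m) {
    out <- matrix(99, n, m) # poison padding: must never leak into results
    out[seq_len(nrow(a)), seq_len(ncol(a))] <- a
    out
  }
  res <- smooth_posterior_batch(list(pad(a1, 5, 6), pad(a2, 5, 6)),
                                len_x = c(4, 3), len_y = c(5, 4), params)
  expect_equal(as.vector(res[[1]]), as.vector(smooth_posterior(a1, params)),
               tolerance = 1e-8)
  expect_equal(as.vector(res[[2]]), as.vector(smooth_posterior(a2, params)),
               tolerance = 1e-8)

  # batch of one equals the unbatched call; shuffling is equivariant
  one <- smooth_posterior_batch(list(a1), 4, 5, params)
  expect_equal(as.vector(one[[1]]), as.vector(smooth_posterior(a1, params)))
  sh <- smooth_posterior_batch(list(pad(a2, 5, 6), pad(a1, 5, 6)),
                               len_x = c(3, 4), len_y = c(4, 5), params)
  expect_equal(as.vector(sh[[2]]), as.vector(res[[1]]))

  expect_error(smooth_posterior_batch(list(a2), 4, 5, params), "exceeds")
})

test_that("align_params validates its inputs", {
  expect_error(align_params(temperature = 0), "positive")
  expect_error(align_params(gap_mode = "affine", open = NULL, extend = -1),
               "affine")
  expect_error(align_params(gap = NA), "finite")
})
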