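make_profiles <- function(B, L, A, seed = 1, mass = 1) {
  set.seed(seed)
  p <- array(runif(B * L * A), c(B, L, A))
  for (k in seq_len(B)) {
    for (i in seq_len(L)) {
      p[k, i, ] <- mass * p[k, i, ] / sum(p[k, i, ])
    }
  }
  p
}

test_that("mrf_params enforces the symmetric zero-diagonal parameterization", {
  L <- 3; A <- 2
  W <- smurf:::sym_couplings(matrix(rnorm((L * A)^2), L * A, L * A), L, A)
  m <- mrf_params(matrix(0, L, A), W)
  expect_equal(m$couplings, t(m$couplings))
  Wbad <- W
  Wbad[1, 3] <- Wbad[1, 3] + 1
  expect_error(mrf_params(matrix(0, L, A), Wbad), "symmetric|asymmetric")
  Wdiag <- W
  Wdiag[1, 2] <- 1
  Wdiag[2, 1] <- 1
  expect_error(mrf_params(matrix(0, L, A), Wdiag), "self-couplings")
})

test_that("with zero couplings the prediction is softmax of the fields everywhere", {
  L <- 4; A <- 5; B <- 3
  fields <- matrix(rnorm(L * A), L, A)
  mrf <- mrf_params(fields, matrix(0, L * A, L * A))
  p <- make_profiles(B, L, A, seed = 2)
  mask <- sample_mask(B, L, 0.5, seed = 3)
  q <- mlm_predict(p, mask, mrf)
  for (i in seq_len(L)) {
    expected <- exp(fields[i, ]) / sum(exp(fields[i, ]))
    for (k in seq_len(B)) {
      expect_equal(q[k, i, ], expected, tolerance = 1e-12)
    }
  }
})

test_that("the two-state single-neighbour conditional matches its closed form", {
  # L = 2, A = 2, v = 0, W_01 = [[c, 0], [0, c]]; neighbour fixed at state 1:
  # P(masked site = state 1) = e^c / (e^c + 1)
  for (c_ in c(0.5, 1.5)) {
    W <- matrix(0, 4, 4)
    W[1, 3] <- c_; W[2, 4] <- c_
    W <- W + t(W)
    mrf <- mrf_params(matrix(0, 2, 2), W)
    p <- array(0, c(1, 2, 2))
    p[1, 1, 1] <- 1 # masked anyway
    p[1, 2, 1] <- 1 # unmasked neighbour: state 1
    mask <- matrix(c(TRUE, FALSE), 1, 2)
    q <- mlm_predict(p, mask, mrf)
    expect_equal(q[1, 1, 1], exp(c_) / (exp(c_) + 1), tolerance = 1e-12)
  }
})

test_that("hard one-hot profiles reproduce the Potts pseudolikelihood conditional", {
  set.seed(5)
  L <- 5; A <- 4; B <- 6
  fields <- matrix(rnorm(L * A, sd = 0.5), L, A)
  W <- smurf:::sym_couplings(matrix(rnorm((L * A)^2, sd = 0.3), L * A, L * A),
                             L, A)
  mrf <- mrf_params(fields, W)
  seqs <- matrix(sample.int(A, B * L, replace = TRUE), B, L)
  p <- array(0, c(B, L, A))
  p[cbind(rep(seq_len(B), L), rep(seq_len(L), each = B), as.vector(seqs))] <- 1
  # mask exactly one site per sequence
  mask <- matrix(FALSE, B, L)
  sites <- sample.int(L, B, replace = TRUE)
  mask[cbind(seq_len(B), sites)] <- TRUE
  q <- mlm_predict(p, mask, mrf)
  # independent conditional-probability oracle, written from the Potts
  # energy directly
  for (k in seq_len(B)) {
    i <- sites[k]
    logits <- fields[i, ]
    for (j in seq_len(L)[-i]) {
      blk <- W[smurf:::block_idx(i, A), smurf:::block_idx(j, A)]
      logits <- logits + blk[, seqs[k, j]]
    }
    expect_equal(q[k, i, ], exp(logits) / sum(exp(logits)),
                 tolerance = 1e-10)
  }
})

test_that("predicted distributions normalize even with soft and gapped profiles", {
  L <- 6; A <- 4; B <- 5
  p <- make_profiles(B, L, A, seed = 7, mass = 0.8)
  W <- smurf:::sym_couplings(matrix(rnorm((L * A)^2, sd = 0.2), L * A, L * A),
                             L, A)
  mrf <- mrf_params(matrix(rnorm(L * A), L, A), W)
  mask <- sample_mask(B, L, 0.3, seed = 8)
  q <- mlm_predict(p, mask, mrf)
  sums <- apply(q, c(1, 2), sum)
  expect_equal(as.vector(sums), rep(1, B * L), tolerance = 1e-6)
})

test_that("mlm_loss hits its closed-form corner cases", {
  L <- 4; A <- 3; B <- 2
  # zero-parameter MRF with one-hot targets: cross entropy log(A) per entry
  mrf0 <- mrf_params(matrix(0, L, A), matrix(0, L * A, L * A))
  p <- array(0, c(B, L, A))
  p[cbind(rep(seq_len(B), L), rep(seq_len(L), each = B),
          sample.int(A, B * L, replace = TRUE))] <- 1
  mask <- sample_mask(B, L, 0.5, seed = 9)
  expect_equal(as.numeric(mlm_loss(p, mask, mrf0, lambda_v = 0,
                                   lambda_w = 0)),
               log(A), tolerance = 1e-12)
  expect_error(mlm_loss(p, mask, mrf0, rate = 1.5), "between")

  # perfectly confident correct predictions: loss approaches zero
  fields <- matrix(-50, 1, A)
  fields[1, 1] <- 50
  mrf1 <- mrf_params(fields, matrix(0, A, A) * 0)
  p1 <- array(0, c(1, 1, A))
  p1[1, 1, 1] <- 1
  m1 <- matrix(TRUE, 1, 1)
  expect_lt(as.numeric(mlm_loss(p1, m1, mrf1, lambda_v = 0, lambda_w = 0)),
            1e-8)
})

test_that("mlm gradients match finite differences in fields, couplings and profiles", {
  set.seed(11)
  B <- 3; L <- 4; A <- 3
  p <- make_profiles(B, L, A, seed = 11, mass = 0.9)
  gap <- 1 - apply(p, c(1, 2), sum)
  mask <- sample_mask(B, L, 0.4, seed = 12)
  fields <- matrix(rnorm(L * A, sd = 0.4), L, A)
  W <- smurf:::sym_couplings(matrix(rnorm((L * A)^2, sd = 0.2), L * A, L * A),
                             L, A)
  g <- smurf:::mlm_loss_grad(p, gap, mask, fields, W, 0.01, 0.01)
  lossf <- function(fields, W, p) {
    gap <- 1 - apply(p, c(1, 2), sum)
    smurf:::mlm_loss_grad(p, gap, mask, fields, W, 0.01, 0.01,
                          want_grads = FALSE)$loss
  }
  eps <- 1e-6
  for (t in 1:5) {
    i <- sample(L, 1); a <- sample(A, 1)
    fp <- fields; fp[i, a] <- fp[i, a] + eps
    fm <- fields; fm[i, a] <- fm[i, a] - eps
    expect_equal(g$gfields[i, a], (lossf(fp, W, p) - lossf(fm, W, p)) / (2 * eps),
                 tolerance = 1e-5)
    k <- sample(B, 1)
    pp <- p; pp[k, i, a] <- pp[k, i, a] + eps
    pm <- p; pm[k, i, a] <- pm[k, i, a] - eps
    expect_equal(g$gprofiles[k, i, a],
                 (lossf(fields, W, pp) - lossf(fields, W, pm)) / (2 * eps),
                 tolerance = 1e-5)
  }
  for (t in 1:5) {
    u <- sample(L * A, 1); v <- sample(L * A, 1)
    if (((u - 1) %/% A) == ((v - 1) %/% A)) next # skip diagonal blocks
    Wp <- W; Wp[u, v] <- Wp[u, v] + eps; Wp[v, u] <- Wp[v, u] + eps
    Wm <- W; Wm[u, v] <- Wm[u, v] - eps; Wm[v, u] <- Wm[v, u] - eps
    fd <- (lossf(fields, Wp, p) - lossf(fields, Wm, p)) / (2 * eps)
    expect_equal(g$gW[u, v] + g$gW[v, u], fd, tolerance = 1e-5)
  }
})

test_that("sample_mask is reproducible with the requested statistics", {
  m1 <- sample_mask(20, 30, 0.15, seed = 13)
  m2 <- sample_mask(20, 30, 0.15, seed = 13)
  expect_identical(m1, m2)
  expect_true(all(rowSums(m1) >= 1))
  expect_true(all(sample_mask(5, 8, 1.0, seed = 1)))
  expect_error(sample_mask(5, 8, 0), "0, 1")

  # empirical fraction within 3 binomial standard errors of the rate
  big <- sample_mask(100, 100, 0.15, seed = 14)
  se <- sqrt(0.15 * 0.85 / length(big))
  expect_lt(abs(mean(big) - 0.15), 3 * se + 0.002) # small redraw bias allowance
})

test_that("contact scores find planted couplings and APC kills rank-one background", {
  L <- 8; A <- 3
  expect_equal(contact_scores(mrf_params(matrix(0, L, A),
                                         matrix(0, L * A, L * A))),
               matrix(0, L, L))

  # single planted block: raw argmax at the planted pair
  W <- matrix(0, L * A, L * A)
  blk <- diag(A) * 2
  W[smurf:::block_idx(2, A), smurf:::block_idx(7, A)] <- blk
  W[smurf:::block_idx(7, A), smurf:::block_idx(2, A)] <- t(blk)
  s <- contact_scores(mrf_params(matrix(0, L, A), W))
  expect_equal(s, t(s))
  expect_equal(diag(s), rep(0, L))
  idx <- which(s == max(s), arr.ind = TRUE)
  expect_true(all(sort(idx[1, ]) == c(2, 7)))

  # APC of a rank-one matrix is identically ~0
  r <- runif(6, 0.5, 2)
  expect_lt(max(abs(smurf:::apc(outer(r, r)))), 1e-8)

  expect_error(contact_scores(mrf_params(matrix(0, 2, A),
                                         matrix(0, 2 * A, 2 * A))), "L >= 3")
})
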