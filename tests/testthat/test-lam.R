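test_that("one-hot encoding validates symbols and zeroes the unknown residue", {
  X <- seq_onehot("ACX", "protein")
  expect_equal(dim(X), c(3L, 20L))
  expect_equal(rowSums(X), c(A = 1, C = 1, X = 0))
  expect_error(seq_onehot("AC*Z", "protein"), "position")
  expect_equal(rowSums(seq_onehot("ACGUN", "rna")), c(A = 1, C = 1, G = 1,
                                                      U = 1, N = 0))
})

test_that("encoding with window 0 is a per-residue linear map", {
  A <- 20
  K <- matrix(rnorm(A * 6), A, 6)
  enc <- encoder_params(K, rnorm(6), 0, "protein")
  X <- seq_onehot("ACDE", "protein")
  E <- encode(X, enc)
  for (i in 1:4) {
    expect_equal(E[i, ], as.vector(X[i, , drop = FALSE] %*% K) + enc$bias)
  }
})

test_that("encoder output is local: edits outside the window leave a row unchanged", {
  w <- 2L
  enc <- init_encoder(w, 8, "protein", seed = 1)
  s1 <- "ACDEFGHIKL"
  s2 <- "ACDEFGHIKV" # position 10 differs
  E1 <- encode(s1, enc)
  E2 <- encode(s2, enc)
  # rows 1..7 have windows ending at position <= 9: unchanged
  expect_equal(E1[1:7, ], E2[1:7, ])
  expect_false(isTRUE(all.equal(E1[10, ], E2[10, ])))
})

test_that("zero kernel and bias give an all-zero embedding", {
  enc <- encoder_params(matrix(0, 3 * 20, 4), rep(0, 4), 1, "protein")
  expect_equal(unname(encode("ACDEF", enc)), matrix(0, 5, 4))
})

test_that("similarity is the dot-product matrix of the embeddings", {
  E <- diag(4)
  expect_equal(similarity(E, E), diag(4)) # unit basis: Kronecker delta
  V <- matrix(rnorm(12), 3, 4)
  S <- similarity(V, V)
  expect_equal(S, t(S))
  expect_equal(diag(S), rowSums(V^2))
  expect_equal(similarity(V, matrix(0, 2, 4)), matrix(0, 3, 2))
  expect_error(similarity(V, matrix(0, 2, 5)), "filter")
})

test_that("build_alignment_tensor composes encode, similarity and posterior", {
  enc <- init_encoder(2, 8, "protein", seed = 4)
  ap <- align_params(gap_mode = "affine", open = -2, extend = -0.5,
                     align_mode = "global")
  query <- "ACDEFGHIK"
  seqs <- list("ACDEFGHK", "CDEFGHIKL")
  tensor <- build_alignment_tensor(seqs, query, enc, ap)
  Eq <- encode(query, enc)
  for (k in seq_along(seqs)) {
    direct <- smooth_posterior(similarity(Eq, encode(seqs[[k]], enc)), ap)
    expect_equal(as.vector(tensor[[k]]), as.vector(direct), tolerance = 1e-12)
  }
  expect_error(build_alignment_tensor(list(), query, enc, ap), "non-empty")
})

test_that("a high-gain encoder aligns the query to itself as the identity", {
  enc <- init_encoder(2, 32, "protein", seed = 5, gain = 3)
  ap <- align_params(temperature = 0.1, gap_mode = "affine", open = -3,
                     extend = -0.5, align_mode = "global")
  q <- "ACDEFGHIKLMNP"
  P <- build_alignment_tensor(list(q), q, enc, ap)[[1]]
  expect_equal(as.vector(P), as.vector(diag(nchar(q))), tolerance = 1e-3)
})

test_that("end-to-end encoder gradients match finite differences", {
  set.seed(6)
  enc <- init_encoder(1, 6, "protein", seed = 6)
  ap <- align_params(gap_mode = "affine", open = -2, extend = -0.5,
                     align_mode = "global", restrict_turns = TRUE)
  query <- random_onehot_seq(8)
  seqs <- lapply(c(7, 9), random_onehot_seq)
  Xq <- seq_onehot(query, "protein")
  Xs <- lapply(seqs, seq_onehot, "protein")
  # scalar functional of the whole tensor: the bootstrap purity loss
  fw <- smurf:::lam_forward(Xq, Xs, enc, ap)
  g <- smurf:::lam_backward(fw, smurf:::basic_align_grad(fw$profiles),
                            Xq, Xs, enc, ap)
  lossf <- function(e) basic_align_loss(seqs, query, e, ap)
  for (t in 1:8) {
    u <- sample(nrow(enc$kernel), 1)
    v <- sample(ncol(enc$kernel), 1)
    ep <- enc; ep$kernel[u, v] <- ep$kernel[u, v] + 1e-5
    em <- enc; em$kernel[u, v] <- em$kernel[u, v] - 1e-5
    fd <- (lossf(ep) - lossf(em)) / 2e-5
    expect_equal(g$kernel[u, v], fd, tolerance = 1e-3)
  }
  b <- sample(length(enc$bias), 1)
  ep <- enc; ep$bias[b] <- ep$bias[b] + 1e-5
  em <- enc; em$bias[b] <- em$bias[b] - 1e-5
  expect_equal(g$bias[b], (lossf(ep) - lossf(em)) / 2e-5, tolerance = 1e-3)
})

test_that("soft MSA rows are distributions: profile plus gap mass is one", {
  enc <- init_encoder(2, 8, "protein", seed = 8)
  ap <- align_params(gap_mode = "affine", open = -2, extend = -0.5,
                     align_mode = "local")
  query <- random_onehot_seq(10)
  seqs <- lapply(c(9, 11, 10), random_onehot_seq)
  tensor <- build_alignment_tensor(seqs, query, enc, ap)
  msa <- soft_msa(tensor, seqs, "protein")
  expect_true(all(msa$profiles >= -1e-10))
  total <- apply(msa$profiles, c(1, 2), sum) + msa$gap_mass
  expect_equal(as.vector(total), rep(1, length(total)), tolerance = 1e-6)
})

test_that("soft_msa contracts posteriors with the one-hot sequences", {
  X <- seq_onehot("ACD", "protein")
  # hard identity posterior reproduces the sequence itself
  msa <- soft_msa(list(diag(3)), list(X), "protein")
  expect_equal(matrix(msa$profiles[1, , ], 3, 20), unname(X))
  expect_equal(as.vector(msa$gap_mass), rep(0, 3))
  # all-zero posterior puts all mass on gaps
  msa0 <- soft_msa(list(matrix(0, 3, 3)), list(X), "protein")
  expect_equal(as.vector(msa0$gap_mass), rep(1, 3))
  # the two-path one-cell posterior splits mass evenly
  msa5 <- soft_msa(list(matrix(0.5, 1, 1)), list(seq_onehot("A", "protein")),
                   "protein")
  expect_equal(msa5$profiles[1, 1, 1], 0.5)
  expect_equal(msa5$gap_mass[1, 1], 0.5)
  expect_error(soft_msa(list(diag(3)), list(seq_onehot("AC", "protein"))),
               "residues")
})

test_that("harden_msa writes a faithful A3M that round-trips through files", {
  # window 0: scores depend on residue identity alone, so the alignment of
  # a sequence with one residue deleted is forced to gap the planted column
  enc <- init_encoder(0, 32, "protein", seed = 9, gain = 3)
  ap <- align_params(gap_mode = "affine", open = -3, extend = -0.5,
                     align_mode = "global")
  q <- "ACDEFGHIKL"
  # identical sequences with a strong encoder give gapless identical rows
  msa <- harden_msa(list(q, q), q, enc, ap)
  expect_equal(unname(unclass(msa)), rep(q, 3))

  # planted single deletion shows up as exactly one '-'
  del <- "ACDEGHIKL" # F removed
  msa2 <- harden_msa(list(del), q, enc, ap)
  expect_equal(unclass(msa2)[[2]], "ACDE-GHIKL")

  tmp <- tempfile(fileext = ".a3m")
  write_a3m(msa2, tmp)
  expect_equal(unclass(read_a3m(tmp)), unclass(msa2))
})
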