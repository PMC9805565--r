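# GREMLIN-style Markov random field over query columns, trained by masked
# language modelling on (soft or hard) alignment profiles.  Couplings are
# stored as one flat (L*A) x (L*A) matrix whose (i,j) residue blocks are the
# pairwise terms; the symmetric parameterization W = (Wraw + Wraw')/2 with
# zeroed diagonal blocks is enforced throughout, and the residue alphabet
# carries no explicit gap state: gap mass in a profile simply contributes
# nothing to the energy.

#' Markov random field parameters
#'
#' Site fields `v` (`L x A`) and pairwise couplings `W` stored as a flat
#' `(L*A) x (L*A)` matrix of residue blocks.  Valid couplings are symmetric
#' as a flat matrix (equivalent to `W_ij[a,b] = W_ji[b,a]`) with all-zero
#' diagonal blocks (`W_ii = 0`).
#'
#' @param fields Numeric `L x A` matrix of site terms.
#' @param couplings Numeric `(L*A) x (L*A)` matrix of pairwise terms.
#' @return An object of class `mrf_params` with elements `fields`,
#'   `couplings`, `L`, `A`.
#' @export
mrf_params <- function(fields, couplings) {
  fields <- as.matrix(fields)
  L <- nrow(fields)
  A <- ncol(fields)
  couplings <- as.matrix(couplings)
  if (nrow(couplings) != L * A || ncol(couplings) != L * A) {
    stop(sprintf("couplings must be %d x %d", L * A, L * A), call. = FALSE)
  }
  if (max(abs(couplings - t(couplings))) > 1e-8) {
    stop("asymmetric couplings: W_ij[a,b] must equal W_ji[b,a]",
         call. = FALSE)
  }
  for (i in seq_len(L)) {
    blk <- block_idx(i, A)
    if (any(couplings[blk, blk] != 0)) {
      stop("self-couplings W_ii must be zero", call. = FALSE)
    }
  }
  structure(list(fields = fields, couplings = couplings, L = L, A = A),
            class = "mrf_params")
}

block_idx <- function(i, A) ((i - 1L) * A + 1L):(i * A)

# symmetrize a raw coupling matrix and zero its diagonal blocks; this is
# the map from unconstrained training parameters to valid couplings
sym_couplings <- function(Wraw, L, A) {
  W <- 0.5 * (Wraw + t(Wraw))
  for (i in seq_len(L)) {
    blk <- block_idx(i, A)
    W[blk, blk] <- 0
  }
  W
}

#' @export
print.mrf_params <- function(x, ...) {
  cat(sprintf("<mrf_params> L = %d columns, A = %d states, ||v|| = %.3g, ||W|| = %.3g\n",
              x$L, x$A, sqrt(sum(x$fields^2)), sqrt(sum(x$couplings^2))))
  invisible(x)
}

#' Sample a masked-language-modelling mask
#'
#' Independent Bernoulli(`rate`) masking of every (sequence, column) entry,
#' re-drawn per sequence until each sequence has at least one masked entry.
#'
#' @param B,L Number of sequences and query columns.
#' @param rate Masking probability in (0, 1].
#' @param seed Integer seed (reproducible: equal seeds give equal masks).
#' @return A `B x L` logical matrix.
#' @export
sample_mask <- function(B, L, rate, seed = NULL) {
  if (!is.numeric(rate) || rate <= 0 || rate > 1) {
    stop("`rate` must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  draw_mask(B, L, rate)
}

# mask draw from the current RNG stream (used inside training loops)
draw_mask <- function(B, L, rate) {
  m <- matrix(runif(B * L) < rate, B, L)
  empty <- which(rowSums(m) == 0L)
  while (length(empty) > 0L) {
    m[empty, ] <- matrix(runif(length(empty) * L) < rate, length(empty), L)
    empty <- empty[rowSums(m[empty, , drop = FALSE]) == 0L]
  }
  m
}

as_profiles <- function(profiles) {
  if (inherits(profiles, "soft_msa")) {
    list(p = profiles$profiles, gap = profiles$gap_mass)
  } else if (is.array(profiles) && length(dim(profiles)) == 3L) {
    p <- profiles
    gap <- 1 - apply(p, c(1, 2), sum)
    list(p = p, gap = gap)
  } else {
    stop("`profiles` must be a soft_msa or a B x L x A array", call. = FALSE)
  }
}

flatten_profiles <- function(p) {
  d <- dim(p) # B x L x A
  # flat row s holds (column 1 residues, column 2 residues, ...)
  out <- matrix(aperm(p, c(1, 3, 2)), d[1], d[2] * d[3])
  # aperm gives B x A x L; matrix() reads column-major so flat index runs a
  # fastest within each column block only if we permute to (B, A, L)
  out
}

unflatten_profiles <- function(flat, L, A) {
  B <- nrow(flat)
  aperm(array(flat, c(B, A, L)), c(1, 3, 2))
}

#' Masked-residue predictions from the MRF energy
#'
#' For every (sequence, column) entry the MRF's conditional distribution
#' over residues is computed from the masked input: masked entries are
#' replaced by the all-zero profile (they contribute nothing to any
#' neighbour's energy), and the logits at column `i` are
#' `v_i[a] + sum_{j != i} sum_b W_ij[a,b] * profile[s, j, b]`.
#' Predictions are meaningful at masked entries; unmasked entries receive
#' the same conditional computed from the identical masked input.
#'
#' @param profiles A [soft_msa()] or `B x L x A` array.
#' @param mask A `B x L` logical matrix from [sample_mask()].
#' @param mrf An [mrf_params()] object.
#' @return A `B x L x A` array of residue distributions (each slice sums
#'   to 1).
#' @export
mlm_predict <- function(profiles, mask, mrf) {
  pr <- as_profiles(profiles)
  stopifnot(inherits(mrf, "mrf_params"))
  d <- dim(pr$p)
  if (!all(d[2:3] == c(mrf$L, mrf$A)) || !all(dim(mask) == d[1:2])) {
    stop("profile / mask / MRF shapes do not agree", call. = FALSE)
  }
  q <- mlm_forward(pr$p, pr$gap, mask, mrf$fields, mrf$couplings)$q
  unflatten_profiles(q, mrf$L, mrf$A)
}

# forward pass shared by prediction, loss and training.
# pflat etc. computed here once; returns softmax predictions and pieces
# needed for the gradient.
mlm_forward <- function(p, gap, mask, fields, W) {
  d <- dim(p)
  B <- d[1]; L <- d[2]; A <- d[3]
  pflat <- flatten_profiles(p)
  maskflat <- mask[, rep(seq_len(L), each = A), drop = FALSE]
  pm <- pflat
  pm[maskflat] <- 0
  logits <- pm %*% W + matrix(as.vector(t(fields)), B, L * A, byrow = TRUE)
  # softmax over residues within each column
  q <- matrix(0, B, L * A)
  for (i in seq_len(L)) {
    blk <- block_idx(i, A)
    z <- logits[, blk, drop = FALSE]
    z <- z - apply(z, 1, max)
    ez <- exp(z)
    q[, blk] <- ez / rowSums(ez)
  }
  list(q = q, pm = pm, pflat = pflat, maskflat = maskflat, B = B, L = L, A = A)
}

#' Masked-language-modelling loss
#'
#' Mean cross entropy, over masked entries, between the MRF's conditional
#' predictions (computed from the masked input) and the true pre-mask
#' profile, plus L2 regularization of the MRF parameters.  Profile mass not
#' assigned to any residue (gap/insertion mass) is spread uniformly over
#' the residue alphabet in the target, so columns a sequence does not align
#' to contribute a uniform target.
#'
#' The regularizer is
#' `(lambda_v * ||v||^2 + lambda_w * (L-1) * (A-1) / 2 * ||W||^2) / B`,
#' the usual GREMLIN-style scaling of coupling versus field penalties.
#'
#' @inheritParams mlm_predict
#' @param lambda_v,lambda_w Regularization weights (defaults 0.01).
#' @param rate Masking rate used only for validation of the mask (fraction
#'   of masked entries must be positive and below 1 on average); ignored if
#'   `NULL`.
#' @return The scalar loss, with attribute `"cross_entropy"` holding the
#'   unregularized term.
#' @export
mlm_loss <- function(profiles, mask, mrf, lambda_v = 0.01, lambda_w = 0.01,
                     rate = NULL) {
  if (!is.null(rate) && (rate <= 0 || rate >= 1)) {
    stop("`rate` must lie strictly between 0 and 1", call. = FALSE)
  }
  pr <- as_profiles(profiles)
  res <- mlm_loss_grad(pr$p, pr$gap, mask, mrf$fields, mrf$couplings,
                       lambda_v, lambda_w, want_grads = FALSE)
  structure(res$loss, cross_entropy = res$ce)
}

# loss + exact gradients. fields (L x A), W flat symmetric.  Returns
# gradients with respect to fields, W (symmetric direction) and the
# (unmasked) profiles; the profile gradient includes both the input side
# (through neighbours' logits) and the target side (the pre-mask profile is
# the cross-entropy target).
mlm_loss_grad <- function(p, gap, mask, fields, W, lambda_v, lambda_w,
                          want_grads = TRUE) {
  fw <- mlm_forward(p, gap, mask, fields, W)
  B <- fw$B; L <- fw$L; A <- fw$A
  # target: profile plus gap mass spread uniformly over residues
  tgt <- fw$pflat + gap[, rep(seq_len(L), each = A), drop = FALSE] / A
  logq <- matrix(0, B, L * A)
  for (i in seq_len(L)) {
    blk <- block_idx(i, A)
    z <- fw$q[, blk, drop = FALSE]
    logq[, blk] <- log(pmax(z, 1e-300))
  }
  nmask <- sum(mask)
  ce_entry <- -(tgt * logq)
  maskflat <- fw$maskflat
  ce <- sum(ce_entry[maskflat]) / nmask
  regv <- lambda_v * sum(fields^2)
  regw <- lambda_w * 0.5 * (L - 1) * (A - 1) * sum(W^2)
  loss <- ce + (regv + regw) / B
  if (!want_grads) return(list(loss = loss, ce = ce))

  # dCE/dlogits at masked entries: (q * sum_a tgt_a - tgt) per column block
  G <- matrix(0, B, L * A)
  for (i in seq_len(L)) {
    blk <- block_idx(i, A)
    tb <- tgt[, blk, drop = FALSE]
    qb <- fw$q[, blk, drop = FALSE]
    gb <- (qb * rowSums(tb) - tb) / nmask
    gb[!mask[, i], ] <- 0
    G[, blk] <- gb
  }
  gfields <- matrix(colSums(G), A, L) # flat is column-major within blocks
  gfields <- t(gfields) + 2 * lambda_v * fields / B
  gW_lin <- crossprod(fw$pm, G)
  gW <- 0.5 * (gW_lin + t(gW_lin)) # symmetric direction (W constrained symmetric)
  gW <- gW + 2 * (lambda_w * 0.5 * (L - 1) * (A - 1) / B) * W
  for (i in seq_len(L)) {
    blk <- block_idx(i, A)
    gW[blk, blk] <- 0
  }
  # profile gradient: input side through neighbours (masked entries were
  # zeroed, so they get no input-side gradient) ...
  gpm <- G %*% W # W symmetric
  gpm[maskflat] <- 0
  # ... plus target side at masked entries; target t_a = p_a + gap/A with
  # gap = 1 - sum_b p_b, so dt_a/dp_c = delta_ac - 1/A
  gtgt <- -logq / nmask
  gtgt[!maskflat] <- 0
  for (i in seq_len(L)) {
    blk <- block_idx(i, A)
    gb <- gtgt[, blk, drop = FALSE]
    gtgt[, blk] <- gb - rowMeans(gb)
  }
  gp <- unflatten_profiles(gpm + gtgt, L, A)
  list(loss = loss, ce = ce, gfields = gfields, gW = gW, gprofiles = gp)
}

#' Contact scores from MRF couplings
#'
#' The raw interaction strength between columns `i` and `j` is the
#' Frobenius norm of the residue coupling block `W_ij`; the returned scores
#' apply the standard average-product correction (APC),
#' `score_ij = raw_ij - rowmean_i * rowmean_j / grandmean`, which removes
#' per-column background coupling caused by conservation and sampling
#' noise.  Scores are symmetric with a zero diagonal; higher means more
#' likely in contact.
#'
#' @param mrf An [mrf_params()] object with at least 3 columns.
#' @return An `L x L` numeric score matrix.
#' @export
contact_scores <- function(mrf) {
  stopifnot(inherits(mrf, "mrf_params"))
  if (mrf$L < 3L) stop("contact scoring needs L >= 3 columns", call. = FALSE)
  arr <- array(mrf$couplings, c(mrf$A, mrf$L, mrf$A, mrf$L))
  raw <- sqrt(apply(arr^2, c(2, 4), sum))
  s <- apc(raw)
  diag(s) <- 0
  0.5 * (s + t(s))
}

# average-product correction of a raw coupling-norm matrix
apc <- function(raw) {
  gm <- mean(raw)
  if (gm == 0) return(raw)
  raw - outer(rowMeans(raw), colMeans(raw)) / gm
}
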