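#' Smoothed pairwise alignment score
#'
#' Computes the logsumexp relaxation of the optimal alignment score:
#' `T * log( sum over paths of exp(path_score / T) )`, where the sum runs
#' over every alignment path permitted by `params` (see [align_params()]).
#' The computation is a three-state (match / deletion / insertion) dynamic
#' program in log space; it never enumerates paths and is stable for
#' temperatures down to about 1e-2 with scores up to about 1e3.
#'
#' As `temperature` approaches 0 the smooth score converges from above to
#' the classic optimal-alignment score of [hard_align()].
#'
#' @param a Numeric score matrix; entry `a[i, j]` is the score for aligning
#'   residue `i` of the first sequence with residue `j` of the second.
#' @param params An [align_params()] object.
#' @return A single numeric score.
#' @seealso [smooth_posterior()], [hard_align()], [brute_force_smooth_score()]
#' @examples
#' a <- matrix(c(2, -1, -1, 2), 2, 2)
#' smooth_score(a, align_params(temperature = 0.05, gap = -1))
#' hard_align(a, align_params(gap = -1))$score
#' @export
smooth_score <- function(a, params) {
  params <- as_align_params(params)
  check_score_matrix(a)
  cpp_sw_score(a, params$temperature, params$open, params$extend,
               params$align_mode == "local", params$restrict_turns)
}

#' Posterior alignment matrix
#'
#' The derivative of [smooth_score()] with respect to the match scores,
#' which equals the expectation of the match-indicator matrix under the
#' Gibbs distribution over paths `p(path) = exp(path_score / T) / Z`: entry
#' `(i, j)` is the probability that residues `i` and `j` are aligned.  All
#' entries lie in `[0, 1]`, and every row and column sums to at most 1
#' (a residue is matched at most once on any path).
#'
#' @inheritParams smooth_score
#' @return A numeric matrix of match probabilities with the same shape as
#'   `a`, with the smooth score attached as attribute `"score"`.
#' @examples
#' smooth_posterior(matrix(0), align_params())[1, 1]  # two equiprobable paths
#' @export
smooth_posterior <- function(a, params) {
  params <- as_align_params(params)
  check_score_matrix(a)
  res <- cpp_sw_posterior(a, params$temperature, params$open, params$extend,
                          params$align_mode == "local", params$restrict_turns)
  structure(res$posterior, score = res$score)
}

#' Batched posterior alignment over padded score matrices
#'
#' Applies [smooth_posterior()] to each slice of a stack of score matrices
#' that have been padded to a common shape.  Only the leading
#' `len_x[k] x len_y[k]` block of slice `k` is read, so padding values can
#' never influence the result.
#'
#' @param a_stack Either a list of numeric matrices or a 3-d array with
#'   dimensions `(batch, max_len_x, max_len_y)`.
#' @param len_x,len_y Integer vectors of true lengths per item.
#' @inheritParams smooth_score
#' @return A list of posterior matrices, item `k` of shape
#'   `len_x[k] x len_y[k]`.
#' @export
smooth_posterior_batch <- function(a_stack, len_x, len_y, params) {
  params <- as_align_params(params)
  if (is.array(a_stack) && length(dim(a_stack)) == 3L) {
    B <- dim(a_stack)[1L]
    a_stack <- lapply(seq_len(B), function(k) {
      matrix(a_stack[k, , ], dim(a_stack)[2L], dim(a_stack)[3L])
    })
  }
  if (!is.list(a_stack) || length(a_stack) == 0L) {
    stop("`a_stack` must be a non-empty list or 3-d array", call. = FALSE)
  }
  B <- length(a_stack)
  len_x <- rep_len(as.integer(len_x), B)
  len_y <- rep_len(as.integer(len_y), B)
  slices <- vector("list", B)
  for (k in seq_len(B)) {
    a <- a_stack[[k]]
    if (len_x[k] > nrow(a) || len_y[k] > ncol(a)) {
      stop(sprintf("item %d: true length (%d x %d) exceeds padded shape (%d x %d)",
                   k, len_x[k], len_y[k], nrow(a), ncol(a)), call. = FALSE)
    }
    if (len_x[k] < 1L || len_y[k] < 1L) {
      stop(sprintf("item %d: true lengths must be positive", k), call. = FALSE)
    }
    slices[[k]] <- a[seq_len(len_x[k]), seq_len(len_y[k]), drop = FALSE]
    check_score_matrix(slices[[k]])
  }
  res <- cpp_sw_posterior_batch(slices, params$temperature, params$open,
                                params$extend, params$align_mode == "local",
                                params$restrict_turns)
  lapply(res, function(r) structure(r$posterior, score = r$score))
}

#' Optimal (hard) pairwise alignment
#'
#' Classic max/argmax dynamic programming with traceback, under exactly the
#' same path conventions as [smooth_score()].  Traceback ties are broken
#' with the fixed priority match > insertion (gap in the first sequence) >
#' deletion (gap in the second sequence); in local mode the highest-scoring
#' end cell encountered first in row-major order is used, so the result is
#' deterministic.
#'
#' @inheritParams smooth_score
#' @return A list with `score` (numeric) and `path`, a two-column integer
#'   matrix of 0-based `(i, j)` match coordinates, strictly increasing in
#'   both columns (zero rows for an empty local alignment).
#' @export
hard_align <- function(a, params) {
  params <- as_align_params(params)
  check_score_matrix(a)
  res <- cpp_sw_hard(a, params$open, params$extend,
                     params$align_mode == "local", params$restrict_turns)
  colnames(res$path) <- c("i", "j")
  res
}

# Vector-Jacobian product through the posterior map, for internal training
# use: given dL/dP, returns dL/da.  Exposed for gradient tests.
sw_posterior_vjp <- function(a, pbar, params) {
  params <- as_align_params(params)
  cpp_sw_vjp(a, pbar, params$temperature, params$open, params$extend,
             params$align_mode == "local", params$restrict_turns)
}
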