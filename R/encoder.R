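# Convolutional residue-context encoder: a single linear convolution of
# window 2w+1 applied to the one-hot sequence, with zero ("same") padding so
# that output row i depends only on residues i-w .. i+w and the output has
# one row per residue.  Similarity scores between two sequences are dot
# products of encoder outputs, which is what the smooth aligner consumes.

#' Encoder parameters
#'
#' A single linear convolution (no activation) of window `2w + 1` over
#' one-hot residues.  The kernel is stored flattened as a
#' `((2w+1) * alphabet_size) x filters` matrix whose row blocks correspond
#' to window offsets `-w, ..., +w`.
#'
#' @param kernel Flattened kernel matrix, `((2w+1)*A) x filters`.
#' @param bias Numeric vector of length `filters`.
#' @param window_half_width Non-negative integer `w`; the window is `2w+1`.
#' @param alphabet A [smurf_alphabet()] or `"protein"` / `"rna"`.
#' @return An object of class `encoder_params`.
#' @seealso [init_encoder()] for random initialization, [encode()]
#' @export
encoder_params <- function(kernel, bias, window_half_width, alphabet = "protein") {
  alphabet <- as_alphabet(alphabet)
  w <- as.integer(window_half_width)
  if (w < 0L) stop("`window_half_width` must be >= 0", call. = FALSE)
  A <- alphabet$size
  kernel <- as.matrix(kernel)
  if (nrow(kernel) != (2L * w + 1L) * A) {
    stop(sprintf("kernel must have (2w+1)*A = %d rows, got %d",
                 (2L * w + 1L) * A, nrow(kernel)), call. = FALSE)
  }
  if (length(bias) != ncol(kernel)) {
    stop("`bias` length must equal the number of filters", call. = FALSE)
  }
  if (!all(is.finite(kernel)) || !all(is.finite(bias))) {
    stop("encoder parameters must be finite", call. = FALSE)
  }
  structure(list(window_half_width = w, filters = ncol(kernel),
                 alphabet = alphabet, kernel = kernel,
                 bias = as.numeric(bias)),
            class = "encoder_params")
}

#' Randomly initialized encoder
#'
#' Kernel entries are drawn from a normal distribution scaled by
#' `1 / sqrt(fan_in)` with `fan_in = (2w+1) * alphabet_size`; the bias
#' starts at zero.  Because the implied score matrix `E_q E_k'` is then a
#' positive-semidefinite quadratic form in the one-hot windows, a fresh
#' random encoder already scores identical residue windows higher than
#' unrelated ones, which is what makes alignment bootstrap training work
#' from scratch.
#'
#' @param window_half_width Window half width `w` (default 9, window 19).
#' @param filters Number of convolutional filters (default 512).
#' @param alphabet A [smurf_alphabet()] or `"protein"` / `"rna"`.
#' @param seed Integer seed for reproducible initialization.
#' @param gain Multiplier on the initialization scale.  Values above 1
#'   raise the typical match score relative to the gap penalties, which
#'   saturates the posterior on confident matches; the training loops use
#'   gain 2 so that the alignment bootstrap starts from (and stays near)
#'   high-coverage alignments.
#' @return An `encoder_params` object.
#' @export
init_encoder <- function(window_half_width = 9L, filters = 512L,
                         alphabet = "protein", seed = 0L, gain = 1) {
  alphabet <- as_alphabet(alphabet)
  w <- as.integer(window_half_width)
  fan_in <- (2L * w + 1L) * alphabet$size
  set.seed(seed)
  kernel <- matrix(rnorm(fan_in * filters, sd = gain / sqrt(fan_in)),
                   fan_in, filters)
  encoder_params(kernel, rep(0, filters), w, alphabet)
}

#' @export
print.encoder_params <- function(x, ...) {
  cat(sprintf("<encoder_params> window %d (w = %d), %d filters, %s alphabet\n",
              2L * x$window_half_width + 1L, x$window_half_width, x$filters,
              x$alphabet$type))
  invisible(x)
}

# one-hot sequence -> stacked context windows, zero-padded at the ends:
# column block o (1..2w+1) of row i holds the one-hot of residue i + o - w - 1
context_matrix <- function(X, w) {
  l <- nrow(X)
  A <- ncol(X)
  if (w == 0L) return(X)
  blocks <- vector("list", 2L * w + 1L)
  zero <- function(k) matrix(0, k, A)
  for (o in seq(-w, w)) {
    shifted <- if (o < 0) {
      rbind(zero(-o), X[seq_len(l + o), , drop = FALSE])
    } else if (o > 0) {
      rbind(X[seq(o + 1L, l), , drop = FALSE], zero(o))
    } else {
      X
    }
    blocks[[o + w + 1L]] <- shifted
  }
  do.call(cbind, blocks)
}

#' Encode a sequence into residue-context vectors
#'
#' Applies the encoder convolution to a sequence.  The output has one row
#' per residue; row `i` is a linear function of the one-hot residues in the
#' window `i-w .. i+w` only (zero-padded past the sequence ends).
#'
#' @param seq A sequence string, character vector, or a one-hot matrix from
#'   [seq_onehot()].
#' @param enc An [encoder_params()] object.
#' @return A numeric `length x filters` matrix of context embeddings.
#' @export
encode <- function(seq, enc) {
  stopifnot(inherits(enc, "encoder_params"))
  X <- if (is.matrix(seq)) seq else seq_onehot(seq, enc$alphabet)
  if (ncol(X) != enc$alphabet$size) {
    stop("one-hot width does not match the encoder alphabet", call. = FALSE)
  }
  ctx <- context_matrix(X, enc$window_half_width)
  sweep(ctx %*% enc$kernel, 2, enc$bias, "+")
}

# gradient of a scalar loss through encode(): given dL/dE, accumulate
# kernel and bias gradients (the one-hot input is data, not a parameter)
encode_backward <- function(X, w, dE) {
  ctx <- context_matrix(X, w)
  list(kernel = crossprod(ctx, dE), bias = colSums(dE))
}

#' Similarity matrix between two encoded sequences
#'
#' Entry `(i, j)` is the dot product of row `i` of the query embedding and
#' row `j` of the other embedding; this matrix is the score input to the
#' smooth aligner.
#'
#' @param query,other Embedding matrices from [encode()] with the same
#'   number of filters.
#' @return A numeric `len_query x len_other` score matrix.
#' @export
similarity <- function(query, other) {
  if (!is.matrix(query) || !is.matrix(other) || ncol(query) != ncol(other)) {
    stop("embeddings must be matrices with matching filter dimension",
         call. = FALSE)
  }
  tcrossprod(query, other)
}

#' Align every sequence of a family to the query
#'
#' The full learned-alignment forward pass: encode the query and each
#' sequence, form each similarity matrix, and run the smooth aligner on it.
#' The whole map is differentiable with respect to the encoder parameters
#' (the training routines use exact reverse-mode gradients through it).
#'
#' @param seqs A list of sequences (strings, character vectors, or one-hot
#'   matrices).
#' @param query The query sequence (same forms accepted).
#' @param enc An [encoder_params()] object.
#' @param params An [align_params()] object.
#' @return A list of posterior alignment matrices, one per sequence, each
#'   of shape `len_query x len_k`.
#' @export
build_alignment_tensor <- function(seqs, query, enc, params) {
  if (!is.list(seqs) || length(seqs) == 0L) {
    stop("`seqs` must be a non-empty list of sequences", call. = FALSE)
  }
  params <- as_align_params(params)
  Xq <- onehot_of(query, enc)
  Eq <- encode(Xq, enc)
  lapply(seqs, function(s) {
    Ek <- encode(onehot_of(s, enc), enc)
    smooth_posterior(similarity(Eq, Ek), params)
  })
}

onehot_of <- function(seq, enc) {
  if (is.matrix(seq)) seq else seq_onehot(seq, enc$alphabet)
}

#' Assemble a soft MSA from posterior alignments
#'
#' Contracts each posterior alignment with its one-hot sequence: the
#' profile row of sequence `k` at query column `i` is
#' `sum_j P_k[i, j] * onehot_k[j, ]`, the expected residue distribution the
#' sequence contributes to that column.  The remaining mass
#' `1 - sum(profile)` is gap mass (the probability the column is unmatched
#' in that sequence, plus any mass on unknown residues).
#'
#' @param alignments List of posterior matrices (query length x sequence
#'   length), e.g. from [build_alignment_tensor()].
#' @param seqs List of sequences or one-hot matrices matching `alignments`.
#' @param alphabet Alphabet used to one-hot plain sequences.
#' @return An object of class `soft_msa`: list with `profiles` (array
#'   `B x L x A`), `gap_mass` (matrix `B x L`) and `alphabet`.
#' @export
soft_msa <- function(alignments, seqs, alphabet = "protein") {
  alphabet <- as_alphabet(alphabet)
  if (length(alignments) != length(seqs)) {
    stop("`alignments` and `seqs` must have the same length", call. = FALSE)
  }
  B <- length(alignments)
  L <- nrow(alignments[[1]])
  A <- alphabet$size
  profiles <- array(0, c(B, L, A))
  gap_mass <- matrix(0, B, L)
  for (k in seq_len(B)) {
    P <- alignments[[k]]
    X <- if (is.matrix(seqs[[k]])) seqs[[k]] else seq_onehot(seqs[[k]], alphabet)
    if (ncol(P) != nrow(X)) {
      stop(sprintf("item %d: posterior has %d columns but sequence has %d residues",
                   k, ncol(P), nrow(X)), call. = FALSE)
    }
    if (nrow(P) != L) {
      stop("all posteriors must have the same query length", call. = FALSE)
    }
    pk <- P %*% X
    profiles[k, , ] <- pk
    gap_mass[k, ] <- 1 - rowSums(pk)
  }
  structure(list(profiles = profiles, gap_mass = gap_mass,
                 alphabet = alphabet),
            class = "soft_msa")
}

#' @export
print.soft_msa <- function(x, ...) {
  d <- dim(x$profiles)
  cat(sprintf("<soft_msa> %d sequences x %d query columns (%s alphabet), mean gap mass %.3f\n",
              d[1], d[2], x$alphabet$type, mean(x$gap_mass)))
  invisible(x)
}

#' Harden the learned alignment into a discrete A3M MSA
#'
#' Runs the classic (hard) aligner on each learned similarity matrix and
#' emits the resulting alignment in A3M dialect: query columns uppercase,
#' deletions `-`, and residues not matched to any query column lowercase
#' (insertions relative to the query).  The first row is the query itself.
#'
#' @inheritParams build_alignment_tensor
#' @param ids Optional sequence identifiers (query first).
#' @return A named character vector of A3M rows (query first), class
#'   `a3m`.
#' @export
harden_msa <- function(seqs, query, enc, params, ids = NULL) {
  params <- as_align_params(params)
  Xq <- onehot_of(query, enc)
  Eq <- encode(Xq, enc)
  qchars <- chars_of(query)
  rows <- character(length(seqs) + 1L)
  rows[1L] <- paste(qchars, collapse = "")
  for (k in seq_along(seqs)) {
    schars <- chars_of(seqs[[k]])
    Ek <- encode(onehot_of(seqs[[k]], enc), enc)
    h <- hard_align(similarity(Eq, Ek), params)
    rows[k + 1L] <- path_to_a3m(h$path, length(qchars), schars)
  }
  if (is.null(ids)) ids <- c("query", paste0("seq", seq_along(seqs)))
  names(rows) <- ids
  structure(rows, class = "a3m")
}

chars_of <- function(seq) {
  if (is.matrix(seq)) {
    if (is.null(rownames(seq))) {
      stop("one-hot matrices need residue rownames to be rendered as text",
           call. = FALSE)
    }
    rownames(seq)
  } else {
    seq_chars(seq)
  }
}

# render one 0-based match path as an A3M row: uppercase at matched query
# columns, '-' at unmatched query columns, lowercase runs for unmatched
# sequence residues placed after the preceding query column
path_to_a3m <- function(path, query_len, schars) {
  out <- character(0)
  sp <- 0L # residues consumed (0-based next index)
  if (nrow(path) > 0) {
    prev_q <- -1L
    for (t in seq_len(nrow(path))) {
      qi <- path[t, 1]
      sj <- path[t, 2]
      if (sj > sp) {
        out <- c(out, tolower(schars[(sp + 1L):sj]))
      }
      if (qi > prev_q + 1L) {
        out <- c(out, rep("-", qi - prev_q - 1L))
      }
      out <- c(out, toupper(schars[sj + 1L]))
      sp <- sj + 1L
      prev_q <- qi
    }
    if (prev_q < query_len - 1L) {
      out <- c(out, rep("-", query_len - 1L - prev_q))
    }
  } else {
    out <- rep("-", query_len)
  }
  if (sp < length(schars)) {
    out <- c(out, tolower(schars[(sp + 1L):length(schars)]))
  }
  paste(out, collapse = "")
}
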