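# Contact-prediction and MSA-quality metrics.

#' Contact-prediction area under the precision curve
#'
#' Ranks all eligible residue pairs (|i - j| >= `min_sep`) by score,
#' descending, with deterministic lexicographic tie-breaks, computes the
#' precision of the top-t predictions for every t from 1 to L, and returns
#' the mean of those L precision values.  Pairs closer than `min_sep` along
#' the chain are excluded from both ranking and truth.
#'
#' @param scores `L x L` symmetric score matrix (as from
#'   [contact_scores()]).
#' @param truth A data frame with 1-based columns `i`, `j` of true contact
#'   pairs, or a `contact_truth` object from [plant_mrf()].
#' @param min_sep Minimum sequence separation (default 6).
#' @return AUC in [0, 1].
#' @export
contact_auc <- function(scores, truth, min_sep = 6L) {
  r <- rank_contacts(scores, truth, min_sep)
  L <- nrow(scores)
  K <- length(r$is_true)
  cum <- cumsum(r$is_true)
  # top-t precision; if fewer than t eligible pairs exist, all of them are
  # taken and the denominator stays t
  prec <- vapply(seq_len(L), function(t) cum[min(t, K)] / t, numeric(1))
  mean(prec)
}

rank_contacts <- function(scores, truth, min_sep) {
  if (!is.matrix(scores) || nrow(scores) != ncol(scores)) {
    stop("`scores` must be a square matrix", call. = FALSE)
  }
  L <- nrow(scores)
  tp <- truth_pairs(truth, L, min_sep)
  if (nrow(tp) == 0L) {
    stop("no true contacts at separation >= min_sep", call. = FALSE)
  }
  idx <- which(upper.tri(scores), arr.ind = TRUE)
  keep <- (idx[, 2] - idx[, 1]) >= min_sep
  idx <- idx[keep, , drop = FALSE]
  s <- scores[idx]
  ord <- order(-s, idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  key <- idx[, 1] * (L + 1L) + idx[, 2]
  truth_key <- tp$i * (L + 1L) + tp$j
  list(pairs = idx, score = s[ord], is_true = key %in% truth_key,
       n_truth = nrow(tp))
}

truth_pairs <- function(truth, L, min_sep) {
  if (inherits(truth, "contact_truth")) {
    df <- truth$pairs
    if (!is.null(truth$L) && truth$L != L) {
      stop("truth length does not match the score matrix", call. = FALSE)
    }
  } else {
    df <- as.data.frame(truth)
  }
  if (nrow(df) == 0L) stop("empty contact truth", call. = FALSE)
  i <- pmin(df$i, df$j)
  j <- pmax(df$i, df$j)
  if (any(i < 1L) || any(j > L)) {
    stop("truth indices outside 1..L", call. = FALSE)
  }
  df <- unique(data.frame(i = i, j = j))
  df[(df$j - df$i) >= min_sep, , drop = FALSE]
}

#' Positive-predictive-value curve
#'
#' Precision of the top-N ranked contact predictions for N = 1 .. `n_max`
#' (default 2L), under the same ranking and eligibility rules as
#' [contact_auc()].
#'
#' @inheritParams contact_auc
#' @param n_max Largest N (default `2 * L`).
#' @return A data frame with columns `n` and `ppv`.
#' @export
ppv_curve <- function(scores, truth, min_sep = 6L, n_max = NULL) {
  r <- rank_contacts(scores, truth, min_sep)
  L <- nrow(scores)
  if (is.null(n_max)) n_max <- 2L * L
  n_max <- min(n_max, length(r$is_true))
  hits <- cumsum(r$is_true[seq_len(n_max)])
  data.frame(n = seq_len(n_max), ppv = hits / seq_len(n_max))
}

#' Pairwise-alignment consistency of an MSA
#'
#' Scores the pairwise alignment induced between every unordered pair of
#' MSA rows: columns where both rows hold residues are scored with the
#' substitution matrix; runs of columns where exactly one row holds a
#' residue are charged an affine gap penalty (`gap_open` for the first
#' position of a run, `gap_extend` thereafter); columns where both rows
#' are gaps are ignored.  High pairwise scores across the MSA mean the rows
#' are aligned consistently with each other, not just with the query.
#'
#' @param msa A character matrix of aligned rows (equal length), or an
#'   `a3m` object (insertion states are dropped).
#' @param submat Substitution matrix (default: packaged BLOSUM62 via
#'   [read_submatrix()]).
#' @param gap_open,gap_extend Affine gap penalties (defaults -11 / -1).
#' @return A list of class `consistency_report`: `scores` (one per pair),
#'   `summary` (median and quartiles) and `aligned_fraction`.
#' @export
msa_consistency <- function(msa, submat = NULL, gap_open = -11,
                            gap_extend = -1) {
  if (inherits(msa, "a3m") || (is.character(msa) && !is.matrix(msa))) {
    af <- aligned_fraction(msa)
    mat <- a3m_to_matrix(msa)
  } else {
    mat <- msa
    af <- mean(mat[-1, , drop = FALSE] != "-")
  }
  if (!is.matrix(mat) || nrow(mat) < 2L) {
    stop("consistency scoring needs an MSA with at least 2 rows",
         call. = FALSE)
  }
  if (is.null(submat)) submat <- read_submatrix()
  B <- nrow(mat)
  scores <- numeric(0)
  pair_i <- integer(0)
  pair_j <- integer(0)
  for (r in seq_len(B - 1L)) {
    for (s in seq((r + 1L), B)) {
      scores <- c(scores, pair_alignment_score(mat[r, ], mat[s, ], submat,
                                               gap_open, gap_extend))
      pair_i <- c(pair_i, r)
      pair_j <- c(pair_j, s)
    }
  }
  structure(list(
    pairs = data.frame(row1 = pair_i, row2 = pair_j, score = scores),
    scores = scores,
    summary = c(q1 = unname(quantile(scores, 0.25)),
                median = median(scores),
                q3 = unname(quantile(scores, 0.75))),
    aligned_fraction = af
  ), class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("<consistency_report> %d pairs; median %.1f (IQR %.1f..%.1f); aligned fraction %.3f\n",
              length(x$scores), x$summary["median"], x$summary["q1"],
              x$summary["q3"], x$aligned_fraction))
  invisible(x)
}

pair_alignment_score <- function(row1, row2, submat, gap_open, gap_extend) {
  keep <- !(row1 == "-" & row2 == "-")
  r1 <- toupper(row1[keep])
  r2 <- toupper(row2[keep])
  if (length(r1) == 0L) return(0)
  both <- r1 != "-" & r2 != "-"
  sc <- 0
  if (any(both)) {
    a1 <- r1[both]
    a2 <- r2[both]
    if (any(!(a1 %in% rownames(submat))) || any(!(a2 %in% colnames(submat)))) {
      bad <- setdiff(unique(c(a1, a2)), rownames(submat))
      stop("residues missing from the substitution matrix: ",
           paste(bad, collapse = " "), call. = FALSE)
    }
    sc <- sum(submat[cbind(a1, a2)])
  }
  gap_state <- !both
  if (any(gap_state)) {
    runs <- rle(gap_state)
    n_open <- sum(runs$values)
    n_ext <- sum(runs$lengths[runs$values]) - n_open
    sc <- sc + n_open * gap_open + n_ext * gap_extend
  }
  sc
}

#' Fraction of residues aligned to the query
#'
#' For an A3M alignment: the fraction of non-query residues that occupy a
#' query column (uppercase) rather than being insertions (lowercase);
#' deletions are not residues and do not count.  For a plain aligned
#' matrix every residue occupies a column, so the value is 1.
#'
#' @param msa An `a3m` object (or character vector of A3M rows); the first
#'   row is the query and is excluded.
#' @return A fraction in [0, 1].
#' @export
aligned_fraction <- function(msa) {
  rows <- if (is.matrix(msa)) apply(msa, 1, paste, collapse = "") else unclass(msa)
  if (length(rows) < 2L) stop("need at least one non-query row", call. = FALSE)
  rows <- rows[-1]
  n_up <- sum(vapply(rows, function(r) {
    ch <- strsplit(r, "")[[1]]
    sum(ch %in% LETTERS)
  }, numeric(1)))
  n_low <- sum(vapply(rows, function(r) {
    ch <- strsplit(r, "")[[1]]
    sum(ch %in% letters)
  }, numeric(1)))
  if (n_up + n_low == 0L) stop("MSA contains no residues", call. = FALSE)
  n_up / (n_up + n_low)
}

#' Plot a PPV curve
#'
#' @param curve Data frame from [ppv_curve()].
#' @param ... Passed to [plot()].
#' @export
plot_ppv <- function(curve, ...) {
  plot(curve$n, curve$ppv, type = "l", lwd = 2, ylim = c(0, 1),
       xlab = "top N predictions", ylab = "positive predictive value", ...)
  invisible(curve)
}

#' Plot predicted contacts against the truth
#'
#' Upper triangle: the top-`n_top` predictions (filled = true positive,
#' cross = false positive); both triangles show the true contacts in grey.
#'
#' @param scores Contact-score matrix.
#' @param truth True-contact data frame or `contact_truth`.
#' @param n_top Number of top predictions to draw (default `L`).
#' @param min_sep Minimum sequence separation.
#' @export
plot_contact_map <- function(scores, truth, n_top = nrow(scores),
                             min_sep = 6L) {
  L <- nrow(scores)
  r <- rank_contacts(scores, truth, min_sep)
  plot(NA, xlim = c(1, L), ylim = c(1, L), xlab = "residue", ylab = "residue",
       asp = 1)
  tp <- truth_pairs(truth, L, min_sep)
  graphics::points(tp$i, tp$j, pch = 16, col = "grey70", cex = 0.8)
  graphics::points(tp$j, tp$i, pch = 16, col = "grey70", cex = 0.8)
  top <- utils::head(seq_along(r$is_true), n_top)
  hit <- r$is_true[top]
  graphics::points(r$pairs[top[hit], 2], r$pairs[top[hit], 1], pch = 19,
                   col = "firebrick")
  if (any(!hit)) {
    graphics::points(r$pairs[top[!hit], 2], r$pairs[top[!hit], 1], pch = 4,
                     col = "steelblue")
  }
  invisible(scores)
}
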