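#' Alignment parameters for the smooth and hard aligners
#'
#' Bundles the knobs of the pairwise alignment dynamic program.  `gap_mode
#' = "linear"` charges `gap` for every unaligned residue; `"affine"` charges
#' `open` for the first position of each maximal gap streak and `extend` for
#' every subsequent one.  Penalties are signed scores added to a path's
#' total, so sensible penalties are negative.  `align_mode = "local"` is
#' Smith-Waterman style: a path may start and end at any match and the empty
#' alignment is a valid path of score 0.  `"global"` is Needleman-Wunsch
#' style: the path's gap structure covers both sequences entirely and
#' terminal gaps are charged like internal ones.
#'
#' `restrict_turns` forbids a deletion (query residue unmatched) from being
#' followed immediately by an insertion, so that of the two orderings of an
#' adjacent insertion/deletion pair only one is counted.  This removes the
#' double counting of equivalent gap orderings that otherwise biases the
#' smooth path distribution toward near-diagonal alignments.
#'
#' @param temperature Positive smoothing temperature. As it approaches 0 the
#'   smooth score approaches the optimal (hard) alignment score; larger
#'   values spread probability mass over more paths.
#' @param gap Per-residue gap penalty (linear mode only).
#' @param open,extend Gap-open and gap-extend penalties (affine mode only).
#' @param gap_mode `"linear"` or `"affine"`.
#' @param align_mode `"local"` or `"global"`.
#' @param restrict_turns Logical; forbid deletion-then-insertion turns.
#'
#' @return An object of class `align_params`.
#' @examples
#' align_params(temperature = 1, gap = -1)
#' align_params(gap_mode = "affine", open = -5, extend = -1,
#'              align_mode = "global", restrict_turns = TRUE)
#' @export
align_params <- function(temperature = 1.0, gap = -1.0, open = NULL,
                         extend = NULL, gap_mode = c("linear", "affine"),
                         align_mode = c("local", "global"),
                         restrict_turns = FALSE) {
  gap_mode <- match.arg(gap_mode)
  align_mode <- match.arg(align_mode)
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be a single positive number", call. = FALSE)
  }
  if (gap_mode == "linear") {
    if (is.null(gap) || !is.finite(gap)) {
      stop("linear gap mode requires a finite `gap` penalty", call. = FALSE)
    }
    open <- gap
    extend <- gap
  } else {
    if (is.null(open) || is.null(extend) ||
        !is.finite(open) || !is.finite(extend)) {
      stop("affine gap mode requires finite `open` and `extend` penalties",
           call. = FALSE)
    }
    gap <- NA_real_
  }
  structure(
    list(temperature = as.numeric(temperature), gap = as.numeric(gap),
         open = as.numeric(open), extend = as.numeric(extend),
         gap_mode = gap_mode, align_mode = align_mode,
         restrict_turns = isTRUE(restrict_turns)),
    class = "align_params"
  )
}

#' @export
print.align_params <- function(x, ...) {
  gaps <- if (x$gap_mode == "linear") {
    sprintf("gap = %g", x$gap)
  } else {
    sprintf("open = %g, extend = %g", x$open, x$extend)
  }
  cat(sprintf("<align_params> %s %s, T = %g, %s%s\n", x$align_mode,
              x$gap_mode, x$temperature, gaps,
              if (x$restrict_turns) ", restricted turns" else ""))
  invisible(x)
}

as_align_params <- function(params) {
  if (!inherits(params, "align_params")) {
    stop("`params` must be created with align_params()", call. = FALSE)
  }
  params
}

check_score_matrix <- function(a) {
  if (!is.matrix(a) || !is.numeric(a)) {
    stop("score matrix must be a numeric matrix", call. = FALSE)
  }
  if (nrow(a) < 1L || ncol(a) < 1L) {
    stop("score matrix must have at least one row and column", call. = FALSE)
  }
  if (!all(is.finite(a))) {
    stop("score matrix entries must all be finite", call. = FALSE)
  }
  invisible(a)
}
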