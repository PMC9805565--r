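# Brute-force path enumeration: the independent oracle for the smooth DP.
# Paths are enumerated as explicit move sequences over the alignment lattice
# ("m" = match, "d" = deletion / query residue unmatched, "i" = insertion /
# other-sequence residue unmatched), because with affine gaps the score of a
# gap segment depends on how its deletions and insertions are interleaved.

#' Enumerate every alignment path of two short sequences
#'
#' Returns all alignment paths permitted by `params` between sequences of
#' lengths `len_x` and `len_y`, each exactly once.  A path is a monotone
#' sequence of moves through the alignment lattice; in local mode paths
#' start and end with a match (the empty path is included), in global mode
#' they consume both sequences completely.  With `restrict_turns` a deletion
#' move is never followed directly by an insertion move.
#'
#' Intended as a testing oracle; lengths are capped at 7 to avoid
#' combinatorial explosion.
#'
#' @param len_x,len_y Sequence lengths (each at most 7).
#' @inheritParams smooth_score
#' @return A list of paths; each path is a list with `matches` (two-column
#'   0-based integer matrix), `moves` (character vector of `"m"`, `"d"`,
#'   `"i"`), and `n_open`/`n_extend` gap-streak counts.
#' @export
enumerate_paths <- function(len_x, len_y, params) {
  params <- as_align_params(params)
  n <- as.integer(len_x)
  m <- as.integer(len_y)
  if (n < 1L || m < 1L) stop("lengths must be at least 1", call. = FALSE)
  if (n > 7L || m > 7L) {
    stop("enumeration is capped at length 7 per sequence", call. = FALSE)
  }
  restrict <- params$restrict_turns
  local <- params$align_mode == "local"
  out <- list()

  if (local) {
    out[[1L]] <- build_path(character(0), 0L, 0L) # empty local path
    # depth-first over move sequences beginning with a match at 0-based cell
    # (si, sj); every prefix ending in a match is itself a valid local path
    rec <- function(i, j, last, moves, si, sj) {
      if (last == "m") {
        out[[length(out) + 1L]] <<- build_path(moves, si, sj)
      }
      if (i < n && j < m) rec(i + 1L, j + 1L, "m", c(moves, "m"), si, sj)
      if (i < n) rec(i + 1L, j, "d", c(moves, "d"), si, sj)
      if (j < m && !(restrict && last == "d")) {
        rec(i, j + 1L, "i", c(moves, "i"), si, sj)
      }
    }
    for (si in seq_len(n)) {
      for (sj in seq_len(m)) {
        rec(si, sj, "m", "m", si - 1L, sj - 1L)
      }
    }
  } else {
    rec <- function(i, j, last, moves) {
      if (i == n && j == m) {
        out[[length(out) + 1L]] <<- build_path(moves, 0L, 0L)
        return(invisible(NULL))
      }
      if (i < n && j < m) rec(i + 1L, j + 1L, "m", c(moves, "m"))
      if (i < n) rec(i + 1L, j, "d", c(moves, "d"))
      if (j < m && !(restrict && last == "d")) {
        rec(i, j + 1L, "i", c(moves, "i"))
      }
    }
    rec(0L, 0L, "", character(0))
  }
  out
}

# Convert a move sequence (with 0-based starting cell: the cell *before*
# the first move, i.e. the first match consumes residues i0, j0) into a
# path object with matches and affine gap-streak counts.
build_path <- function(moves, i0, j0) {
  i <- i0
  j <- j0
  mi <- integer(0)
  mj <- integer(0)
  n_open <- 0L
  n_extend <- 0L
  last <- ""
  for (mv in moves) {
    if (mv == "m") {
      mi <- c(mi, i)
      mj <- c(mj, j)
      i <- i + 1L
      j <- j + 1L
    } else if (mv == "d") {
      if (last == "d") n_extend <- n_extend + 1L else n_open <- n_open + 1L
      i <- i + 1L
    } else {
      if (mv != "i") stop("unknown move: ", mv, call. = FALSE)
      if (last == "i") n_extend <- n_extend + 1L else n_open <- n_open + 1L
      j <- j + 1L
    }
    last <- mv
  }
  list(matches = cbind(i = mi, j = mj), moves = moves,
       n_open = n_open, n_extend = n_extend)
}

#' Score a single alignment path
#'
#' Sums the match scores along a path and adds its gap penalties.  Linear
#' mode charges `gap` once per unaligned residue (in global mode all
#' unaligned residues; in local mode only those between the first and last
#' match).  Affine mode charges `open` for the first position of each
#' maximal gap streak and `extend` for the rest.  If `path` carries an
#' explicit move sequence (as produced by [enumerate_paths()]) the streak
#' structure is read from it; for a bare match matrix each gap segment is
#' taken as one contiguous streak per sequence.
#'
#' @param a Numeric score matrix.
#' @param path Either a path object from [enumerate_paths()] or a
#'   two-column 0-based integer matrix of matches.
#' @inheritParams smooth_score
#' @return A single numeric path score.
#' @export
path_score <- function(a, path, params) {
  params <- as_align_params(params)
  check_score_matrix(a)
  n <- nrow(a)
  m <- ncol(a)
  has_moves <- is.list(path) && !is.null(path$moves)
  matches <- if (is.list(path)) path$matches else path
  if (is.null(matches)) matches <- cbind(i = integer(0), j = integer(0))
  matches <- matrix(as.integer(matches), ncol = 2)
  k <- nrow(matches)
  if (k > 0) {
    if (any(matches[, 1] < 0L) || any(matches[, 2] < 0L) ||
        any(matches[, 1] >= n) || any(matches[, 2] >= m)) {
      stop("invalid path: match indices outside the score matrix",
           call. = FALSE)
    }
    if (k > 1 && (any(diff(matches[, 1]) <= 0L) ||
                  any(diff(matches[, 2]) <= 0L))) {
      stop("invalid path: match indices must be strictly increasing in both coordinates",
           call. = FALSE)
    }
  }
  local <- params$align_mode == "local"
  if (k == 0 && !local) {
    if (!has_moves) {
      stop("a global path with no matches needs an explicit move sequence",
           call. = FALSE)
    }
  }
  match_sum <- if (k > 0) sum(a[matches + 1L]) else 0
  if (has_moves) {
    gap_pen <- path$n_open * params$open + path$n_extend * params$extend
    return(match_sum + gap_pen)
  }
  # derive gap segments from matches alone (one streak per sequence/segment)
  if (local) {
    if (k < 2) return(match_sum)
    dx <- diff(matches[, 1]) - 1L
    dy <- diff(matches[, 2]) - 1L
  } else {
    xi <- c(-1L, matches[, 1], n)
    yj <- c(-1L, matches[, 2], m)
    dx <- diff(xi) - 1L
    dy <- diff(yj) - 1L
  }
  gaps <- c(dx, dy)
  gaps <- gaps[gaps > 0L]
  match_sum + length(gaps) * params$open + sum(gaps - 1L) * params$extend
}

#' Brute-force smooth score by explicit path enumeration
#'
#' Identical contract to [smooth_score()], computed as
#' `T * log(sum exp(path_score / T))` over the complete path list from
#' [enumerate_paths()].  This is the independent oracle used to validate
#' the dynamic program; it is only feasible for sequences of length at
#' most 7.
#'
#' @inheritParams smooth_score
#' @return A single numeric score.
#' @export
brute_force_smooth_score <- function(a, params) {
  params <- as_align_params(params)
  check_score_matrix(a)
  paths <- enumerate_paths(nrow(a), ncol(a), params)
  scores <- vapply(paths, function(p) path_score(a, p, params), numeric(1))
  params$temperature * logsumexp(scores / params$temperature)
}

#' Brute-force posterior alignment by explicit path enumeration
#'
#' Identical contract to [smooth_posterior()]: the expectation of the
#' match-indicator matrix under path probabilities proportional to
#' `exp(path_score / T)`, computed over the complete enumerated path list.
#'
#' @inheritParams smooth_score
#' @return A numeric matrix of match probabilities.
#' @export
brute_force_posterior <- function(a, params) {
  params <- as_align_params(params)
  check_score_matrix(a)
  paths <- enumerate_paths(nrow(a), ncol(a), params)
  scores <- vapply(paths, function(p) path_score(a, p, params), numeric(1))
  w <- scores / params$temperature
  w <- exp(w - logsumexp(w))
  P <- matrix(0, nrow(a), ncol(a))
  for (t in seq_along(paths)) {
    mt <- paths[[t]]$matches
    if (nrow(mt) > 0) P[mt + 1L] <- P[mt + 1L] + w[t]
  }
  P
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}
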