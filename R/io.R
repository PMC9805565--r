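# Readers and writers for the plain-text formats the pipeline touches:
# FASTA (via Biostrings), the A3M alignment dialect, NCBI-layout
# substitution matrices, and whitespace contact tables.

#' Read unaligned sequences from a FASTA file
#'
#' Sequences are upper-cased and returned in file order; by convention the
#' first record is the query/reference sequence.
#'
#' @param path Path to a FASTA file.
#' @param alphabet If non-NULL, validate residues against this alphabet
#'   (unknown symbols are allowed and later encoded as all-zero one-hots).
#' @return A named character vector of sequences.
#' @export
read_fasta <- function(path, alphabet = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  seqs <- toupper(as.character(set))
  ids <- names(set)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  bad <- grepl("[^A-Z]", seqs)
  if (any(bad)) {
    k <- which(bad)[1]
    ch <- regmatches(seqs[k], regexpr("[^A-Z]", seqs[k]))
    stop(sprintf("record '%s' contains illegal character '%s'", ids[k], ch),
         call. = FALSE)
  }
  if (!is.null(alphabet)) {
    alphabet <- as_alphabet(alphabet)
    ok <- paste(c(alphabet$letters, alphabet$unknown), collapse = "")
    bad <- grepl(sprintf("[^%s]", ok), seqs)
    if (any(bad)) {
      k <- which(bad)[1]
      stop(sprintf("record '%s' contains symbols outside the %s alphabet",
                   ids[k], alphabet$type), call. = FALSE)
    }
  }
  setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrapping width.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(seqs)) {
    writeLines(paste0(">", ids[k]), con)
    s <- seqs[[k]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read / write A3M alignments
#'
#' The A3M dialect used throughout the package: every row has exactly one
#' uppercase letter or `-` per query column; lowercase letters are
#' insertions relative to the query and do not occupy columns.  The first
#' row is the query.
#'
#' @param path Path to an A3M file.
#' @return For `read_a3m`, a named character vector of rows with class
#'   `a3m`.
#' @export
read_a3m <- function(path) {
  rows <- read_fasta_raw(path)
  validate_a3m(rows)
}

read_fasta_raw <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty alignment file: ", path, call. = FALSE)
  setNames(as.character(set), names(set))
}

validate_a3m <- function(rows) {
  qlen <- a3m_row_width(rows[[1]])
  widths <- vapply(rows, a3m_row_width, integer(1))
  if (any(widths != qlen)) {
    k <- which(widths != qlen)[1]
    stop(sprintf("A3M row '%s' covers %d query columns but the query has %d",
                 names(rows)[k], widths[k], qlen), call. = FALSE)
  }
  structure(rows, class = "a3m")
}

a3m_row_width <- function(row) {
  sum(strsplit(row, "")[[1]] %in% c(LETTERS, "-"))
}

#' @rdname read_a3m
#' @param msa An `a3m` object (named character vector of rows).
#' @export
write_a3m <- function(msa, path) {
  write_fasta(unclass(msa), path, width = 1e9) # one line per row
}

#' Per-row alignment paths implied by an A3M alignment
#'
#' Reconstructs, for every row, the 0-based `(query_column, residue_index)`
#' match path that the A3M encodes (uppercase = match, `-` = deletion,
#' lowercase = insertion, skipped).
#'
#' @param msa An `a3m` object.
#' @return A list of two-column integer matrices, one per row.
#' @export
a3m_paths <- function(msa) {
  lapply(unclass(msa), function(row) {
    chars <- strsplit(row, "")[[1]]
    qi <- -1L
    sj <- -1L
    mi <- integer(0)
    mj <- integer(0)
    for (ch in chars) {
      if (ch == "-") {
        qi <- qi + 1L
      } else if (ch %in% LETTERS) {
        qi <- qi + 1L
        sj <- sj + 1L
        mi <- c(mi, qi)
        mj <- c(mj, sj)
      } else {
        sj <- sj + 1L
      }
    }
    cbind(i = mi, j = mj)
  })
}

#' Convert an A3M alignment to a query-column character matrix
#'
#' Drops insertion (lowercase) states and returns the match-state alignment
#' as a `rows x query_length` character matrix with `-` for deletions.
#'
#' @param msa An `a3m` object or character vector of A3M rows.
#' @return A character matrix.
#' @export
a3m_to_matrix <- function(msa) {
  msa <- validate_a3m(msa)
  rows <- lapply(unclass(msa), function(row) {
    chars <- strsplit(row, "")[[1]]
    chars[chars %in% c(LETTERS, "-")]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(msa)
  out
}

#' Read a substitution matrix in NCBI text layout
#'
#' Parses the standard whitespace-separated substitution-matrix format
#' (comment lines starting with `#`, a header row of residue letters, one
#' labelled row per residue), e.g. the BLOSUM62 file shipped under
#' `extdata`.
#'
#' @param path Path to the matrix file; defaults to the packaged BLOSUM62.
#' @return A numeric matrix with residue row/column names.
#' @export
read_submatrix <- function(path = system.file("extdata", "BLOSUM62.txt",
                                              package = "smurf")) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  mat <- matrix(NA_real_, length(rows), length(header),
                dimnames = list(vapply(rows, `[`, "", 1), header))
  for (r in seq_along(rows)) {
    vals <- as.numeric(rows[[r]][-1])
    if (length(vals) != length(header)) {
      stop("malformed substitution-matrix row: ", rows[[r]][1], call. = FALSE)
    }
    mat[r, ] <- vals
  }
  mat
}

#' Read / write contact tables
#'
#' Contact score tables are whitespace-separated `i j score` with 1-based
#' residue indices sorted by descending score; truth tables are `i j`
#' pairs.  Header lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return `read_contacts` returns a data frame with columns `i`, `j` and,
#'   if present, `score`.
#' @export
read_contacts <- function(path) {
  df <- read.table(path, header = FALSE, comment.char = "#")
  if (ncol(df) < 2) stop("contact table needs at least two columns", call. = FALSE)
  names(df) <- c("i", "j", "score")[seq_len(min(3, ncol(df)))]
  df[seq_len(min(3, ncol(df)))]
}

#' @rdname read_contacts
#' @param scores A symmetric contact-score matrix (as from
#'   [contact_scores()]) or a data frame with columns `i`, `j`, `score`.
#' @export
write_contact_scores <- function(scores, path) {
  if (is.matrix(scores)) {
    L <- nrow(scores)
    idx <- which(upper.tri(scores), arr.ind = TRUE)
    df <- data.frame(i = idx[, 1], j = idx[, 2],
                     score = scores[idx])
  } else {
    df <- scores
  }
  df <- df[order(-df$score, df$i, df$j), ]
  write.table(df, path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname read_contacts
#' @param pairs Data frame with 1-based columns `i`, `j`.
#' @export
write_contacts <- function(pairs, path) {
  write.table(pairs[c("i", "j")], path, quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
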