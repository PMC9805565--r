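#' Residue alphabets
#'
#' The package works over a fixed residue alphabet: 20 amino acids plus the
#' unknown symbol `X` for protein, or `ACGU` plus `N` for RNA.  Unknown
#' symbols are encoded as the all-zero one-hot row, so they contribute
#' nothing to encoder outputs or profile mass.
#'
#' @param type `"protein"` or `"rna"`.
#' @return An object of class `smurf_alphabet` with fields `letters`
#'   (ordinary residues), `unknown` (the wildcard symbol) and `size`.
#' @examples
#' smurf_alphabet("rna")
#' @export
smurf_alphabet <- function(type = c("protein", "rna")) {
  type <- match.arg(type)
  if (type == "protein") {
    letters <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    unknown <- "X"
  } else {
    letters <- c("A", "C", "G", "U")
    unknown <- "N"
  }
  structure(list(type = type, letters = letters, unknown = unknown,
                 size = length(letters)),
            class = "smurf_alphabet")
}

#' @export
print.smurf_alphabet <- function(x, ...) {
  cat(sprintf("<smurf_alphabet> %s: %s (+%s unknown)\n", x$type,
              paste(x$letters, collapse = ""), x$unknown))
  invisible(x)
}

as_alphabet <- function(alphabet) {
  if (is.character(alphabet) && length(alphabet) == 1L) {
    return(smurf_alphabet(alphabet))
  }
  if (!inherits(alphabet, "smurf_alphabet")) {
    stop("`alphabet` must be \"protein\", \"rna\", or a smurf_alphabet",
         call. = FALSE)
  }
  alphabet
}

#' One-hot encode a sequence
#'
#' @param seq A single sequence string or character vector of residues.
#' @param alphabet A [smurf_alphabet()] (or `"protein"` / `"rna"`).
#' @return A numeric matrix of shape `length x alphabet_size`; rows for the
#'   unknown symbol are all zero.
#' @export
seq_onehot <- function(seq, alphabet = "protein") {
  alphabet <- as_alphabet(alphabet)
  chars <- seq_chars(seq)
  bad <- which(!(chars %in% c(alphabet$letters, alphabet$unknown)))
  if (length(bad) > 0) {
    stop(sprintf("symbols outside the %s alphabet at position(s) %s: %s",
                 alphabet$type, paste(head(bad, 5), collapse = ", "),
                 paste(unique(chars[head(bad, 5)]), collapse = " ")),
         call. = FALSE)
  }
  X <- matrix(0, length(chars), alphabet$size)
  idx <- match(chars, alphabet$letters)
  hit <- which(!is.na(idx))
  X[cbind(hit, idx[hit])] <- 1
  rownames(X) <- chars
  X
}

seq_chars <- function(seq) {
  if (length(seq) == 1L && nchar(seq) > 1L) {
    strsplit(toupper(seq), "")[[1]]
  } else {
    toupper(as.character(seq))
  }
}
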