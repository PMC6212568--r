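#' The 22-symbol amino-acid alphabet
#'
#' Sequences are modelled over the 20 standard amino acids plus a wildcard
#' symbol \code{"X"} for any non-standard residue (selenocysteine and
#' friends are mapped here) and a padding symbol \code{"-"} used to fill
#' positions beyond the end of a sequence up to the model's maximum length.
#'
#' The ordering is fixed and canonical: the 20 standard one-letter codes in
#' alphabetical order, then the wildcard, then padding. Encoded tensors,
#' saved models and the decoder's argmax all assume this order, so it must
#' never be permuted.
#'
#' @return Character vector of length 22 with names \code{"wildcard"} and
#'   \code{"padding"} on the two special symbols.
#' @examples
#' aa_alphabet()
#' @export
aa_alphabet <- function() {
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  out <- c(aas, "X", "-")
  names(out) <- c(rep("", 20L), "wildcard", "padding")
  out
}

#' @keywords internal
.check_alphabet <- function(alphabet) {
  if (length(alphabet) != 22L || anyDuplicated(alphabet))
    stop("alphabet must contain exactly 22 distinct symbols", call. = FALSE)
  invisible(alphabet)
}

#' One-hot encode an amino-acid sequence
#'
#' Converts a sequence into the flat one-hot tensor the networks consume:
#' \code{max_len} blocks of 22 entries, one block per position, flattened
#' position-major to a vector of length \code{max_len * 22} (3080 at the
#' default maximum length of 140). Positions past the end of the sequence
#' one-hot the padding symbol. Characters outside the standard alphabet are
#' mapped to the wildcard.
#'
#' @param seq Character scalar, an amino-acid string of length
#'   \code{<= max_len}. Case-insensitive.
#' @param max_len Maximum sequence length; default 140.
#' @param alphabet The symbol alphabet; see [aa_alphabet()].
#' @return Numeric vector of length \code{max_len * 22}, entries 0/1, with
#'   exactly one 1 per 22-wide block (so the entries sum to \code{max_len}).
#' @seealso [decode_sequence()], [encode_sequences()]
#' @examples
#' x <- encode_sequence("ACDEFG")
#' length(x)  # 3080
#' sum(x)     # 140
#' decode_sequence(x)
#' @export
encode_sequence <- function(seq, max_len = 140L, alphabet = aa_alphabet()) {
  .check_alphabet(alphabet)
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n > max_len)
    stop("sequence has ", n, " residues but max_len is ", max_len, call. = FALSE)
  k <- length(alphabet)
  idx <- match(chars, alphabet)
  idx[is.na(idx)] <- which(names(alphabet) == "wildcard")
  pad <- which(names(alphabet) == "padding")
  idx <- c(idx, rep(pad, max_len - n))
  out <- numeric(max_len * k)
  out[(seq_len(max_len) - 1L) * k + idx] <- 1
  out
}

#' One-hot encode many sequences into a matrix
#'
#' @param seqs Character vector of amino-acid strings.
#' @inheritParams encode_sequence
#' @return Numeric matrix with one row per sequence and
#'   \code{max_len * 22} columns.
#' @export
encode_sequences <- function(seqs, max_len = 140L, alphabet = aa_alphabet()) {
  out <- vapply(seqs, encode_sequence, numeric(max_len * 22L),
                max_len = max_len, alphabet = alphabet, USE.NAMES = FALSE)
  matrix(t(out), nrow = length(seqs), dimnames = list(names(seqs), NULL))
}

#' Decode a one-hot (or soft) sequence tensor back to a string
#'
#' The inverse of [encode_sequence()], total on any real-valued tensor of
#' the right length, so raw decoder-network output can be decoded directly:
#' within each 22-wide block the argmax selects the symbol (ties broken by
#' the lowest symbol index, deterministically). The trailing run of padding
#' symbols is stripped; a padding argmax occurring \emph{before} a
#' non-padding position is mapped to the wildcard so that positional
#' correspondence with the tensor is preserved for motif analysis.
#'
#' @param x Numeric vector of length \code{max_len * 22}.
#' @inheritParams encode_sequence
#' @return Character scalar (possibly \code{""} if every block argmaxes to
#'   padding).
#' @export
decode_sequence <- function(x, max_len = length(x) %/% 22L,
                            alphabet = aa_alphabet()) {
  .check_alphabet(alphabet)
  k <- length(alphabet)
  if (length(x) != max_len * k)
    stop("tensor has length ", length(x), ", expected ", max_len * k,
         call. = FALSE)
  m <- matrix(x, nrow = k)
  idx <- apply(m, 2L, which.max)
  pad <- which(names(alphabet) == "padding")
  wild <- which(names(alphabet) == "wildcard")
  is_pad <- idx == pad
  # last non-padding position; everything after it is the trailing pad run
  last <- if (all(is_pad)) 0L else max(which(!is_pad))
  if (last == 0L) return("")
  idx <- idx[seq_len(last)]
  idx[idx == pad] <- wild   # interior padding -> wildcard
  paste(alphabet[idx], collapse = "")
}

#' Decode each row of a tensor matrix
#'
#' @param x Numeric matrix, one encoded sequence per row.
#' @inheritParams decode_sequence
#' @return Character vector of sequences.
#' @export
decode_sequences <- function(x, max_len = ncol(x) %/% 22L,
                             alphabet = aa_alphabet()) {
  apply(x, 1L, decode_sequence, max_len = max_len, alphabet = alphabet)
}
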