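#' The 20-letter amino-acid alphabet
#'
#' Uppercase one-letter codes of the 20 standard amino acids, in alphabetical
#' order.  Sequences containing any other letter (including ambiguity codes
#' such as B, X or Z) are rejected throughout the package.
#'
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Token vocabulary for the sequence model
#'
#' A fixed bijection between symbols and integer ids.  The default vocabulary
#' has 24 tokens: padding, start, stop, the 20 amino acids, and one reserved
#' control token that never appears in sequences.  Ids are 1-based.
#'
#' @param extra character vector of additional control symbols appended after
#'   the amino acids.  The default single reserved symbol yields the 24-token
#'   vocabulary the model configuration expects.
#' @return an object of class `token_vocabulary` with elements `tokens`
#'   (symbols in id order), `size`, and the special-token ids `pad_id`,
#'   `start_id`, `stop_id`, plus `residue_ids` (ids of the 20 amino acids)
#'   and `sample_ids` (ids a generator may emit: residues plus stop).
#' @export
default_vocab <- function(extra = "<x>") {
  tokens <- c("<pad>", "<s>", "</s>", AA_ALPHABET, extra)
  if (anyDuplicated(tokens)) stop("vocabulary symbols must be unique")
  v <- list(
    tokens = tokens,
    size = length(tokens),
    pad_id = 1L,
    start_id = 2L,
    stop_id = 3L,
    residue_ids = seq_along(AA_ALPHABET) + 3L
  )
  v$sample_ids <- c(v$residue_ids, v$stop_id)
  v$index <- setNames(seq_along(tokens), tokens)
  class(v) <- "token_vocabulary"
  v
}

#' @export
print.token_vocabulary <- function(x, ...) {
  cat("token_vocabulary:", x$size, "tokens:",
      paste(x$tokens, collapse = " "), "\n")
  invisible(x)
}

#' Encode symbols to token ids / decode ids back to symbols
#'
#' @param vocab a `token_vocabulary`
#' @param symbols character vector of single symbols
#' @return integer ids (`vocab_encode`) or symbols (`vocab_decode`)
#' @export
vocab_encode <- function(vocab, symbols) {
  ids <- unname(vocab$index[symbols])
  if (anyNA(ids)) {
    bad <- which(is.na(ids))[1]
    stop(sprintf("unknown symbol '%s' at index %d", symbols[bad], bad))
  }
  ids
}

#' @rdname vocab_encode
#' @param ids integer token ids (1-based)
#' @export
vocab_decode <- function(vocab, ids) {
  if (any(ids < 1L | ids > vocab$size))
    stop("token id out of vocabulary range")
  vocab$tokens[ids]
}

#' Tokenize an amino-acid sequence
#'
#' Maps a sequence to `[start, residues..., stop]` token ids.  The empty
#' sequence maps to `[start, stop]`.
#'
#' @param seq a single amino-acid string over [AA_ALPHABET]
#' @param vocab a `token_vocabulary`
#' @return integer vector of length `nchar(seq) + 2`
#' @export
tokenize <- function(seq, vocab = default_vocab()) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% AA_ALPHABET))
  if (length(bad))
    stop(sprintf("forbidden character '%s' at position %d (alphabet is %s)",
                 chars[bad[1]], bad[1], paste(AA_ALPHABET, collapse = "")))
  c(vocab$start_id, if (length(chars)) unname(vocab$index[chars]), vocab$stop_id)
}

#' Reverse of [tokenize()]
#'
#' @param ids token ids beginning with the start id and ending with the stop id
#' @inheritParams tokenize
#' @return the amino-acid string
#' @export
detokenize <- function(ids, vocab = default_vocab()) {
  if (length(ids) < 2L || ids[1] != vocab$start_id || ids[length(ids)] != vocab$stop_id)
    stop("token ids must start with the start token and end with the stop token")
  inner <- ids[-c(1L, length(ids))]
  if (!all(inner %in% vocab$residue_ids))
    stop("interior token ids must be amino-acid tokens")
  paste(vocab$tokens[inner], collapse = "")
}

#' Validate (and normalise) an amino-acid sequence
#'
#' Uppercases lowercase input with a warning; rejects any character outside
#' the 20-letter alphabet.
#'
#' @param seq character string
#' @param what label used in error messages
#' @return the validated uppercase string
#' @export
validate_aa <- function(seq, what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  if (grepl("[a-z]", seq)) {
    warning(sprintf("%s contains lowercase letters; converting to uppercase", what))
    seq <- toupper(seq)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% AA_ALPHABET))
  if (length(bad))
    stop(sprintf("%s: forbidden character '%s' at position %d",
                 what, chars[bad[1]], bad[1]))
  seq
}

#' Test whether strings are valid amino-acid sequences
#'
#' Vectorised, returns `FALSE` (rather than erroring) for sequences with
#' characters outside the alphabet.  Case sensitive.
#'
#' @param seqs character vector
#' @return logical vector
#' @export
is_valid_aa <- function(seqs) {
  !is.na(seqs) & !grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), seqs)
}
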