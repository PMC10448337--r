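#' Amino-acid token vocabulary
#'
#' The model vocabulary contains four special tokens (`[PAD]`, `[CLS]`,
#' `[SEP]`, `[MASK]`), the twenty standard amino-acid letters, `X` for any
#' nonstandard residue, and the two boundary sentinels `B` (true protein
#' start) and `J` (true protein end).  `B` and `J` are usable as sentinels
#' precisely because they are absent from the standard amino-acid code.
#'
#' Token ids are 0-based and stable across sessions: `[PAD]` is always id 0
#' so that zero-padded id buffers are valid token sequences.
#'
#' @return A list with elements `tokens` (character vector in id order),
#'   `ids` (named integer vector mapping token to 0-based id), `size`,
#'   and `aa_ids` (ids of the 20 standard amino acids).
#' @export
#' @examples
#' v <- mf_vocab()
#' v$ids[["[CLS]"]]
#' mf_decode(mf_encode(c("M", "K", "V")))
mf_vocab <- function() {
  .mf_vocab_cache
}

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
SPECIAL_TOKENS <- c("[PAD]", "[CLS]", "[SEP]", "[MASK]")
BOUNDARY_START <- "B"
BOUNDARY_END <- "J"

.make_vocab <- function() {
  tokens <- c(SPECIAL_TOKENS, AA_LETTERS, "X", BOUNDARY_START, BOUNDARY_END)
  ids <- stats::setNames(seq_along(tokens) - 1L, tokens)
  list(
    tokens = tokens,
    ids = ids,
    size = length(tokens),
    aa_ids = unname(ids[AA_LETTERS]),
    pad_id = unname(ids[["[PAD]"]]),
    cls_id = unname(ids[["[CLS]"]]),
    sep_id = unname(ids[["[SEP]"]]),
    mask_id = unname(ids[["[MASK]"]]),
    b_id = unname(ids[[BOUNDARY_START]]),
    j_id = unname(ids[[BOUNDARY_END]])
  )
}

.mf_vocab_cache <- .make_vocab()

#' Encode tokens to 0-based ids / decode ids back to tokens
#'
#' @param tokens Character vector of tokens (single letters or special
#'   markers such as `"[CLS]"`).
#' @param ids Integer vector of 0-based token ids.
#' @return `mf_encode` returns an integer vector of 0-based ids;
#'   `mf_decode` the corresponding character vector.
#' @export
mf_encode <- function(tokens) {
  v <- mf_vocab()
  out <- v$ids[tokens]
  if (anyNA(out)) {
    bad <- unique(tokens[is.na(out)])
    stop("unknown token(s): ", paste(bad, collapse = ", "))
  }
  unname(out)
}

#' @rdname mf_encode
#' @export
mf_decode <- function(ids) {
  v <- mf_vocab()
  if (any(ids < 0L | ids >= v$size)) stop("token id out of range")
  v$tokens[ids + 1L]
}

#' Sanitize a raw amino-acid sequence
#'
#' Uppercases and maps any character that is not one of the 20 standard
#' amino-acid letters (selenocysteine U, pyrrolysine O, ambiguity codes,
#' `*`, etc.) to `'X'`.  `B` and `J` are reserved boundary sentinels and are
#' therefore also mapped to `'X'` when they appear in input data.
#'
#' @param sequence Character scalar amino-acid sequence.
#' @return Sanitized sequence string over the 20 amino acids plus `X`.
#' @export
mf_sanitize_sequence <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  chars[!(chars %in% AA_LETTERS)] <- "X"
  paste(chars, collapse = "")
}
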