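# SMILES vocabulary and sequence encoding. Sequences are framed as
# GO, x_1, ..., x_N, EOS; PAD fills ragged batches.

GO_TOKEN <- "<GO>"
EOS_TOKEN <- "<EOS>"
PAD_TOKEN <- "<PAD>"

#' Build a SMILES token vocabulary
#'
#' Collects every token occurring in the corpus and prepends the
#' reserved GO/EOS/PAD tokens. Ordering is deterministic: reserved
#' tokens first, then sorted corpus tokens.
#'
#' @param smiles character vector of SMILES (or a `molecule_record`
#'   data frame, whose canonical SMILES are used).
#' @return object of class `clm_vocabulary`.
#' @export
build_vocabulary <- function(smiles) {
  if (is.data.frame(smiles)) smiles <- smiles$canonical_smiles
  smiles <- smiles[!is.na(smiles)]
  stopifnot(length(smiles) > 0L)
  toks <- unique(unlist(lapply(smiles, tokenize_smiles)))
  toks <- sort(toks, method = "radix")
  tokens <- c(GO_TOKEN, EOS_TOKEN, PAD_TOKEN, toks)
  structure(list(tokens = tokens,
                 index = setNames(seq_along(tokens), tokens),
                 go = 1L, eos = 2L, pad = 3L),
            class = "clm_vocabulary")
}

#' @export
print.clm_vocabulary <- function(x, ...) {
  cat("SMILES vocabulary:", length(x$tokens), "tokens",
      "(3 reserved + ", length(x$tokens) - 3L, "chemical)\n")
  invisible(x)
}

#' Encode / decode SMILES token sequences
#'
#' `encode_smiles()` maps a SMILES string to the integer sequence
#' GO, tokens..., EOS; `decode_smiles()` inverts it, dropping framing
#' and padding. Round trip is exact for any string whose tokens are in
#' the vocabulary; unknown tokens raise an error naming the token.
#'
#' @param smiles character scalar.
#' @param vocab a `clm_vocabulary`.
#' @return `encode_smiles()`: integer vector; `decode_smiles()`:
#'   character scalar.
#' @export
encode_smiles <- function(smiles, vocab) {
  toks <- tokenize_smiles(smiles)
  if (is.null(toks)) stop("malformed SMILES: ", smiles)
  idx <- vocab$index[toks]
  if (anyNA(idx)) {
    bad <- toks[is.na(idx)][1]
    stop("token not in vocabulary: '", bad, "'")
  }
  as.integer(c(vocab$go, idx, vocab$eos))
}

#' @rdname encode_smiles
#' @param indices integer vector of token indices.
#' @export
decode_smiles <- function(indices, vocab) {
  keep <- !(indices %in% c(vocab$go, vocab$eos, vocab$pad)) & indices > 0L
  paste(vocab$tokens[indices[keep]], collapse = "")
}

# pack a list of index sequences into a padded matrix + lengths
.pack_sequences <- function(seqs, pad, max_len = NULL) {
  lens <- lengths(seqs)
  Tm <- if (is.null(max_len)) max(lens) else max_len
  X <- matrix(pad, length(seqs), Tm)
  for (i in seq_along(seqs)) {
    L <- min(lens[i], Tm)
    X[i, seq_len(L)] <- seqs[[i]][seq_len(L)]
  }
  list(X = X, lengths = pmin(lens, Tm))
}
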