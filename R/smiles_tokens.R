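#' Tokenize a SMILES string
#'
#' Splits a SMILES string into chemically atomic tokens: bracket atoms
#' (`[nH]`, `[O-]`, ...), two-letter elements (`Cl`, `Br`), two-digit ring
#' closures (`%nn`), and single characters. These are the tokens the
#' chemical language model is trained over.
#'
#' @param smiles character scalar.
#' @return character vector of tokens, or `NULL` if the string contains a
#'   malformed bracket atom.
#' @export
#' @examples
#' tokenize_smiles("CCl")        # "C" "Cl"
#' tokenize_smiles("c1cc[nH]c1") # bracket atom is one token
tokenize_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (is.na(smiles) || !nzchar(smiles)) return(character(0))
  out <- character(0)
  i <- 1L
  n <- nchar(smiles)
  while (i <= n) {
    ch <- substr(smiles, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(smiles, i, n), fixed = TRUE)
      if (j < 0) return(NULL)
      out <- c(out, substr(smiles, i, i + j - 1L))
      i <- i + j
    } else if (ch == "%" && i + 2L <= n &&
               grepl("^[0-9]{2}$", substr(smiles, i + 1L, i + 2L))) {
      out <- c(out, substr(smiles, i, i + 2L))
      i <- i + 3L
    } else if (ch %in% c("C", "B") && i < n &&
               substr(smiles, i, i + 1L) %in% c("Cl", "Br")) {
      out <- c(out, substr(smiles, i, i + 1L))
      i <- i + 2L
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  out
}

.ORGANIC_ATOMS <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I",
                    "b", "c", "n", "o", "p", "s")
.BOND_CHARS <- c("-", "=", "#", ":", "/", "\\", "~")

#' Lexical SMILES validity check
#'
#' A fast syntactic gate applied before any toolkit parse: branch
#' parentheses must balance and never close an empty scope, ring-closure
#' digits must pair up, bracket atoms must be well formed, and every token
#' must be a known atom, bond, branch or ring symbol. The chemistry
#' toolkit is lenient with some malformed strings (for example a dangling
#' branch opening), so generated SMILES are only treated as valid when
#' they pass this check *and* canonicalize successfully.
#'
#' @param smiles character vector.
#' @return logical vector.
#' @export
#' @examples
#' smiles_lexically_valid(c("CCO", "C(", "C1CC"))  # TRUE FALSE FALSE
smiles_lexically_valid <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    toks <- tokenize_smiles(s)
    if (is.null(toks) || length(toks) == 0L) return(FALSE)
    depth <- 0L
    rings <- character(0)
    prev_atom <- FALSE
    for (tk in toks) {
      if (tk == "(") {
        if (!prev_atom) return(FALSE)
        depth <- depth + 1L
      } else if (tk == ")") {
        depth <- depth - 1L
        if (depth < 0L) return(FALSE)
      } else if (grepl("^[0-9]$", tk) || grepl("^%[0-9]{2}$", tk)) {
        if (tk %in% rings) rings <- setdiff(rings, tk) else rings <- c(rings, tk)
      } else if (grepl("^\\[", tk)) {
        if (!grepl("^\\[[0-9]*[A-Za-z@*][^\\]]*\\]$", tk)) return(FALSE)
        prev_atom <- TRUE
        next
      } else if (tk %in% .ORGANIC_ATOMS) {
        prev_atom <- TRUE
        next
      } else if (tk %in% .BOND_CHARS) {
        if (!prev_atom) return(FALSE)
      } else if (tk == ".") {
        prev_atom <- FALSE
      } else {
        return(FALSE)
      }
    }
    depth == 0L && length(rings) == 0L && prev_atom
  }, logical(1), USE.NAMES = FALSE)
}
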