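# SMILES tokenization: atom-level greedy longest match.
#
# Two-character element symbols (Cl, Br) and whole bracket atoms ([...])
# are single tokens; every other character (aromatic atoms, bond symbols,
# branch parens, ring-closure digits) is its own token. Concatenating the
# tokens always reproduces the input string exactly.

# organic-subset symbols recognised outside brackets, longest first
.SMILES_TWO_CHAR <- c("Cl", "Br")
.SMILES_ONE_CHAR <- c(
  "B", "C", "N", "O", "P", "S", "F", "I",
  "b", "c", "n", "o", "p", "s",
  "(", ")", "=", "#", "-", "+", "/", "\\", ".", "@", "%",
  as.character(0:9)
)

#' Tokenize a SMILES string
#'
#' Greedy longest-match tokenizer over the SMILES alphabet. `Cl` and `Br`
#' are emitted as single tokens, bracket atoms such as `[nH]` as one token
#' from `[` to the matching `]`, and all other characters one by one.
#'
#' @param smiles a single non-empty SMILES string.
#' @return an object of class `token_sequence`: a list with `tokens`
#'   (character vector), `ids` (integer vector, indices into the vocabulary
#'   that produced them when tokenized via a model), and `length`.
#' @examples
#' tokenize("CCO")$tokens        # "C" "C" "O"
#' tokenize("CCl")$length        # 2
#' @export
tokenize <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      nchar(smiles) == 0L) {
    stop("smiles must be a single non-empty string")
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  tokens <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) {
        stop(sprintf("unbalanced bracket atom starting at position %d in '%s'",
                     i, smiles))
      }
      tokens <- c(tokens, paste0(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "]") {
      stop(sprintf("unmatched ']' at position %d in '%s'", i, smiles))
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% .SMILES_TWO_CHAR) {
      tokens <- c(tokens, paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else if (ch %in% .SMILES_ONE_CHAR) {
      tokens <- c(tokens, ch)
      i <- i + 1L
    } else {
      stop(sprintf("character '%s' at position %d of '%s' is outside the SMILES vocabulary",
                   ch, i, smiles))
    }
  }
  structure(list(tokens = tokens, ids = seq_along(tokens),
                 length = length(tokens)),
            class = "token_sequence")
}

#' @rdname tokenize
#' @param x a `token_sequence` or character vector of tokens.
#' @return `detokenize`: the reconstructed SMILES string.
#' @export
detokenize <- function(x) {
  tokens <- if (inherits(x, "token_sequence")) x$tokens else x
  paste0(tokens, collapse = "")
}

# Special tokens used by the autoencoder vocabulary. <pad> is id 1 so that
# zero-initialised id buffers never alias a real symbol.
.SPECIAL_TOKENS <- c("<pad>", "<sos>", "<eos>", "<unk>")

#' Build a token vocabulary from a SMILES corpus
#'
#' Collects every distinct token seen in the corpus, sorted for determinism,
#' prefixed by the special tokens `<pad>`, `<sos>`, `<eos>`, `<unk>`.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector: the ordered vocabulary.
#' @export
build_vocab <- function(smiles) {
  toks <- unique(unlist(lapply(smiles, function(s) tokenize(s)$tokens)))
  c(.SPECIAL_TOKENS, sort(toks, method = "radix"))
}

# token ids (1-based into vocab) for one SMILES; errors name unknown tokens
token_ids <- function(smiles, vocab) {
  toks <- tokenize(smiles)$tokens
  ids <- match(toks, vocab)
  if (anyNA(ids)) {
    bad <- unique(toks[is.na(ids)])
    stop(sprintf("tokens not in vocabulary: %s (smiles '%s')",
                 paste(bad, collapse = ", "), smiles))
  }
  ids
}
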