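## k-mer tokenization: DNA sequences <-> overlapping k-mer token ids.
## Ids are 0-based; specials occupy ids 0..4, k-mers follow lexicographically.

.SPECIAL_TOKENS <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]")
.PAD_ID <- 0L
.UNK_ID <- 1L
.CLS_ID <- 2L
.SEP_ID <- 3L
.MASK_ID <- 4L

#' Build a k-mer vocabulary
#'
#' Enumerates all 4^k DNA k-mers plus the five special tokens `[PAD]`,
#' `[UNK]`, `[CLS]`, `[SEP]`, `[MASK]`.  Specials take ids 0--4 (in that
#' order); k-mers follow in lexicographic order over A < C < G < T, so ids are
#' stable across runs and machines.
#'
#' @param k k-mer length; supported range 1--8.
#' @return a [KmerVocabulary] of size 4^k + 5.
#' @examples
#' v <- buildVocabulary(3)
#' vocabSize(v)  # 69
#' @export
buildVocabulary <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k != as.integer(k) ||
      k < 1 || k > 8)
    stop("k must be a single integer in 1..8")
  k <- as.integer(k)
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(rep(list(bases), k), stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; reverse columns so the
  # *last* base varies fastest, i.e. lexicographic order.
  kmers <- do.call(paste0, grid[, rev(seq_len(k)), drop = FALSE])
  new("KmerVocabulary", k = k, tokens = c(.SPECIAL_TOKENS, kmers))
}

#' Map tokens to ids and back
#'
#' @param vocab a [KmerVocabulary].
#' @param token character vector of tokens.
#' @param id integer vector of 0-based ids.
#' @return `tokenId()` returns 0-based ids (k-mers containing characters
#'   outside A/C/G/T map to the `[UNK]` id); `idToToken()` returns the token
#'   strings.
#' @export
tokenId <- function(vocab, token) {
  ids <- match(token, vocab@tokens) - 1L
  ids[is.na(ids)] <- .UNK_ID
  ids
}

#' @rdname tokenId
#' @export
idToToken <- function(vocab, id) {
  stopifnot(all(id >= 0L), all(id < length(vocab@tokens)))
  vocab@tokens[id + 1L]
}

#' Tokenize a DNA sequence into overlapping k-mers
#'
#' Slides a k-base window at stride 1, so an L-base sequence yields
#' L - k + 1 tokens; e.g. `"ATGGCTG"` at k = 6 gives the two tokens
#' `ATGGCT` and `TGGCTG`.  Any k-mer containing a character outside
#' A/C/G/T (e.g. N) maps to `[UNK]`.  Input is upper-cased first, so
#' soft-masked genome sequence is treated as ordinary bases.
#'
#' When the tokenized length (including specials) exceeds `maxLen` the k-mer
#' tokens are truncated symmetrically around the central token, with a
#' warning -- benchmark windows are centered on the candidate site, so the
#' center is the part that must survive.
#'
#' @param seq a single DNA string (or length-1 [Biostrings::DNAStringSet]).
#' @param vocab a [KmerVocabulary].
#' @param maxLen optional maximum token count; output is right-padded with
#'   `[PAD]` (mask 0) up to this length.
#' @param addSpecials wrap the token run in `[CLS]` ... `[SEP]` (default TRUE).
#' @return a [TokenizedSequence].
#' @export
tokenize <- function(seq, vocab, maxLen = NULL, addSpecials = TRUE) {
  if (methods::is(seq, "DNAStringSet") || methods::is(seq, "DNAString"))
    seq <- as.character(seq)
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  k <- vocab@k
  L <- nchar(seq)
  if (L < k)
    stop(sprintf("sequence length %d is shorter than k = %d", L, k))
  n <- L - k + 1L
  kmers <- substring(seq, seq_len(n), seq_len(n) + k - 1L)
  ids <- tokenId(vocab, kmers)
  spans <- cbind(start = 0:(n - 1L), end = 0:(n - 1L) + k)

  nspec <- if (addSpecials) 2L else 0L
  if (!is.null(maxLen) && n + nspec > maxLen) {
    keep <- maxLen - nspec
    if (keep < 1L)
      stop("maxLen leaves no room for sequence tokens")
    # symmetric truncation around the central token
    lo <- (n - keep) %/% 2L + 1L
    sel <- lo:(lo + keep - 1L)
    warning(sprintf(
      "tokenized length %d exceeds maxLen %d; truncated symmetrically to %d k-mer tokens",
      n + nspec, maxLen, keep))
    ids <- ids[sel]; spans <- spans[sel, , drop = FALSE]; n <- keep
  }
  if (addSpecials) {
    ids <- c(.CLS_ID, ids, .SEP_ID)
    spans <- rbind(c(NA_integer_, NA_integer_), spans,
                   c(NA_integer_, NA_integer_))
  }
  mask <- rep(1L, length(ids))
  if (!is.null(maxLen) && length(ids) < maxLen) {
    npad <- maxLen - length(ids)
    ids <- c(ids, rep(.PAD_ID, npad))
    mask <- c(mask, rep(0L, npad))
    spans <- rbind(spans, matrix(NA_integer_, npad, 2L))
  }
  colnames(spans) <- c("start", "end")
  new("TokenizedSequence", ids = as.integer(ids), mask = as.integer(mask),
      spans = spans, k = k)
}

#' Reconstruct the DNA sequence from stride-1 k-mer tokens
#'
#' Inverse of [tokenize()] for sequences without ambiguity codes: the first
#' token contributes k bases and each subsequent token its last base.
#'
#' @param tok a [TokenizedSequence].
#' @param vocab the [KmerVocabulary] used to tokenize.
#' @return the reconstructed DNA string.
#' @export
detokenize <- function(tok, vocab) {
  real <- tok@mask == 1L & !is.na(tok@spans[, 1L])
  ids <- tok@ids[real]
  if (!length(ids)) stop("no k-mer tokens to reconstruct from")
  if (any(ids == .UNK_ID))
    stop("cannot reconstruct: [UNK] token present")
  if (any(ids < 5L))
    stop("cannot reconstruct: unexpected special token among k-mers")
  spans <- tok@spans[real, , drop = FALSE]
  if (nrow(spans) > 1L && any(diff(spans[, 1L]) != 1L))
    stop("cannot reconstruct: token spans are not consecutive stride-1 k-mers")
  toks <- idToToken(vocab, ids)
  k <- vocab@k
  paste0(toks[1L], paste(substring(toks[-1L], k, k), collapse = ""))
}

#' Read or write a vocabulary as plain text
#'
#' One token per line; the id of the token on line i is i - 1, matching the
#' usual k-mer language-model vocabulary convention.
#'
#' @param vocab a [KmerVocabulary].
#' @param path file path.
#' @return `readVocabulary()` returns a [KmerVocabulary].
#' @export
writeVocabulary <- function(vocab, path) {
  writeLines(vocab@tokens, path)
  invisible(path)
}

#' @rdname writeVocabulary
#' @export
readVocabulary <- function(path) {
  tokens <- readLines(path)
  if (length(tokens) < 6L || !identical(tokens[1:5], .SPECIAL_TOKENS))
    stop("not a vocabulary file: first five lines must be the special tokens")
  new("KmerVocabulary", k = nchar(tokens[6L]), tokens = tokens)
}

## Batched tokenization to an id matrix (rows = sequences).  All sequences
## must share one length; used by the model forward pass.
.tokenizeMatrix <- function(seqs, vocab, addSpecials = TRUE) {
  stopifnot(length(unique(nchar(seqs))) == 1L)
  toks <- lapply(seqs, tokenize, vocab = vocab, addSpecials = addSpecials)
  ids <- do.call(rbind, lapply(toks, methods::slot, "ids"))
  list(ids = ids, spans = toks[[1L]]@spans, k = vocab@k)
}
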