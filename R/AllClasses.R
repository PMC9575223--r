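#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet width
#' @importFrom S4Vectors metadata metadata<- mcols mcols<-
NULL

#' KmerVocabulary: bijection between k-mer tokens and integer ids
#'
#' A vocabulary over all 4^k DNA k-mers plus the five special tokens
#' `[PAD]`, `[UNK]`, `[CLS]`, `[SEP]`, `[MASK]` (ids 0--4, in that order),
#' followed by the k-mers in lexicographic order (A < C < G < T) starting at
#' id 5.  Total size is 4^k + 5.  Ids are 0-based and stable across runs.
#'
#' @slot k k-mer length (integer, 1--8).
#' @slot tokens character vector of all tokens; the id of `tokens[i]` is
#'   `i - 1`.
#' @name KmerVocabulary
#' @aliases KmerVocabulary
#' @exportClass KmerVocabulary
setClass("KmerVocabulary",
  representation(k = "integer", tokens = "character"))

setValidity("KmerVocabulary", function(object) {
  msg <- character()
  if (length(object@k) != 1L || object@k < 1L)
    msg <- c(msg, "k must be a single positive integer")
  if (length(object@tokens) != 4L^object@k + 5L)
    msg <- c(msg, sprintf("vocabulary must contain 4^k + 5 = %d tokens",
                          4L^object@k + 5L))
  if (anyDuplicated(object@tokens))
    msg <- c(msg, "tokens must be unique")
  if (!identical(object@tokens[1:5], .SPECIAL_TOKENS))
    msg <- c(msg, "first five tokens must be the special tokens")
  if (length(msg)) msg else TRUE
})

#' TokenizedSequence: token ids with mask and source coordinates
#'
#' @slot ids integer vector of 0-based token ids.
#' @slot mask integer vector, 1 for real tokens (incl. CLS/SEP), 0 for padding.
#' @slot spans integer matrix with columns `start`, `end` giving the 0-based
#'   half-open coordinates of each k-mer token in the source sequence; rows for
#'   special/padding tokens are `NA`.
#' @slot k k-mer length used.
#' @name TokenizedSequence
#' @aliases TokenizedSequence
#' @exportClass TokenizedSequence
setClass("TokenizedSequence",
  representation(ids = "integer", mask = "integer", spans = "matrix",
                 k = "integer"))

setValidity("TokenizedSequence", function(object) {
  msg <- character()
  if (length(object@mask) != length(object@ids))
    msg <- c(msg, "mask length must equal ids length")
  if (nrow(object@spans) != length(object@ids))
    msg <- c(msg, "spans must have one row per token")
  if (!all(object@mask %in% c(0L, 1L)))
    msg <- c(msg, "mask must be binary")
  if (length(msg)) msg else TRUE
})

#' MethDataSet: labeled fixed-length methylation sequence windows
#'
#' Container for a benchmark-shaped dataset: equal-length DNA windows centered
#' on a candidate site, each labeled 1 (methylated) or 0 (non-methylated),
#' with optional per-record tags (species, methylation type, context, ...).
#'
#' @slot sequences a [Biostrings::DNAStringSet]; all elements the same width.
#' @slot labels integer vector in \{0, 1\}, parallel to `sequences`.
#' @slot meta data.frame of per-record tags (may have zero columns).
#' @name MethDataSet
#' @aliases MethDataSet
#' @exportClass MethDataSet
setClass("MethDataSet",
  representation(sequences = "DNAStringSet", labels = "integer",
                 meta = "data.frame"))

setValidity("MethDataSet", function(object) {
  msg <- character()
  n <- length(object@sequences)
  if (length(object@labels) != n)
    msg <- c(msg, "labels must be parallel to sequences")
  if (n > 0 && length(unique(Biostrings::width(object@sequences))) != 1L)
    msg <- c(msg, "all sequences must share one length")
  if (!all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0 or 1")
  if (nrow(object@meta) != 0L && nrow(object@meta) != n)
    msg <- c(msg, "meta must have one row per record (or none)")
  if (length(msg)) msg else TRUE
})

#' MethFusionModel: dual-scale fused transformer classifier
#'
#' Holds the two k-mer vocabularies, the two scale-specific transformer
#' encoders, the sigmoid fusion gate, and the classification head.  Parameters
#' live in a named list tree (`params`); `config` records the architecture
#' (k-mer pair, encoder profile, input length).
#'
#' @slot config named list: `k1`, `k2`, `seqLen`, `encoder` (an encoder
#'   config as from [encoderConfig()]), `threshold`.
#' @slot params named list with elements `enc1`, `enc2`, `fusion`, `head`.
#' @slot vocab1,vocab2 the [KmerVocabulary] of each scale.
#' @name MethFusionModel
#' @aliases MethFusionModel
#' @exportClass MethFusionModel
setClass("MethFusionModel",
  representation(config = "list", params = "list",
                 vocab1 = "KmerVocabulary", vocab2 = "KmerVocabulary"))

#' MotifPWM: position weight matrix with support count
#'
#' @slot prob numeric matrix, width x 4 (columns A, C, G, T); rows sum to 1.
#' @slot nsites number of subsequences the matrix was built from.
#' @name MotifPWM
#' @aliases MotifPWM
#' @exportClass MotifPWM
setClass("MotifPWM",
  representation(prob = "matrix", nsites = "integer"))

setValidity("MotifPWM", function(object) {
  msg <- character()
  if (ncol(object@prob) != 4L)
    msg <- c(msg, "prob must have 4 columns (A, C, G, T)")
  if (any(abs(rowSums(object@prob) - 1) > 1e-9))
    msg <- c(msg, "each row of prob must sum to 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "KmerVocabulary", function(object) {
  cat(sprintf("KmerVocabulary: k=%d, %d tokens (4^k + 5)\n",
              object@k, length(object@tokens)))
})

setMethod("show", "MethDataSet", function(object) {
  n <- length(object@sequences)
  w <- if (n) Biostrings::width(object@sequences)[1] else NA_integer_
  cat(sprintf("MethDataSet: %d records, width %s bp, %d positive / %d negative\n",
              n, w, sum(object@labels == 1L), sum(object@labels == 0L)))
  if (ncol(object@meta))
    cat("  tags:", paste(colnames(object@meta), collapse = ", "), "\n")
})

setMethod("show", "MethFusionModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "MethFusionModel: scales %d-mer + %d-mer, input %d bp\n",
    cfg$k1, cfg$k2, cfg$seqLen))
  ec <- cfg$encoder
  cat(sprintf("  encoders: %d layers, d_m=%d, %d heads, ffn=%d\n",
              ec$numLayers, ec$modelDim, ec$numHeads, ec$ffDim))
})

setMethod("show", "MotifPWM", function(object) {
  cat(sprintf("MotifPWM: width %d, built from %d subsequences; consensus %s\n",
              nrow(object@prob), object@nsites, pwmConsensus(object)))
})
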