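#' @export
setGeneric("kmerSize", function(x) standardGeneric("kmerSize"))

#' @export
setGeneric("vocabSize", function(x) standardGeneric("vocabSize"))

#' @export
setGeneric("vocabTokens", function(x) standardGeneric("vocabTokens"))

#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @export
setGeneric("labels")

#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))

#' Accessors
#'
#' `kmerSize()` returns the k of a vocabulary (or the scale pair of a model);
#' `vocabSize()` the number of tokens (4^k + 5); `vocabTokens()` the ordered
#' token table; `sequences()` / `labels()` the contents of a [MethDataSet];
#' `modelConfig()` the architecture list of a [MethFusionModel].
#'
#' @param x the object.
#' @name accessors
#' @aliases kmerSize vocabSize vocabTokens sequences modelConfig
NULL

setMethod("kmerSize", "KmerVocabulary", function(x) x@k)
setMethod("vocabSize", "KmerVocabulary", function(x) length(x@tokens))
setMethod("vocabTokens", "KmerVocabulary", function(x) x@tokens)
setMethod("kmerSize", "MethFusionModel",
          function(x) c(x@config$k1, x@config$k2))
setMethod("sequences", "MethDataSet", function(x) x@sequences)
setMethod("labels", "MethDataSet", function(object, ...) object@labels)
setMethod("modelConfig", "MethFusionModel", function(x) x@config)

#' @export
setMethod("length", "MethDataSet", function(x) length(x@sequences))

#' Subset a MethDataSet
#' @param x a [MethDataSet].
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "MethDataSet", function(x, i, j, ..., drop = FALSE) {
  meta <- if (nrow(x@meta)) x@meta[i, , drop = FALSE] else x@meta
  rownames(meta) <- NULL
  new("MethDataSet", sequences = x@sequences[i], labels = x@labels[i],
      meta = meta)
})
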