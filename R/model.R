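## Dual-scale model: two k-mer tokenizers -> two transformer encoders ->
## CLS-pooled vectors -> dimension-wise sigmoid fusion gate -> fully
## connected classification head -> methylation probability.

#' Construct a dual-scale fusion model
#'
#' Builds the full classifier: a k1-mer and a k2-mer vocabulary, one
#' transformer encoder per scale (parameters not shared -- the vocabularies
#' differ), the sigmoid fusion gate, and a two-layer classification head
#' (d_m -> d_m/2 -> 1).  The default scale pair (3, 6) is the combination
#' with the best benchmark performance.
#'
#' @param seqLen input window length in bases (default 41).
#' @param k1,k2 the two k-mer scales (default 3 and 6).
#' @param encoder an [encoderConfig()]; default the desk profile.
#' @param headDropout dropout rate in the classification head during
#'   training (default 0.1).
#' @param threshold decision threshold on the probability (default 0.5).
#' @param seed seed for parameter initialization.
#' @return a [MethFusionModel].
#' @examples
#' m <- buildModel(seqLen = 41, seed = 1)
#' @export
buildModel <- function(seqLen = 41L, k1 = 3L, k2 = 6L,
                       encoder = encoderConfig("desk"),
                       headDropout = 0.1, threshold = 0.5, seed = 1L) {
  stopifnot(seqLen >= max(k1, k2))
  v1 <- buildVocabulary(k1); v2 <- buildVocabulary(k2)
  d <- encoder$modelDim; dh <- max(1L, d %/% 2L)
  set.seed(seed)
  xa <- function(nr, nc)
    matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
  params <- list(
    enc1 = .initEncoder(encoder, vocabSize(v1)),
    enc2 = .initEncoder(encoder, vocabSize(v2)),
    fusion = list(W1 = xa(d, d), W2 = xa(d, d)),
    head = list(Wh1 = xa(d, dh), bh1 = numeric(dh),
                wh2 = xa(dh, 1L), bh2 = 0))
  cfg <- list(k1 = as.integer(k1), k2 = as.integer(k2),
              seqLen = as.integer(seqLen), encoder = encoder,
              headDropout = headDropout, threshold = threshold)
  new("MethFusionModel", config = cfg, params = params,
      vocab1 = v1, vocab2 = v2)
}

#' Model parameters
#' @param x a [MethFusionModel].
#' @return the nested parameter list (`enc1`, `enc2`, `fusion`, `head`).
#' @export
modelParams <- function(x) x@params

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Fuse two representations through the sigmoid gate
#'
#' Computes the dimension-wise gate F = sigmoid(h1 W1 + h2 W2) and returns
#' F * h1 + (1 - F) * h2 -- a per-dimension convex combination of the two
#' scale representations, so each output coordinate lies between the
#' corresponding coordinates of `h1` and `h2`.
#'
#' @param h1,h2 numeric vectors of length d_m (or matrices with d_m columns,
#'   one row per sample).
#' @param W1,W2 trainable d_m x d_m gate matrices.
#' @return the fused representation, same shape as the inputs; the gate is
#'   attached as attribute `"gate"`.
#' @export
fusionGate <- function(h1, h2, W1, W2) {
  v <- is.null(dim(h1))
  if (v) { h1 <- matrix(h1, 1L); h2 <- matrix(h2, 1L) }
  if (ncol(h1) != nrow(W1) || ncol(h2) != nrow(W2) ||
      !all(dim(W1) == dim(W2)) || ncol(h1) != ncol(h2))
    stop("dimension mismatch in fusion gate")
  G <- .sigmoid(h1 %*% W1 + h2 %*% W2)
  out <- G * h1 + (1 - G) * h2
  if (v) { g <- drop(G); out <- drop(out); attr(out, "gate") <- g }
  else attr(out, "gate") <- G
  out
}

## Head forward on a B x d matrix of fused vectors.  Dropout only when
## training; mask cached for backward.
.headForward <- function(head, hM, rate = 0, training = FALSE) {
  Z1 <- .addBias(hM %*% head$Wh1, head$bh1)
  A1 <- pmax(Z1, 0)
  dm <- if (training) .dropoutMask(nrow(A1), ncol(A1), rate) else NULL
  D <- if (is.null(dm)) A1 else A1 * dm
  logit <- drop(D %*% head$wh2) + head$bh2
  p <- .sigmoid(logit)
  list(p = p, logit = logit, Z1 = Z1, D = D, dm = dm)
}

#' Classify a fused representation
#'
#' Two fully connected layers (d_m -> d_m/2, ReLU, then a single logit) and a
#' sigmoid give the methylation probability.  Deterministic at inference
#' (dropout off).
#'
#' @param hM numeric vector of length d_m (or matrix, samples x d_m).
#' @param head named list with `Wh1`, `bh1`, `wh2`, `bh2` (e.g.
#'   `modelParams(model)$head`).
#' @return probability vector in \[0, 1\].
#' @export
classifyHidden <- function(hM, head) {
  if (is.null(dim(hM))) hM <- matrix(hM, 1L)
  if (any(!is.finite(hM))) stop("non-finite input to classification head")
  .headForward(head, hM)$p
}

## ---- full forward / backward --------------------------------------------

## Batched forward.  ids1/ids2: B x T integer matrices (0-based ids),
## mask1/mask2 binary matrices.  perturb1/perturb2 add to the respective
## embedding outputs (FGM site).  Returns probabilities + caches for backward.
.modelForward <- function(model, tokens, perturb1 = NULL, perturb2 = NULL,
                          training = FALSE, keepAttention = FALSE,
                          needCache = training) {
  cfg <- model@config$encoder
  f1 <- .encForward(model@params$enc1, tokens$ids1, tokens$mask1, cfg,
                    perturb = perturb1, training = training,
                    keepAttention = keepAttention, needCache = needCache)
  f2 <- .encForward(model@params$enc2, tokens$ids2, tokens$mask2, cfg,
                    perturb = perturb2, training = training,
                    keepAttention = keepAttention, needCache = needCache)
  fu <- model@params$fusion
  G <- .sigmoid(f1$pooled %*% fu$W1 + f2$pooled %*% fu$W2)
  hM <- G * f1$pooled + (1 - G) * f2$pooled
  hf <- .headForward(model@params$head, hM,
                     rate = model@config$headDropout, training = training)
  list(p = hf$p, f1 = f1, f2 = f2, G = G, hM = hM, hf = hf)
}

## Backward from dLogit (length B).  Returns gradient tree matching params
## plus dS1/dS2, the embedding-output gradients used by FGM.
.modelBackward <- function(model, fwd, dLogit) {
  cfg <- model@config$encoder
  head <- model@params$head; fu <- model@params$fusion
  hf <- fwd$hf
  dLogit <- matrix(dLogit, ncol = 1L)
  dwh2 <- crossprod(hf$D, dLogit)
  dbh2 <- sum(dLogit)
  dD <- dLogit %*% t(head$wh2)
  if (!is.null(hf$dm)) dD <- dD * hf$dm
  dZ1 <- dD * (hf$Z1 > 0)
  dWh1 <- crossprod(fwd$hM, dZ1)
  dbh1 <- colSums(dZ1)
  dhM <- dZ1 %*% t(head$Wh1)

  h1 <- fwd$f1$pooled; h2 <- fwd$f2$pooled; G <- fwd$G
  dG <- dhM * (h1 - h2)
  dGz <- dG * G * (1 - G)
  dW1 <- crossprod(h1, dGz)
  dW2 <- crossprod(h2, dGz)
  dh1 <- dhM * G + dGz %*% t(fu$W1)
  dh2 <- dhM * (1 - G) + dGz %*% t(fu$W2)

  b1 <- .encBackward(model@params$enc1, fwd$f1, cfg, dh1)
  b2 <- .encBackward(model@params$enc2, fwd$f2, cfg, dh2)
  list(grads = list(enc1 = b1$grads, enc2 = b2$grads,
                    fusion = list(W1 = dW1, W2 = dW2),
                    head = list(Wh1 = dWh1, bh1 = dbh1,
                                wh2 = dwh2, bh2 = dbh2)),
       dS1 = b1$dS, dS2 = b2$dS)
}

## Tokenize a character vector of equal-length sequences at both scales.
.modelTokens <- function(model, seqs) {
  t1 <- .tokenizeMatrix(seqs, model@vocab1)
  t2 <- .tokenizeMatrix(seqs, model@vocab2)
  list(ids1 = t1$ids, mask1 = matrix(1L, nrow(t1$ids), ncol(t1$ids)),
       ids2 = t2$ids, mask2 = matrix(1L, nrow(t2$ids), ncol(t2$ids)),
       spans1 = t1$spans, spans2 = t2$spans)
}

#' Predict methylation probabilities
#'
#' Tokenizes each sequence at both scales, encodes, fuses and classifies.
#' Attention maps can be retained for interpretation.
#'
#' @param object a [MethFusionModel].
#' @param newdata a [MethDataSet], [Biostrings::DNAStringSet], or character
#'   vector of sequences of the model's input length.
#' @param keepAttention retain per-scale attention maps (in attribute
#'   `"attention"`: for each scale a list of per-layer `T x T x h` arrays per
#'   sequence).
#' @param batchSize forward batch size.
#' @param ... unused.
#' @return data.frame with columns `id`, `sequence`, `probability`, `label`
#'   (1 iff probability >= the model threshold).
#' @export
setMethod("predict", "MethFusionModel",
function(object, newdata, keepAttention = FALSE, batchSize = 64L, ...) {
  seqs <- if (methods::is(newdata, "MethDataSet"))
    as.character(sequences(newdata))
  else as.character(newdata)
  if (any(nchar(seqs) != object@config$seqLen))
    stop(sprintf("model expects %d-bp sequences", object@config$seqLen))
  n <- length(seqs)
  probs <- numeric(n)
  attn <- if (keepAttention) vector("list", n) else NULL
  for (lo in seq(1L, n, by = batchSize)) {
    hi <- min(lo + batchSize - 1L, n)
    tk <- .modelTokens(object, seqs[lo:hi])
    fwd <- .modelForward(object, tk, keepAttention = keepAttention)
    probs[lo:hi] <- fwd$p
    if (keepAttention) {
      B <- hi - lo + 1L
      h <- object@config$encoder$numHeads
      for (b in seq_len(B)) {
        sl <- ((b - 1L) * h + 1L):(b * h)
        attn[[lo + b - 1L]] <- list(
          scale1 = lapply(fwd$f1$attn, function(a) a[, , sl, drop = FALSE]),
          scale2 = lapply(fwd$f2$attn, function(a) a[, , sl, drop = FALSE]),
          spans1 = tk$spans1, spans2 = tk$spans2)
      }
    }
  }
  ids <- if (methods::is(newdata, "MethDataSet") &&
             !is.null(names(sequences(newdata)))) names(sequences(newdata))
  else sprintf("seq%d", seq_len(n))
  out <- data.frame(id = ids, sequence = seqs, probability = probs,
                    label = as.integer(probs >= object@config$threshold),
                    stringsAsFactors = FALSE)
  if (keepAttention) attr(out, "attention") <- attn
  out
})

#' Write predictions as TSV
#' @param pred data.frame from [predict()].
#' @param path output path.
#' @export
writePredictions <- function(pred, path) {
  utils::write.table(pred[, c("id", "sequence", "probability", "label")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- checkpointing -------------------------------------------------------

#' Save and load model checkpoints
#'
#' A checkpoint is the named parameter tree plus the architecture config,
#' serialized with R's native format.  `loadPretrained()` validates every
#' tensor against the target architecture and fails listing the offending
#' names; with `partial = TRUE` mismatched or missing tensors keep their
#' fresh initialization and are reported in a message (e.g. loading an
#' encoder-only checkpoint under a new head).
#'
#' @param model a [MethFusionModel].
#' @param path checkpoint path.
#' @param partial allow a partial load (default FALSE).
#' @return `loadPretrained()` returns the model with parameters replaced.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(config = model@config, params = model@params), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadPretrained <- function(model, path, partial = FALSE) {
  ck <- readRDS(path)
  flatNew <- .flattenParams(ck$params)
  flatCur <- .flattenParams(model@params)
  bad <- character(); missing <- setdiff(names(flatCur), names(flatNew))
  for (nm in intersect(names(flatCur), names(flatNew))) {
    if (!identical(dim(flatCur[[nm]]) %||% length(flatCur[[nm]]),
                   dim(flatNew[[nm]]) %||% length(flatNew[[nm]])))
      bad <- c(bad, nm)
  }
  if (length(bad) && !partial)
    stop("checkpoint tensor shape mismatch: ", paste(bad, collapse = ", "))
  if (length(missing) && !partial)
    stop("checkpoint missing tensors: ", paste(missing, collapse = ", "))
  skipped <- union(bad, missing)
  for (nm in setdiff(names(flatCur), skipped))
    flatCur[[nm]] <- flatNew[[nm]]
  if (length(skipped))
    message("loadPretrained: kept fresh initialization for ",
            length(skipped), " tensors: ",
            paste(utils::head(skipped, 10L), collapse = ", "),
            if (length(skipped) > 10L) ", ...")
  model@params <- .unflattenParams(flatCur, model@params)
  model
}

## Flatten a nested parameter list into a named flat list ("enc1.layers.1.Wq")
.flattenParams <- function(tree, prefix = NULL) {
  out <- list()
  for (nm in seq_along(tree)) {
    key <- if (is.null(names(tree)) || names(tree)[nm] == "")
      as.character(nm) else names(tree)[nm]
    full <- if (is.null(prefix)) key else paste(prefix, key, sep = ".")
    el <- tree[[nm]]
    if (is.list(el)) out <- c(out, .flattenParams(el, full))
    else out[[full]] <- el
  }
  out
}

.unflattenParams <- function(flat, template, prefix = NULL) {
  for (nm in seq_along(template)) {
    key <- if (is.null(names(template)) || names(template)[nm] == "")
      as.character(nm) else names(template)[nm]
    full <- if (is.null(prefix)) key else paste(prefix, key, sep = ".")
    if (is.list(template[[nm]]))
      template[[nm]] <- .unflattenParams(flat, template[[nm]], full)
    else template[[nm]] <- flat[[full]]
  }
  template
}
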