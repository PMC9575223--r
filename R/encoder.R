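## Transformer encoder: BERT-style post-norm blocks over embedded k-mer
## tokens.  Forward/backward are hand-written (no autodiff framework); the
## attention inner loop is compiled (src/attention.cpp) and everything else is
## vectorized R.  Batches are stored row-major: sequence b of a batch of B
## length-T token runs occupies rows (b-1)*T + 1 .. b*T of the (B*T) x d_m
## state matrix.

#' Encoder architecture configuration
#'
#' Two stock profiles are provided.  `"desk"` (2 layers, d_m = 64, 4 heads,
#' feed-forward 128) trains in minutes on one CPU and is the default
#' everywhere in this package; `"full"` mirrors the BERT-base geometry
#' (12 layers, d_m = 768, 12 heads) used by genomic language models, for use
#' with an externally pretrained checkpoint.
#'
#' @param profile `"desk"` or `"full"`, or NULL when giving dims directly.
#' @param pooling sequence pooling: `"cls"` (final-layer CLS row, the BERT
#'   convention) or `"mean"` (masked mean over token positions).
#' @param numLayers,modelDim,numHeads,ffDim,maxLen,dropout explicit settings;
#'   any given value overrides the profile.  `numHeads` must divide
#'   `modelDim` (head dim d_k = d_m / h).
#' @return a named list with class `"encoderConfig"`.
#' @export
encoderConfig <- function(profile = c("desk", "full"),
                          numLayers = NULL, modelDim = NULL, numHeads = NULL,
                          ffDim = NULL, maxLen = 512L, dropout = NULL,
                          pooling = c("cls", "mean")) {
  base <- switch(match.arg(profile),
    desk = list(numLayers = 2L, modelDim = 64L, numHeads = 4L,
                ffDim = 128L, dropout = 0.1),
    full = list(numLayers = 12L, modelDim = 768L, numHeads = 12L,
                ffDim = 3072L, dropout = 0.1))
  cfg <- list(
    numLayers = as.integer(numLayers %||% base$numLayers),
    modelDim  = as.integer(modelDim %||% base$modelDim),
    numHeads  = as.integer(numHeads %||% base$numHeads),
    ffDim     = as.integer(ffDim %||% base$ffDim),
    maxLen    = as.integer(maxLen),
    dropout   = dropout %||% base$dropout,
    pooling   = match.arg(pooling))
  if (cfg$modelDim %% cfg$numHeads != 0L)
    stop("numHeads must divide modelDim (h * d_k = d_m)")
  cfg$headDim <- cfg$modelDim %/% cfg$numHeads
  if (cfg$numLayers < 0L || cfg$modelDim < 1L || cfg$ffDim < 1L)
    stop("encoder dimensions must be positive")
  class(cfg) <- "encoderConfig"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scaled dot-product self-attention
#'
#' Computes Q = X W_q, K = X W_k, V = X W_v, then
#' softmax(Q K' / sqrt(d_k)) V.  Masked key positions (mask 0) are set to
#' -Inf before the softmax and so receive exactly zero weight.  Exposed as a
#' single-head building block; the model itself uses the batched compiled
#' path.
#'
#' @param X numeric matrix, positions x d_m.
#' @param Wq,Wk,Wv projection matrices, d_m x d_k.
#' @param mask optional binary vector over positions (1 = real, 0 = padding).
#' @return list with `output` (positions x d_k) and `attention`
#'   (positions x positions, rows summing to 1).
#' @export
selfAttention <- function(X, Wq, Wk, Wv, mask = NULL) {
  stopifnot(is.matrix(X), ncol(X) == nrow(Wq), ncol(X) == nrow(Wk),
            ncol(X) == nrow(Wv))
  if (ncol(Wq) != ncol(Wk) || ncol(Wq) != ncol(Wv))
    stop("Wq, Wk, Wv must project to a common head dimension d_k")
  dk <- ncol(Wq)
  Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
  S <- tcrossprod(Q, K) / sqrt(dk)
  if (!is.null(mask)) {
    stopifnot(length(mask) == nrow(X))
    S[, mask == 0] <- -Inf
  }
  A <- .softmaxRows(S)
  list(output = A %*% V, attention = A)
}

#' Multi-head attention
#'
#' Runs `h` independent [selfAttention()] heads, concatenates their outputs,
#' and maps back to d_m through the output projection W_O.
#'
#' @param X numeric matrix, positions x d_m.
#' @param heads list of `h` lists, each with elements `Wq`, `Wk`, `Wv`
#'   (d_m x d_k).
#' @param Wo output projection, (h * d_k) x d_m.
#' @param mask optional binary vector over positions.
#' @return numeric matrix, positions x d_m.
#' @export
multiHeadAttention <- function(X, heads, Wo, mask = NULL) {
  dk <- ncol(heads[[1L]]$Wq)
  if (length(heads) * dk != ncol(X))
    stop("h * d_k must equal d_m")
  outs <- lapply(heads, function(hd)
    selfAttention(X, hd$Wq, hd$Wk, hd$Wv, mask)$output)
  do.call(cbind, outs) %*% Wo
}

.softmaxRows <- function(S) {
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E[is.na(E)] <- 0   # rows that are all -Inf (fully masked) -> zeros
  E / pmax(rowSums(E), .Machine$double.xmin)
}

## ---- parameter initialization -------------------------------------------

## Xavier init for projections; embeddings scaled so per-token norms are
## O(1) regardless of d_m (keeps the FGM epsilon scale comparable across
## model sizes).
.initEncoder <- function(cfg, vocabSize) {
  d <- cfg$modelDim; ff <- cfg$ffDim
  xa <- function(nr, nc)
    matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
  emb <- function(nr, nc)
    matrix(stats::rnorm(nr * nc, sd = 0.8 / sqrt(nc)), nr, nc)
  layers <- lapply(seq_len(cfg$numLayers), function(l) list(
    Wq = xa(d, d), bq = numeric(d),
    Wk = xa(d, d), bk = numeric(d),
    Wv = xa(d, d), bv = numeric(d),
    Wo = xa(d, d), bo = numeric(d),
    g1 = rep(1, d), b1 = numeric(d),
    W1 = xa(d, ff), bf1 = numeric(ff),
    W2 = xa(ff, d), bf2 = numeric(d),
    g2 = rep(1, d), b2 = numeric(d)))
  list(E = emb(vocabSize, d), P = emb(cfg$maxLen, d), layers = layers)
}

## ---- forward / backward --------------------------------------------------

.gelu <- function(x) x * stats::pnorm(x)
.geluGrad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

.addBias <- function(M, b) M + matrix(b, nrow(M), length(b), byrow = TRUE)
.byRow <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

.lnForward <- function(M, gamma, beta, eps = 1e-12) {
  mu <- rowMeans(M)
  Mc <- M - mu
  v <- rowMeans(Mc * Mc)
  inv <- 1 / sqrt(v + eps)
  xhat <- Mc * inv
  out <- xhat * .byRow(gamma, nrow(M)) + .byRow(beta, nrow(M))
  list(out = out, xhat = xhat, inv = inv)
}

.lnBackward <- function(dOut, cache, gamma) {
  xhat <- cache$xhat
  dgamma <- colSums(dOut * xhat)
  dbeta <- colSums(dOut)
  dxhat <- dOut * .byRow(gamma, nrow(dOut))
  dX <- cache$inv *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

.dropoutMask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= rate) / (1 - rate), nr, nc)
}

## ids: B x T integer matrix of 0-based token ids; mask: B x T binary.
## perturb: optional (B*T) x d matrix added to the embedding-lookup output
## (the FGM perturbation site).  training enables dropout.
.encForward <- function(enc, ids, mask, cfg, perturb = NULL,
                        training = FALSE, keepAttention = FALSE,
                        needCache = TRUE) {
  B <- nrow(ids); T <- ncol(ids); d <- cfg$modelDim
  if (any(ids < 0L) || any(ids >= nrow(enc$E)))
    stop("token id out of vocabulary range")
  if (T > nrow(enc$P))
    stop(sprintf("sequence of %d tokens exceeds positional table (%d)",
                 T, nrow(enc$P)))
  flat <- as.vector(t(ids)) + 1L            # row (b-1)*T + t <- seq b, tok t
  S <- enc$E[flat, , drop = FALSE]
  if (!is.null(perturb)) S <- S + perturb
  X <- S + enc$P[rep(seq_len(T), B), , drop = FALSE]
  maskM <- matrix(as.numeric(mask), B, T)
  rate <- if (training) cfg$dropout else 0
  caches <- vector("list", cfg$numLayers)
  attns <- if (keepAttention) vector("list", cfg$numLayers) else NULL

  for (l in seq_len(cfg$numLayers)) {
    dm1 <- .dropoutMask(B * T, d, rate)
    dm2 <- .dropoutMask(B * T, d, rate)
    ca <- .encLayerForwardCpp(X, enc$layers[[l]], B, T, cfg$numHeads,
                              cfg$headDim, maskM, dm1, dm2,
                              needCache = needCache,
                              keepAttn = keepAttention)
    if (needCache) {
      ca$Xin <- X; ca$dm1 <- dm1; ca$dm2 <- dm2
      caches[[l]] <- ca
    }
    X <- ca$X2
    if (keepAttention) attns[[l]] <- ca$attn
  }
  if (identical(cfg$pooling, "mean")) {
    maskv <- as.vector(t(mask))
    grp <- rep(seq_len(B), each = T)
    cnt <- rowsum(maskv, grp)
    pooled <- rowsum(X * maskv, grp) / as.vector(cnt)
  } else {
    pooled <- X[(seq_len(B) - 1L) * T + 1L, , drop = FALSE]  # CLS rows
  }
  list(X = X, pooled = pooled, caches = caches, attn = attns,
       flat = flat, B = B, T = T, maskv = as.vector(t(mask)))
}

## dPooled: B x d gradient at the pooled CLS vectors.  Returns the parameter
## gradient tree, plus dS, the gradient at the embedding-lookup output
## (the quantity FGM normalizes).
.encBackward <- function(enc, fwd, cfg, dPooled) {
  B <- fwd$B; T <- fwd$T; d <- cfg$modelDim
  dX <- matrix(0, B * T, d)
  if (identical(cfg$pooling, "mean")) {
    grp <- rep(seq_len(B), each = T)
    cnt <- as.vector(rowsum(fwd$maskv, grp))
    dX <- (dPooled / cnt)[grp, , drop = FALSE] * fwd$maskv
  } else {
    dX[(seq_len(B) - 1L) * T + 1L, ] <- dPooled
  }
  gl <- vector("list", cfg$numLayers)

  for (l in rev(seq_len(cfg$numLayers))) {
    ca <- fwd$caches[[l]]
    bk <- .encLayerBackwardCpp(dX, ca$Xin, enc$layers[[l]], ca, B, T,
                               cfg$numHeads, cfg$headDim, ca$dm1, ca$dm2)
    gl[[l]] <- list(
      Wq = bk$Wq, bq = as.numeric(bk$bq),
      Wk = bk$Wk, bk = as.numeric(bk$bk),
      Wv = bk$Wv, bv = as.numeric(bk$bv),
      Wo = bk$Wo, bo = as.numeric(bk$bo),
      g1 = as.numeric(bk$g1), b1 = as.numeric(bk$b1),
      W1 = bk$W1, bf1 = as.numeric(bk$bf1),
      W2 = bk$W2, bf2 = as.numeric(bk$bf2),
      g2 = as.numeric(bk$g2), b2 = as.numeric(bk$b2))
    dX <- bk$dXin
  }
  ## dX is now the gradient at X0 = S + P; split into embedding tables
  dE <- matrix(0, nrow(enc$E), d)
  agg <- rowsum(dX, group = fwd$flat)
  dE[as.integer(rownames(agg)), ] <- agg
  dP <- matrix(0, nrow(enc$P), d)
  aggP <- rowsum(dX, group = rep(seq_len(T), B))
  dP[seq_len(T), ] <- aggP
  list(grads = list(E = dE, P = dP, layers = gl), dS = dX)
}

#' Encode a tokenized sequence
#'
#' Embeds token ids (token table plus learned absolute positional
#' embeddings), applies the configured number of post-norm transformer layers
#' (multi-head attention, residual + layer norm, feed-forward,
#' residual + layer norm), and pools the final-layer CLS row.
#'
#' @param tok a [TokenizedSequence] (or an integer vector of 0-based ids with
#'   an all-ones mask).
#' @param params encoder parameter list (e.g. `modelParams(model)$enc1` or
#'   from the internal initializer).
#' @param config an [encoderConfig()].
#' @param keepAttention retain per-layer attention maps
#'   (array T x T x heads per layer).
#' @return list with `states` (tokens x d_m matrix), `pooled` (length-d_m CLS
#'   vector) and, if requested, `attention`.
#' @export
encodeSequences <- function(tok, params, config, keepAttention = FALSE) {
  if (methods::is(tok, "TokenizedSequence")) {
    ids <- matrix(tok@ids, 1L); mask <- matrix(tok@mask, 1L)
  } else {
    ids <- matrix(as.integer(tok), 1L); mask <- matrix(1L, 1L, length(tok))
  }
  fwd <- .encForward(params, ids, mask, config,
                     keepAttention = keepAttention)
  out <- list(states = fwd$X, pooled = drop(fwd$pooled))
  if (keepAttention)
    out$attention <- lapply(fwd$attn, function(a) a)  # T x T x h per layer
  out
}
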