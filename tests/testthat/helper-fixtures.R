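# Shared fixtures: tiny architectures and seeded random sequences so every
# test builds its inputs in code.

tinyEncoderConfig <- function(numLayers = 1L, modelDim = 8L, numHeads = 2L,
                              ffDim = 12L, maxLen = 32L, dropout = 0) {
  # dropout off so finite-difference gradient checks see a deterministic loss
  encoderConfig(numLayers = numLayers, modelDim = modelDim,
                numHeads = numHeads, ffDim = ffDim, maxLen = maxLen,
                dropout = dropout)
}

tinyModel <- function(seqLen = 11L, seed = 7L, k1 = 2L, k2 = 3L,
                      headDropout = 0) {
  buildModel(seqLen = seqLen, k1 = k1, k2 = k2,
             encoder = tinyEncoderConfig(), headDropout = headDropout,
             seed = seed)
}

randomDNA <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# Brute-force single-head attention oracle: explicit double loop over query
# and key positions (kept independent of the package's linear-algebra path).
oracleSelfAttention <- function(X, Wq, Wk, Wv, mask = NULL) {
  n <- nrow(X); dk <- ncol(Wq)
  Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
  A <- matrix(0, n, n)
  out <- matrix(0, n, dk)
  for (i in seq_len(n)) {
    s <- numeric(n)
    for (j in seq_len(n)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
    if (!is.null(mask)) s[mask == 0] <- -Inf
    e <- exp(s - max(s))
    A[i, ] <- e / sum(e)
    for (j in seq_len(n)) out[i, ] <- out[i, ] + A[i, j] * V[j, ]
  }
  list(output = out, attention = A)
}

# Concordant-pair AUC oracle (ties count 1/2).
oracleAUC <- function(probs, labels) {
  pos <- probs[labels == 1]; neg <- probs[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
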