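test_that("self-attention matches the spec contract on degenerate cases", {
  set.seed(1)
  d <- 6; dk <- 3
  Wq <- matrix(rnorm(d * dk), d, dk)
  Wk <- matrix(rnorm(d * dk), d, dk)
  Wv <- matrix(rnorm(d * dk), d, dk)
  # single position: A = [[1]], output = the V row
  X1 <- matrix(rnorm(d), 1, d)
  r1 <- selfAttention(X1, Wq, Wk, Wv)
  expect_equal(r1$attention, matrix(1, 1, 1))
  expect_equal(r1$output, X1 %*% Wv)
  # zero queries: uniform attention, output = column means of V
  X <- matrix(rnorm(4 * d), 4, d)
  r2 <- selfAttention(X, Wq * 0, Wk, Wv)
  expect_equal(r2$attention, matrix(0.25, 4, 4))
  V <- X %*% Wv
  expect_equal(r2$output, matrix(colMeans(V), 4, dk, byrow = TRUE))
})

test_that("self-attention agrees with the double-loop oracle", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(2:6, 1); d <- 8; dk <- 4
    X <- matrix(rnorm(n * d), n, d)
    Wq <- matrix(rnorm(d * dk), d, dk)
    Wk <- matrix(rnorm(d * dk), d, dk)
    Wv <- matrix(rnorm(d * dk), d, dk)
    mask <- if (i %% 3 == 0 && n > 2) c(rep(1, n - 1), 0) else NULL
    got <- selfAttention(X, Wq, Wk, Wv, mask)
    want <- oracleSelfAttention(X, Wq, Wk, Wv, mask)
    expect_equal(got$output, want$output, tolerance = 1e-6)
    expect_equal(got$attention, want$attention, tolerance = 1e-6)
    # rows sum to 1; masked key column zero
    expect_equal(rowSums(got$attention), rep(1, n), tolerance = 1e-5)
    if (!is.null(mask)) expect_true(all(got$attention[, n] == 0))
    # convex-hull property per coordinate
    V <- X %*% Wv
    expect_true(all(got$output <= matrix(apply(V, 2, max), n, dk,
                                         byrow = TRUE) + 1e-9))
    expect_true(all(got$output >= matrix(apply(V, 2, min), n, dk,
                                         byrow = TRUE) - 1e-9))
  }
})

test_that("multi-head attention reduces correctly and matches its oracle", {
  set.seed(7)
  d <- 8; n <- 5
  X <- matrix(rnorm(n * d), n, d)
  # h = 1 with identity W_O equals single-head self-attention output
  hd <- list(Wq = matrix(rnorm(d * d), d, d),
             Wk = matrix(rnorm(d * d), d, d),
             Wv = matrix(rnorm(d * d), d, d))
  got1 <- multiHeadAttention(X, list(hd), diag(d))
  expect_equal(got1, selfAttention(X, hd$Wq, hd$Wk, hd$Wv)$output,
               tolerance = 1e-10)
  # duplicate heads: concatenation of h identical blocks times W_O
  dk <- 4
  hd2 <- list(Wq = matrix(rnorm(d * dk), d, dk),
              Wk = matrix(rnorm(d * dk), d, dk),
              Wv = matrix(rnorm(d * dk), d, dk))
  Wo <- matrix(rnorm(d * d), d, d)
  got2 <- multiHeadAttention(X, list(hd2, hd2), Wo)
  blk <- selfAttention(X, hd2$Wq, hd2$Wk, hd2$Wv)$output
  expect_equal(got2, cbind(blk, blk) %*% Wo, tolerance = 1e-10)
  # random instances vs sequential-head oracle
  for (i in 1:20) {
    heads <- lapply(1:2, function(j)
      list(Wq = matrix(rnorm(d * dk), d, dk),
           Wk = matrix(rnorm(d * dk), d, dk),
           Wv = matrix(rnorm(d * dk), d, dk)))
    Wo <- matrix(rnorm(d * d), d, d)
    want <- do.call(cbind, lapply(heads, function(hh)
      oracleSelfAttention(X, hh$Wq, hh$Wk, hh$Wv)$output)) %*% Wo
    expect_equal(multiHeadAttention(X, heads, Wo), want, tolerance = 1e-6)
  }
  expect_error(multiHeadAttention(X, list(hd2), diag(d)), "d_m")
})

test_that("encoder configuration enforces h * d_k = d_m and profiles", {
  desk <- encoderConfig("desk")
  expect_equal(desk$numLayers, 2L)
  expect_equal(desk$modelDim, 64L)
  expect_equal(desk$numHeads, 4L)
  full <- encoderConfig("full")
  expect_equal(c(full$numLayers, full$modelDim, full$numHeads),
               c(12L, 768L, 12L))
  expect_equal(full$headDim * full$numHeads, full$modelDim)
  expect_error(encoderConfig(numHeads = 5, modelDim = 64), "divide")
})

test_that("encode pools CLS, ignores padding, and is deterministic", {
  cfg <- tinyEncoderConfig()
  v <- buildVocabulary(2)
  set.seed(3)
  enc <- methFusion:::.initEncoder(cfg, vocabSize(v))
  s <- "ACGTACGTAAC"
  tk <- tokenize(s, v)
  r1 <- encodeSequences(tk, enc, cfg)
  # appending PAD leaves pooled output unchanged
  tkPad <- tokenize(s, v, maxLen = length(tk@ids) + 4L)
  r2 <- encodeSequences(tkPad, enc, cfg)
  expect_equal(r1$pooled, r2$pooled, tolerance = 1e-10)
  # bitwise determinism across runs
  r3 <- encodeSequences(tk, enc, cfg)
  expect_identical(r1$pooled, r3$pooled)
  # zero layers: pooled equals the embedded CLS row (token + position)
  cfg0 <- tinyEncoderConfig(numLayers = 0L)
  enc0 <- methFusion:::.initEncoder(cfg0, vocabSize(v))
  r0 <- encodeSequences(tk, enc0, cfg0)
  expect_equal(r0$pooled, enc0$E[tk@ids[1] + 1L, ] + enc0$P[1, ])
  # out-of-range token id
  bad <- tk; bad@ids[2] <- 10000L
  expect_error(encodeSequences(bad, enc, cfg), "vocabulary range")
})

test_that("attention maps from encode are row-stochastic", {
  cfg <- tinyEncoderConfig(numLayers = 2L)
  v <- buildVocabulary(3)
  set.seed(5)
  enc <- methFusion:::.initEncoder(cfg, vocabSize(v))
  tk <- tokenize(randomDNA(1, 15, seed = 8), v)
  r <- encodeSequences(tk, enc, cfg, keepAttention = TRUE)
  expect_length(r$attention, 2L)
  for (a in r$attention) {
    for (h in seq_len(dim(a)[3]))
      expect_equal(rowSums(a[, , h]), rep(1, nrow(a[, , h])),
                   tolerance = 1e-5)
  }
})

test_that("token order information enters only through position embeddings", {
  # with positional embeddings zeroed, permuting the two non-CLS tokens
  # leaves the pooled vector unchanged
  cfg <- tinyEncoderConfig(numLayers = 1L)
  v <- buildVocabulary(1)
  set.seed(11)
  enc <- methFusion:::.initEncoder(cfg, vocabSize(v))
  enc$P[] <- 0
  idsA <- c(2L, tokenId(v, c("A", "C", "G")), 3L)
  idsB <- c(2L, tokenId(v, c("G", "A", "C")), 3L)
  rA <- encodeSequences(idsA, enc, cfg)
  rB <- encodeSequences(idsB, enc, cfg)
  expect_equal(rA$pooled, rB$pooled, tolerance = 1e-10)
})

test_that("model gradients match finite differences on a tiny instance", {
  m <- tinyModel(seed = 7)
  seqs <- randomDNA(3, 11, seed = 21)
  y <- c(1, 0, 1)
  tok <- methFusion:::.modelTokens(m, seqs)
  fwd <- methFusion:::.modelForward(m, tok, training = TRUE)
  bwd <- methFusion:::.modelBackward(m, fwd, (fwd$p - y) / 3)
  flat <- methFusion:::.flattenParams(m@params)
  gflat <- methFusion:::.flattenParams(bwd$grads)
  eps <- 1e-5
  set.seed(12)
  for (nm in sample(names(flat), 25)) {
    ii <- sample(length(flat[[nm]]), 1)
    f2 <- flat
    f2[[nm]][ii] <- f2[[nm]][ii] + eps
    m2 <- m; m2@params <- methFusion:::.unflattenParams(f2, m@params)
    lp <- crossEntropyLoss(methFusion:::.modelForward(m2, tok)$p, y)
    f2[[nm]][ii] <- f2[[nm]][ii] - 2 * eps
    m2@params <- methFusion:::.unflattenParams(f2, m@params)
    lm_ <- crossEntropyLoss(methFusion:::.modelForward(m2, tok)$p, y)
    num <- (lp - lm_) / (2 * eps)
    expect_equal(unname(gflat[[nm]][ii]), num, tolerance = 1e-4,
                 label = sprintf("analytic gradient of %s", nm))
  }
})

test_that("checkpoints round-trip and mismatches are reported by name", {
  m <- tinyModel(seed = 3)
  path <- tempfile(fileext = ".rds")
  saveModel(m, path)
  m2 <- tinyModel(seed = 99)
  m3 <- loadPretrained(m2, path)
  expect_equal(m3@params, m@params)
  # wrong architecture: named load error
  mBig <- buildModel(seqLen = 11, k1 = 2, k2 = 3,
                     encoder = tinyEncoderConfig(modelDim = 16L),
                     seed = 1)
  expect_error(loadPretrained(mBig, path), "enc1")
  # partial load keeps fresh init for mismatched tensors, reports them
  expect_message(m4 <- loadPretrained(mBig, path, partial = TRUE),
                 "fresh initialization")
  expect_equal(dim(m4@params$enc1$layers[[1]]$Wq), c(16L, 16L))
})
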