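test_that("cross-entropy loss matches hand evaluations", {
  expect_equal(crossEntropyLoss(0.5, 1), log(2), tolerance = 1e-12)
  expect_equal(crossEntropyLoss(0.5, 0), log(2), tolerance = 1e-12)
  expect_equal(crossEntropyLoss(0.9, 1), -log(0.9), tolerance = 1e-12)
  expect_lt(crossEntropyLoss(1 - 1e-9, 1), 1e-6)   # p -> y: loss -> 0
  expect_lt(crossEntropyLoss(1e-9, 0), 1e-6)
  # clamping keeps the loss finite
  expect_true(is.finite(crossEntropyLoss(0, 1)))
  # batch version averages
  expect_equal(crossEntropyLoss(c(0.9, 0.5), c(1, 0)),
               mean(c(-log(0.9), log(2))), tolerance = 1e-12)
  expect_equal(crossEntropyLoss(c(0.9, 0.5), c(1, 0), reduce = FALSE),
               c(-log(0.9), log(2)), tolerance = 1e-12)
})

test_that("FGM perturbation has exact norm epsilon and handles edge cases", {
  r <- fgmPerturbation(c(3, 4), 1)
  expect_equal(r, c(0.6, 0.8), tolerance = 1e-15)
  expect_equal(fgmPerturbation(c(0, 0), 1), c(0, 0))
  expect_equal(fgmPerturbation(rep(1e-13, 4), 2), rep(0, 4))
  expect_error(fgmPerturbation(c(1, NA), 1), "finite")
  expect_error(fgmPerturbation(c(1, 2), -1))
  # norm contract over 100 seeded random gradients, matrix shapes included
  set.seed(101)
  for (i in 1:100) {
    g <- matrix(rnorm(24, sd = 10^runif(1, -4, 2)), 4, 6)
    r <- fgmPerturbation(g, 0.5)
    expect_equal(sqrt(sum(r^2)), 0.5, tolerance = 1e-9)
    expect_equal(dim(r), dim(g))
    # oriented along the gradient (loss-ascent direction)
    expect_gt(sum(r * g), 0)
  }
})

test_that("a zero-epsilon adversarial step equals a plain step bitwise", {
  m <- tinyModel(seed = 41)
  ds <- generateDataset(syntheticSpec(nPerClass = 16, seqLen = 11,
                                      motifStart = 2, jitter = 1, seed = 3))
  tok <- methFusion:::.datasetTokens(m, ds)
  y <- labels(ds)
  tc <- trainingConfig(seed = 1)
  run <- function(adv) {
    set.seed(99)
    st <- adversarialStep(m, tok, y, NULL, tc, adv)
    st
  }
  a <- run(adversarialConfig(epsilon = 0))
  b <- run(adversarialConfig(enabled = FALSE))
  expect_identical(a$model@params, b$model@params)
  expect_identical(a$cleanLoss, b$cleanLoss)
  expect_identical(a$advLoss, a$cleanLoss)
  # and the step is reproducible bitwise across runs
  c2 <- run(adversarialConfig(epsilon = 0))
  expect_identical(a$model@params, c2$model@params)
})

test_that("small-epsilon FGM perturbations increase the loss", {
  # first-order ascent property, checked empirically over seeded batches
  m <- tinyModel(seed = 17)
  worse <- 0; total <- 40
  set.seed(7)
  for (i in seq_len(total)) {
    seqs <- randomDNA(8, 11)
    y <- rbinom(8, 1, 0.5)
    tok <- methFusion:::.modelTokens(m, seqs)
    fwd <- methFusion:::.modelForward(m, tok, training = TRUE)
    clean <- crossEntropyLoss(fwd$p, y)
    bwd <- methFusion:::.modelBackward(m, fwd, (fwd$p - y) / 8)
    r1 <- fgmPerturbation(bwd$dS1, 0.05)
    r2 <- fgmPerturbation(bwd$dS2, 0.05)
    adv <- crossEntropyLoss(
      methFusion:::.modelForward(m, tok, perturb1 = r1, perturb2 = r2)$p, y)
    if (adv >= clean - 1e-6) worse <- worse + 1
  }
  expect_gte(worse / total, 0.9)
})

test_that("training is seeded-reproducible and the history is well-formed", {
  ds <- generateDataset(syntheticSpec(nPerClass = 24, seqLen = 11,
                                      motifStart = 2, jitter = 1, seed = 5))
  sp <- stratifiedSplit(ds, c(train = .75, validation = .25, test = 0),
                        seed = 2)
  m <- tinyModel(seed = 6)
  tc <- trainingConfig(epochs = 3, patience = 5, batchSize = 8, seed = 11)
  f1 <- trainModel(m, ds[sp$train], ds[sp$validation], tc)
  f2 <- trainModel(m, ds[sp$train], ds[sp$validation], tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model@params, f2$model@params)
  expect_equal(nrow(f1$history), 3L)
  expect_named(f1$history, c("epoch", "trainLoss", "advLoss", "valLoss",
                             "valACC", "valMCC", "valAUC"))
  expect_error(trainModel(m, ds[integer(0)], ds[sp$validation], tc),
               "empty")
})

test_that("patience zero stops after the first non-improving epoch", {
  ds <- generateDataset(syntheticSpec(nPerClass = 16, seqLen = 11,
                                      motifStart = 2, jitter = 1, seed = 8))
  sp <- stratifiedSplit(ds, c(train = .75, validation = .25, test = 0),
                        seed = 1)
  m <- tinyModel(seed = 2)
  # lr 0 never improves the metric: epoch 1 sets the incumbent, epoch 2 is
  # the first non-improving epoch, then the loop must stop
  tc <- trainingConfig(epochs = 10, patience = 0, batchSize = 8,
                       lr = 1e-12, seed = 3)
  fit <- trainModel(m, ds[sp$train], ds[sp$validation], tc)
  expect_equal(nrow(fit$history), 2L)
})

test_that("training on a separable toy task overfits to perfect accuracy", {
  # positives all carry a fixed one-hot motif, negatives none
  onehot <- (defaultMotifPWM("GCGCGC", 1) >= 1) * 1
  ds <- generateDataset(syntheticSpec(nPerClass = 100, seqLen = 11,
                                      motif = onehot, motifStart = 2,
                                      jitter = 0, seed = 4))
  m <- buildModel(seqLen = 11, k1 = 2, k2 = 3,
                  encoder = tinyEncoderConfig(numLayers = 1L,
                                              modelDim = 16L, ffDim = 32L),
                  headDropout = 0, seed = 10)
  tc <- trainingConfig(epochs = 30, patience = 30, batchSize = 25, seed = 5)
  fit <- trainModel(m, ds, ds, tc, adversarialConfig(enabled = FALSE))
  trainAcc <- max(fit$history$valACC)   # evaluated on the training data
  expect_equal(trainAcc, 1.0)
})

test_that("zero-epoch fine-tuning returns identical parameters", {
  m <- tinyModel(seed = 13)
  ds <- generateDataset(syntheticSpec(nPerClass = 8, seqLen = 11,
                                      motifStart = 2, jitter = 1, seed = 1))
  out <- fineTune(m, ds, ds, trainingConfig(epochs = 0))
  expect_identical(out$model@params, m@params)
})

test_that("history serializes as CSV", {
  h <- data.frame(epoch = 1:2, trainLoss = c(.7, .6), advLoss = c(.7, .61),
                  valLoss = c(.69, .6), valACC = c(.5, .7),
                  valMCC = c(0, .4), valAUC = c(.5, .8))
  path <- tempfile(fileext = ".csv")
  writeHistory(h, path)
  expect_equal(utils::read.csv(path), h, tolerance = 1e-12)
})
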