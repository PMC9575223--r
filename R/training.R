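## Training loop with FGM adversarial perturbation of the token-embedding
## output, manual AdamW, early stopping on a validation metric, and
## fine-tuning for transfer between methylation contexts.

#' Binary cross-entropy loss
#'
#' L_CE(p, y) = -y log p - (1 - y) log(1 - p), with p clamped to
#' \[1e-7, 1 - 1e-7\].  Vector inputs give the batch mean.
#'
#' @param p predicted probabilities.
#' @param y true labels in \{0, 1\}.
#' @param reduce return the mean over the batch (default TRUE).
#' @return nonnegative loss value(s).
#' @export
crossEntropyLoss <- function(p, y, reduce = TRUE) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  l <- -y * log(p) - (1 - y) * log(1 - p)
  if (reduce) mean(l) else l
}

#' FGM perturbation
#'
#' Normalizes the loss gradient at the embedding output to L2 norm epsilon:
#' r_adv = epsilon * g / ||g||_2, the one-step worst-case (loss-increasing)
#' perturbation direction.  A vanishing gradient (||g||_2 < 1e-12) yields a
#' zero perturbation.
#'
#' @param g gradient array (any shape) of the loss w.r.t. the embedding
#'   output.
#' @param epsilon nonnegative perturbation norm.
#' @return an array of the same shape with ||r_adv||_2 = epsilon (or all
#'   zeros for a vanishing gradient).
#' @export
fgmPerturbation <- function(g, epsilon) {
  stopifnot(epsilon >= 0)
  if (any(!is.finite(g))) stop("non-finite gradient in FGM perturbation")
  nrm <- sqrt(sum(g * g))
  if (nrm < 1e-12) return(g * 0)
  g * (epsilon / nrm)
}

#' Training configuration
#'
#' @param batchSize minibatch size (default 32).
#' @param epochs maximum epochs (default 30).
#' @param lr learning rate (default 1e-3, tuned to the desk encoder profile;
#'   use ~2e-5 with the full profile).
#' @param optimizer `"adamw"`, `"adam"`, or `"sgd"`.
#' @param weightDecay decoupled weight decay on matrix-shaped parameters
#'   (AdamW only; default 0.01).
#' @param clipNorm global gradient-norm clip (default 1); `Inf` disables.
#' @param warmupSteps linear learning-rate warmup over the first steps
#'   (default 20), the usual stabilizer for post-norm transformer stacks.
#' @param patience early-stopping patience in epochs (default 5); stopping is
#'   on the validation metric.
#' @param metric validation metric for early stopping: `"mcc"` (default),
#'   `"auc"`, `"acc"`, or `"loss"`.
#' @param seed seed fixing all stochastic choices of the run.
#' @return named list of class `"trainingConfig"`.
#' @export
trainingConfig <- function(batchSize = 32L, epochs = 30L, lr = 1e-3,
                           optimizer = c("adamw", "adam", "sgd"),
                           weightDecay = 0.01, clipNorm = 1,
                           warmupSteps = 20L, patience = 5L,
                           metric = c("mcc", "auc", "acc", "loss"),
                           seed = 1L) {
  stopifnot(batchSize >= 1L, epochs >= 0L, lr > 0, patience >= 0L,
            clipNorm > 0, warmupSteps >= 0L)
  structure(list(batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), lr = lr,
                 optimizer = match.arg(optimizer),
                 weightDecay = weightDecay, clipNorm = clipNorm,
                 warmupSteps = as.integer(warmupSteps),
                 patience = as.integer(patience),
                 metric = match.arg(metric), seed = as.integer(seed)),
            class = "trainingConfig")
}

#' Adversarial-training configuration
#'
#' With `epsilon = 0` (or `enabled = FALSE`) the training loop is exactly the
#' plain loop -- no extra forward/backward passes, identical RNG stream.
#'
#' @param epsilon FGM perturbation norm (default 1).
#' @param enabled switch (default TRUE).
#' @param mode `"both"` optimizes clean + adversarial cross-entropy;
#'   `"adversarial-only"` optimizes only the perturbed-batch loss.
#' @return named list of class `"adversarialConfig"`.
#' @export
adversarialConfig <- function(epsilon = 1, enabled = TRUE,
                              mode = c("both", "adversarial-only")) {
  stopifnot(epsilon >= 0)
  structure(list(epsilon = epsilon, enabled = isTRUE(enabled),
                 mode = match.arg(mode)),
            class = "adversarialConfig")
}

## ---- parameter-tree arithmetic ------------------------------------------

.treeMap2 <- function(f, a, b) {
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- .treeMap2(f, a[[i]], b[[i]])
    a
  } else f(a, b)
}

.treeZero <- function(a) {
  if (is.list(a)) lapply(a, .treeZero) else a * 0
}

## AdamW step over flattened parameter/gradient lists (one compiled pass per
## tensor).  Decay applies to matrix-shaped leaves only (embeddings,
## projections), never to biases or layer-norm parameters, the usual
## convention.
.optimStep <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  lr <- cfg$lr
  if (!is.null(cfg$warmupSteps) && cfg$warmupSteps > 0L &&
      state$t <= cfg$warmupSteps)
    lr <- lr * state$t / cfg$warmupSteps
  flatP <- .flattenParams(params)
  flatG <- .flattenParams(grads)
  clip <- cfg$clipNorm %||% Inf
  if (is.finite(clip)) {
    gn <- sqrt(sum(vapply(flatG, function(g) sum(g * g), numeric(1))))
    if (gn > clip)
      flatG <- lapply(flatG, function(g) g * (clip / gn))
  }
  if (cfg$optimizer == "sgd") {
    for (nm in names(flatP)) flatP[[nm]] <- flatP[[nm]] - lr * flatG[[nm]]
    return(list(params = .unflattenParams(flatP, params), state = state))
  }
  wdAll <- if (cfg$optimizer == "adamw") cfg$weightDecay else 0
  for (nm in names(flatP)) {
    wd <- if (is.matrix(flatP[[nm]])) wdAll else 0
    res <- .adamLeafCpp(flatP[[nm]], flatG[[nm]], state$m[[nm]],
                        state$v[[nm]], state$t, lr, wd, 0.9, 0.999, 1e-8)
    flatP[[nm]] <- res$p
    state$m[[nm]] <- res$m
    state$v[[nm]] <- res$v
  }
  list(params = .unflattenParams(flatP, params), state = state)
}

.initOptimState <- function(params) {
  flat <- .flattenParams(params)
  list(t = 0L, m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0))
}

## ---- one adversarial step ------------------------------------------------

#' One training step with FGM adversarial perturbation
#'
#' Runs the clean forward/backward pass, builds the FGM perturbation from the
#' gradient at each scale's token-embedding output (the model parameters are
#' held constant during this construction -- no gradient flows through it),
#' re-runs the forward pass on the perturbed embeddings, and applies one
#' optimizer update on the summed clean + adversarial cross-entropy (or the
#' adversarial loss alone in `"adversarial-only"` mode).  With epsilon 0 the
#' adversarial passes are skipped entirely and the step is a plain step.
#'
#' @param model a [MethFusionModel].
#' @param tokens pre-tokenized batch (as from the internal tokenizer): list
#'   with `ids1`, `mask1`, `ids2`, `mask2`.
#' @param y labels in \{0, 1\} for the batch.
#' @param optState optimizer state from a previous step, or NULL.
#' @param training a [trainingConfig()].
#' @param adversarial an [adversarialConfig()].
#' @return list with `model`, `optState`, `cleanLoss`, `advLoss`.
#' @export
adversarialStep <- function(model, tokens, y, optState = NULL,
                            training = trainingConfig(),
                            adversarial = adversarialConfig()) {
  if (is.null(optState)) optState <- .initOptimState(model@params)
  B <- nrow(tokens$ids1)
  fwd <- .modelForward(model, tokens, training = TRUE)
  cleanLoss <- crossEntropyLoss(fwd$p, y)
  dLogit <- (fwd$p - y) / B
  bwd <- .modelBackward(model, fwd, dLogit)

  doAdv <- adversarial$enabled && adversarial$epsilon > 0
  if (doAdv) {
    r1 <- fgmPerturbation(bwd$dS1, adversarial$epsilon)
    r2 <- fgmPerturbation(bwd$dS2, adversarial$epsilon)
    fwdA <- .modelForward(model, tokens, perturb1 = r1, perturb2 = r2,
                          training = TRUE)
    advLoss <- crossEntropyLoss(fwdA$p, y)
    bwdA <- .modelBackward(model, fwdA, (fwdA$p - y) / B)
    grads <- if (adversarial$mode == "adversarial-only") bwdA$grads
    else .treeMap2(`+`, bwd$grads, bwdA$grads)
  } else {
    advLoss <- cleanLoss
    grads <- bwd$grads
  }
  st <- .optimStep(model@params, grads, optState, training)
  model@params <- st$params
  list(model = model, optState = st$state,
       cleanLoss = cleanLoss, advLoss = advLoss)
}

## ---- training loop -------------------------------------------------------

.datasetTokens <- function(model, ds) {
  .modelTokens(model, as.character(sequences(ds)))
}

.sliceTokens <- function(tokens, idx) {
  list(ids1 = tokens$ids1[idx, , drop = FALSE],
       mask1 = tokens$mask1[idx, , drop = FALSE],
       ids2 = tokens$ids2[idx, , drop = FALSE],
       mask2 = tokens$mask2[idx, , drop = FALSE])
}

.predictTokens <- function(model, tokens, batchSize = 128L) {
  n <- nrow(tokens$ids1)
  p <- numeric(n)
  for (lo in seq(1L, n, by = batchSize)) {
    hi <- min(lo + batchSize - 1L, n)
    p[lo:hi] <- .modelForward(model, .sliceTokens(tokens, lo:hi))$p
  }
  p
}

.valMetric <- function(metric, probs, y, loss, threshold) {
  switch(metric,
    loss = -loss,
    auc = rocPrCurves(probs, y)$auc,
    {
      m <- computeMetrics(confusionCounts(probs, y, threshold))
      if (metric == "mcc") m["MCC"] else m["ACC"]
    })
}

#' Train the dual-scale model
#'
#' Seeded minibatch loop over the training set, one [adversarialStep()] per
#' batch, validation after every epoch, and early stopping on the configured
#' validation metric (patience in epochs).  Returns the parameters of the
#' best-validation epoch together with the full per-epoch history.
#'
#' @param model a [MethFusionModel] (fresh from [buildModel()] or pretrained).
#' @param trainSet,valSet disjoint [MethDataSet]s.
#' @param training a [trainingConfig()].
#' @param adversarial an [adversarialConfig()].
#' @param verbose print per-epoch progress.
#' @return list with `model` (best checkpoint) and `history`, a data.frame
#'   with per-epoch train loss, adversarial loss, validation loss and
#'   validation ACC/MCC/AUC.
#' @export
trainModel <- function(model, trainSet, valSet,
                       training = trainingConfig(),
                       adversarial = adversarialConfig(),
                       verbose = FALSE) {
  if (length(trainSet) == 0L || length(valSet) == 0L)
    stop("empty training or validation set")
  set.seed(training$seed)
  trTok <- .datasetTokens(model, trainSet)
  vaTok <- .datasetTokens(model, valSet)
  yTr <- labels(trainSet); yVa <- labels(valSet)
  n <- length(yTr)
  optState <- NULL
  best <- list(metric = -Inf, params = model@params, epoch = 0L)
  bad <- 0L
  hist <- data.frame(epoch = integer(), trainLoss = numeric(),
                     advLoss = numeric(), valLoss = numeric(),
                     valACC = numeric(), valMCC = numeric(),
                     valAUC = numeric())
  for (ep in seq_len(training$epochs)) {
    ord <- sample.int(n)
    losses <- advLosses <- numeric()
    for (lo in seq(1L, n, by = training$batchSize)) {
      idx <- ord[lo:min(lo + training$batchSize - 1L, n)]
      st <- adversarialStep(model, .sliceTokens(trTok, idx), yTr[idx],
                            optState, training, adversarial)
      model <- st$model; optState <- st$optState
      losses <- c(losses, st$cleanLoss)
      advLosses <- c(advLosses, st$advLoss)
    }
    pVa <- .predictTokens(model, vaTok)
    valLoss <- crossEntropyLoss(pVa, yVa)
    cm <- computeMetrics(confusionCounts(pVa, yVa, model@config$threshold))
    auc <- rocPrCurves(pVa, yVa)$auc
    hist <- rbind(hist, data.frame(
      epoch = ep, trainLoss = mean(losses), advLoss = mean(advLosses),
      valLoss = valLoss, valACC = unname(cm["ACC"]),
      valMCC = unname(cm["MCC"]), valAUC = auc))
    metric <- .valMetric(training$metric, pVa, yVa, valLoss,
                         model@config$threshold)
    if (verbose)
      message(sprintf(
        "epoch %d: train %.4f adv %.4f | val loss %.4f ACC %.3f MCC %.3f AUC %.3f",
        ep, mean(losses), mean(advLosses), valLoss, cm["ACC"], cm["MCC"], auc))
    if (metric > best$metric) {
      best <- list(metric = metric, params = model@params, epoch = ep)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad > training$patience) break
    }
  }
  model@params <- best$params
  list(model = model, history = hist, bestEpoch = best$epoch)
}

#' Fine-tune a pretrained model on a new task
#'
#' All parameters start from the source model; training then proceeds on the
#' target data exactly as in [trainModel()].  Zero epochs returns the model
#' unchanged.  This is the transfer-learning route: pretrain on the abundant
#' context (e.g. CpG) and fine-tune on the scarce one (CHG or CHH).
#'
#' @inheritParams trainModel
#' @return list with `model` and `history` (as [trainModel()]).
#' @export
fineTune <- function(model, trainSet, valSet,
                     training = trainingConfig(),
                     adversarial = adversarialConfig(),
                     verbose = FALSE) {
  if (training$epochs == 0L)
    return(list(model = model,
                history = data.frame(), bestEpoch = 0L))
  trainModel(model, trainSet, valSet, training, adversarial, verbose)
}

#' Write a training history as CSV
#' @param history data.frame from [trainModel()].
#' @param path output path.
#' @export
writeHistory <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
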