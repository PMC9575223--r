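## Threshold metrics (ACC, MCC, SN, SP), ROC/PR curves with AUC/AP, and
## cross-condition evaluation grids.

#' Confusion counts at a threshold
#'
#' Prediction is 1 iff probability >= threshold.
#'
#' @param probs predicted probabilities.
#' @param labels true labels in \{0, 1\}.
#' @param threshold decision threshold (default 0.5).
#' @return named integer vector with `TP`, `FN`, `TN`, `FP`.
#' @export
confusionCounts <- function(probs, labels, threshold = 0.5) {
  if (length(probs) != length(labels))
    stop("probs and labels must have equal length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  pred <- as.integer(probs >= threshold)
  c(TP = sum(pred == 1L & labels == 1),
    FN = sum(pred == 0L & labels == 1),
    TN = sum(pred == 0L & labels == 0),
    FP = sum(pred == 1L & labels == 0))
}

#' Threshold classification metrics
#'
#' ACC = (TP + TN) / (TP + FN + TN + FP);
#' MCC = (TP * TN - FP * FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)),
#' defined as 0 when any factor of the denominator is zero (the usual
#' convention for degenerate confusion tables);
#' SN = TP / (TP + FN); SP = TN / (TN + FP).  An undefined SN or SP
#' (empty class) is reported as NaN with a warning.
#'
#' @param counts named vector from [confusionCounts()].
#' @return named numeric vector `ACC`, `MCC`, `SN`, `SP`.
#' @export
computeMetrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); fn <- as.numeric(counts[["FN"]])
  tn <- as.numeric(counts[["TN"]]); fp <- as.numeric(counts[["FP"]])
  n <- tp + fn + tn + fp
  if (n == 0) stop("all confusion counts are zero")
  acc <- (tp + tn) / n
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
  sn <- if (tp + fn == 0) { warning("SN undefined: no positives"); NaN }
  else tp / (tp + fn)
  sp <- if (tn + fp == 0) { warning("SP undefined: no negatives"); NaN }
  else tn / (tn + fp)
  c(ACC = acc, MCC = mcc, SN = sn, SP = sp)
}

#' ROC and PR curves with AUC and AP
#'
#' Sweeps the decision threshold over the unique scores (ties grouped, so
#' equal scores move together), builds the ROC curve (AUC by the trapezoid
#' rule -- equivalently the concordant-pair fraction with ties counted 1/2)
#' and the PR curve with step-interpolated average precision
#' (AP = sum over recall increments of precision at that point).
#'
#' @param probs predicted scores.
#' @param labels true labels in \{0, 1\}; both classes must be present.
#' @return list with `roc` (data.frame fpr, tpr), `auc`, `pr` (data.frame
#'   recall, precision), `ap`.
#' @export
rocPrCurves <- function(probs, labels) {
  if (length(probs) != length(labels))
    stop("probs and labels must have equal length")
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0 || N == 0) stop("both classes must be present")
  ord <- order(probs, decreasing = TRUE)
  y <- labels[ord]; s <- probs[ord]
  grp <- cumsum(!duplicated(s))           # tie groups in descending order
  tpCum <- cumsum(y == 1); fpCum <- cumsum(y == 0)
  last <- which(diff(c(grp, Inf)) != 0)    # last index of each tie group
  tp <- tpCum[last]; fp <- fpCum[last]
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  recall <- tp / P
  precision <- tp / (tp + fp)
  ap <- sum(diff(c(0, recall)) * precision)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc,
       pr = data.frame(recall = recall, precision = precision), ap = ap)
}

#' Evaluate a model on a labeled dataset
#'
#' @param model a [MethFusionModel].
#' @param dataset a [MethDataSet].
#' @param threshold decision threshold (default: the model's).
#' @return named numeric vector `ACC`, `MCC`, `SN`, `SP`, `AUC`, `AP`.
#' @export
evaluateModel <- function(model, dataset, threshold = NULL) {
  threshold <- threshold %||% model@config$threshold
  pred <- predict(model, dataset)
  y <- labels(dataset)
  m <- computeMetrics(confusionCounts(pred$probability, y, threshold))
  rp <- rocPrCurves(pred$probability, y)
  c(m, AUC = rp$auc, AP = rp$ap)
}

#' Cross-condition evaluation grid
#'
#' Evaluates every model (trained on condition A, B, ...) on every test set;
#' the train-on-row / test-on-column layout of cross-species and
#' cross-cell-line validation heatmaps.
#'
#' @param models named list of [MethFusionModel]s (names = training
#'   conditions).
#' @param testSets named list of [MethDataSet]s (names = test conditions);
#'   all must match the models' input length.
#' @return long-format data.frame with columns `train`, `test`, and one
#'   column per metric; the ACC matrix is attached as attribute `"ACC"`.
#' @export
crossGrid <- function(models, testSets) {
  rows <- list()
  for (tr in names(models)) {
    for (te in names(testSets)) {
      sl <- unique(Biostrings::width(sequences(testSets[[te]])))
      if (length(sl) != 1L || sl != models[[tr]]@config$seqLen)
        stop(sprintf("length contract violation for pair (%s -> %s)", tr, te))
      m <- evaluateModel(models[[tr]], testSets[[te]])
      rows[[paste(tr, te)]] <- data.frame(train = tr, test = te, t(m))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  accMat <- matrix(out$ACC, nrow = length(models), byrow = TRUE,
                   dimnames = list(names(models), names(testSets)))
  attr(out, "ACC") <- accMat
  out
}

#' Read or write a cross-grid as CSV
#' @param grid data.frame from [crossGrid()].
#' @param path file path.
#' @export
writeGrid <- function(grid, path) {
  utils::write.csv(grid, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGrid
#' @export
readGrid <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a metrics report as TSV
#' @param metrics named numeric vector (e.g. from [evaluateModel()]).
#' @param path output path.
#' @export
writeMetrics <- function(metrics, path) {
  utils::write.table(data.frame(metric = names(metrics),
                                value = unname(metrics)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
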