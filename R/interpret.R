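## Attention-based interpretation: attention maps -> per-token scores ->
## per-base importance tracks -> motif windows -> PWMs -> MEME export.

#' Reduce attention maps to per-token scores
#'
#' Takes the retained attention maps of one sequence at one scale (a list of
#' per-layer `T x T x heads` arrays) and reduces them to one score per token
#' position.  The default policy uses the last layer, averages heads, and
#' reads the CLS row -- how much the pooled classification token attends to
#' each position.  Alternatives: `"colmean"` (mean attention received by each
#' position from all queries) and `"diag"` (attention mass each query places
#' within a +/- `bandwidth` diagonal band, a measure of local focus).
#'
#' @param maps list of per-layer attention arrays (`T x T x h`), e.g.
#'   `attr(pred, "attention")[[i]]$scale1` after
#'   `predict(..., keepAttention = TRUE)`.
#' @param policy `"cls"`, `"colmean"`, or `"diag"`.
#' @param layer layer index, or `"last"` (default).
#' @param bandwidth band half-width for the `"diag"` policy (default 1).
#' @return numeric vector of length T (all token positions, specials
#'   included).
#' @export
attentionTokenScores <- function(maps, policy = c("cls", "colmean", "diag"),
                                 layer = "last", bandwidth = 1L) {
  if (is.null(maps) || !length(maps))
    stop("no attention maps present; run the forward pass with keepAttention")
  policy <- match.arg(policy)
  l <- if (identical(layer, "last")) length(maps) else as.integer(layer)
  a <- maps[[l]]                         # T x T x h
  M <- apply(a, c(1L, 2L), mean)         # head mean
  T <- nrow(M)
  switch(policy,
    cls = M[1L, ],
    colmean = colMeans(M),
    diag = vapply(seq_len(T), function(j) {
      lo <- max(1L, j - bandwidth); hi <- min(T, j + bandwidth)
      sum(M[j, lo:hi])
    }, numeric(1)))
}

#' Map token scores to per-base importance
#'
#' Each base's raw score is the mean score of every k-mer token covering it;
#' the track is then min-max normalized to \[0, 1\] (a constant track becomes
#' all zeros).
#'
#' @param tokenScores per-token scores (from [attentionTokenScores()]).
#' @param spans the token span matrix of the [TokenizedSequence] (special
#'   tokens have NA spans and are ignored).
#' @param seqLen sequence length in bases.
#' @return numeric vector of length `seqLen` in \[0, 1\].
#' @export
tokenToPositionScores <- function(tokenScores, spans, seqLen) {
  if (length(tokenScores) != nrow(spans))
    stop("token scores and spans disagree in length")
  raw <- numeric(seqLen); cov <- numeric(seqLen)
  for (i in seq_along(tokenScores)) {
    s <- spans[i, 1L]
    if (is.na(s)) next
    e <- spans[i, 2L]
    if (e > seqLen) stop("token span exceeds sequence length")
    idx <- (s + 1L):e
    raw[idx] <- raw[idx] + tokenScores[i]
    cov[idx] <- cov[idx] + 1
  }
  raw[cov > 0] <- raw[cov > 0] / cov[cov > 0]
  rng <- range(raw)
  if (diff(rng) < 1e-15) return(numeric(seqLen))
  (raw - rng[1L]) / diff(rng)
}

#' Per-base importance tracks for a set of sequences
#'
#' Convenience wrapper: runs the model forward with attention retained and
#' returns the normalized per-base importance of every sequence at the chosen
#' scale.
#'
#' @param model a [MethFusionModel].
#' @param seqs character vector / [Biostrings::DNAStringSet] / [MethDataSet]
#'   of model-length sequences.
#' @param scale 1 (k1-mer branch) or 2 (k2-mer branch).
#' @param policy,layer passed to [attentionTokenScores()].
#' @return numeric matrix, sequences x positions, each row in \[0, 1\].
#' @export
positionImportance <- function(model, seqs, scale = 1L,
                               policy = "cls", layer = "last") {
  pred <- predict(model, seqs, keepAttention = TRUE)
  attn <- attr(pred, "attention")
  L <- model@config$seqLen
  out <- matrix(0, length(attn), L)
  for (i in seq_along(attn)) {
    a <- attn[[i]]
    maps <- if (scale == 1L) a$scale1 else a$scale2
    spans <- if (scale == 1L) a$spans1 else a$spans2
    ts <- attentionTokenScores(maps, policy = policy, layer = layer)
    out[i, ] <- tokenToPositionScores(ts, spans, L)
  }
  rownames(out) <- pred$id
  out
}

#' Extract high-importance motif windows across sequences
#'
#' Per sequence, finds maximal runs of bases with importance >= `threshold`
#' and length >= `minWidth`; each run is anchored at its importance peak.
#' Runs are grouped by anchor position, the modal anchor is selected, and a
#' fixed-width window (`minWidth` bases, centered on each run's own peak so
#' peaks align) is extracted from every run whose anchor lies within
#' `tol` bases of the mode.  Returns that aligned subsequence set -- the
#' input for [buildPWM()].  No passing run is not an error: the result is
#' empty.
#'
#' @param importance matrix from [positionImportance()] (sequences x
#'   positions).
#' @param seqs the corresponding sequences (character vector or coercible).
#' @param threshold importance cutoff on the normalized track (default 0.6).
#' @param minWidth minimum run length and extracted window width (default 6).
#' @param tol anchor grouping tolerance in bases (default `minWidth %/% 2`).
#' @return character vector of aligned `minWidth`-wide subsequences, with the
#'   anchor positions (0-based) as attribute `"anchors"` and the modal anchor
#'   as attribute `"modalAnchor"`.
#' @export
extractMotifWindows <- function(importance, seqs, threshold = 0.6,
                                minWidth = 6L, tol = NULL) {
  seqs <- as.character(seqs)
  stopifnot(nrow(importance) == length(seqs))
  tol <- tol %||% (minWidth %/% 2L)
  L <- ncol(importance)
  anchors <- integer(); srcs <- integer()
  runs <- matrix(integer(), 0L, 2L)
  for (i in seq_len(nrow(importance))) {
    above <- importance[i, ] >= threshold
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= minWidth)) {
      run <- starts[j]:ends[j]
      peak <- run[which.max(importance[i, run])]
      anchors <- c(anchors, peak); srcs <- c(srcs, i)
      runs <- rbind(runs, c(starts[j], ends[j]))
    }
  }
  if (!length(anchors)) {
    message("extractMotifWindows: no run passed the threshold")
    return(character())
  }
  modal <- as.integer(names(which.max(table(anchors))))
  keep <- abs(anchors - modal) <= tol
  half <- minWidth %/% 2L
  subs <- character(); kept <- integer()
  for (w in which(keep)) {
    # window centered on the peak, clamped to stay inside the run (so a
    # run of exactly minWidth bases is returned as-is), then the sequence
    st <- anchors[w] - half + 1L
    st <- max(runs[w, 1L], min(st, runs[w, 2L] - minWidth + 1L))
    st <- max(1L, min(st, L - minWidth + 1L))
    subs <- c(subs, substr(seqs[srcs[w]], st, st + minWidth - 1L))
    kept <- c(kept, anchors[w])
  }
  structure(subs, anchors = kept - 1L, modalAnchor = modal - 1L)
}

#' Build a position weight matrix from aligned subsequences
#'
#' Per-column base frequencies with a pseudocount of 0.25 per base, so a
#' column of n sequences gives (count + 0.25) / (n + 1).
#'
#' @param subseqs character vector of equal-width DNA subsequences (>= 2).
#' @param pseudocount per-base pseudocount (default 0.25).
#' @return a [MotifPWM].
#' @export
buildPWM <- function(subseqs, pseudocount = 0.25) {
  subseqs <- toupper(as.character(subseqs))
  if (length(subseqs) < 2L) stop("need at least 2 subsequences")
  w <- unique(nchar(subseqs))
  if (length(w) != 1L) stop("subsequences must share one width")
  bases <- c("A", "C", "G", "T")
  mat <- matrix(0, w, 4L, dimnames = list(NULL, bases))
  n <- length(subseqs)
  for (j in seq_len(w)) {
    col <- substr(subseqs, j, j)
    cnt <- table(factor(col, levels = bases))
    mat[j, ] <- (as.numeric(cnt) + pseudocount) / (n + 4 * pseudocount)
  }
  new("MotifPWM", prob = mat, nsites = n)
}

#' Consensus string of a PWM
#' @param pwm a [MotifPWM] or a width x 4 probability matrix.
#' @return character consensus (max-probability base per column).
#' @export
pwmConsensus <- function(pwm) {
  m <- if (methods::is(pwm, "MotifPWM")) pwm@prob else pwm
  paste(c("A", "C", "G", "T")[max.col(m)], collapse = "")
}

#' Export motifs in MEME minimal format
#'
#' Writes the standard minimal motif exchange format (version line, ACGT
#' alphabet, uniform background, one letter-probability matrix block per
#' motif with its nsites), consumable by TOMTOM/STREME-family tools.  An
#' empty motif list gives a valid header-only file.
#'
#' @param motifs list of [MotifPWM] (or a single one); names become motif
#'   identifiers.
#' @param path output path.
#' @export
exportMEME <- function(motifs, path) {
  if (methods::is(motifs, "MotifPWM")) motifs <- list(motifs)
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
             "Background letter frequencies",
             "A 0.25 C 0.25 G 0.25 T 0.25", "")
  nms <- names(motifs) %||% sprintf("motif%d", seq_along(motifs))
  for (i in seq_along(motifs)) {
    m <- motifs[[i]]
    lines <- c(lines,
      sprintf("MOTIF %s", nms[i]),
      sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
              nrow(m@prob), m@nsites),
      apply(m@prob, 1L, function(r) paste(sprintf("%.6f", r), collapse = " ")),
      "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname exportMEME
#' @return `readMEME()` returns a named list of [MotifPWM].
#' @export
readMEME <- function(path) {
  lines <- readLines(path)
  if (!grepl("^MEME version", lines[1L])) stop("not a MEME-format file")
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^MOTIF ", lines[i])) {
      nm <- sub("^MOTIF +", "", lines[i])
      i <- i + 1L
      hdr <- lines[i]
      w <- as.integer(sub(".* w= *([0-9]+).*", "\\1", hdr))
      ns <- as.integer(sub(".* nsites= *([0-9]+).*", "\\1", hdr))
      rows <- lines[(i + 1L):(i + w)]
      mat <- do.call(rbind, lapply(strsplit(trimws(rows), " +"), as.numeric))
      colnames(mat) <- c("A", "C", "G", "T")
      mat <- mat / rowSums(mat)
      out[[nm]] <- new("MotifPWM", prob = mat, nsites = ns)
      i <- i + w
    }
    i <- i + 1L
  }
  out
}

#' Write importance tracks as TSV
#' @param importance matrix from [positionImportance()].
#' @param path output path.
#' @export
writeImportance <- function(importance, path) {
  df <- data.frame(id = rownames(importance) %||%
                     sprintf("seq%d", seq_len(nrow(importance))),
                   importance, check.names = FALSE)
  colnames(df) <- c("id", sprintf("pos%d", seq_len(ncol(importance))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
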