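## Genome-scale scanning: slide a fixed odd-length window over a region,
## keep candidates centered on C (optionally CpG context), predict each
## candidate, and aggregate calls into fixed-width bins.  In memory the
## intervals live in GRanges (1-based closed, the container's convention);
## on disk bedGraph/BED are 0-based half-open as the formats require.

#' @importFrom GenomicRanges GRanges start end seqnames mcols mcols<-
#' @importFrom IRanges IRanges
NULL

.H_BASES <- c("A", "C", "T")

#' Classify the cytosine sequence context
#'
#' For a C at 0-based position `pos` of `seq`: `CG` downstream gives CpG;
#' `C H G` gives CHG and `C H H` gives CHH, with H = A, C, or T; any
#' ambiguity code (or a truncated context) gives `"other"`.
#'
#' @param seq a DNA string (or coercible).
#' @param pos 0-based position(s) of the cytosine; vectorized.
#' @return character vector in `c("CpG", "CHG", "CHH", "other")`.
#' @export
classifyContext <- function(seq, pos) {
  seq <- toupper(as.character(seq))
  L <- nchar(seq)
  vapply(pos, function(p) {
    if (p < 0L || p >= L) stop("position outside sequence")
    if (substr(seq, p + 1L, p + 1L) != "C")
      stop(sprintf("center base at position %d is not C", p))
    if (p + 2L > L) stop("no downstream base available")
    b1 <- substr(seq, p + 2L, p + 2L)
    if (b1 == "G") return("CpG")
    if (!b1 %in% .H_BASES) return("other")
    if (p + 3L > L) return("other")
    b2 <- substr(seq, p + 3L, p + 3L)
    if (b2 == "G") return("CHG")
    if (b2 %in% .H_BASES) return("CHH")
    "other"
  }, character(1))
}

.loadContig <- function(genome, chrom) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (methods::is(genome, "DNAStringSet")) {
    names(genome) <- sub(" .*", "", names(genome))
    if (!chrom %in% names(genome))
      stop(sprintf("contig '%s' not found", chrom))
    return(toupper(as.character(genome[[chrom]])))
  }
  stop("genome must be a FASTA path or a DNAStringSet")
}

#' Enumerate candidate windows over a genomic region
#'
#' Slides an odd-length window one base at a time over `[start, end)`
#' (0-based half-open) and keeps windows whose center base is C -- and, with
#' `cpgOnly = TRUE`, whose center context is CpG.  Windows that would overlap
#' the contig (or region) ends are dropped.
#'
#' @param genome FASTA path or [Biostrings::DNAStringSet].
#' @param chrom contig name.
#' @param start,end region, 0-based half-open.
#' @param window odd window length in bases (default 71).
#' @param cpgOnly keep only CpG-context centers (default TRUE).
#' @return a [GenomicRanges::GRanges] of the windows with metadata columns
#'   `center0` (0-based center coordinate), `centerBase`, `context`.
#' @export
scanRegion <- function(genome, chrom, start, end, window = 71L,
                       cpgOnly = TRUE) {
  if (window %% 2L != 1L) stop("window length must be odd")
  contig <- .loadContig(genome, chrom)
  L <- nchar(contig)
  if (start < 0L || end > L || start >= end)
    stop(sprintf("region [%d, %d) outside contig of length %d", start, end, L))
  flank <- (window - 1L) %/% 2L
  centers <- seq.int(start + flank, end - flank - 1L)   # window fits in region
  centers <- centers[centers + flank < L]
  if (!length(centers)) return(.emptyWindows(chrom))
  centerBase <- substring(contig, centers + 1L, centers + 1L)
  centers <- centers[centerBase == "C"]
  if (!length(centers)) return(.emptyWindows(chrom))
  ctx <- classifyContext(contig, centers)
  if (cpgOnly) {
    keep <- ctx == "CpG"
    centers <- centers[keep]; ctx <- ctx[keep]
  }
  if (!length(centers)) return(.emptyWindows(chrom))
  gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = centers - flank + 1L, end = centers + flank + 1L))
  S4Vectors::mcols(gr)$center0 <- centers
  S4Vectors::mcols(gr)$centerBase <- "C"
  S4Vectors::mcols(gr)$context <- ctx
  gr
}

.emptyWindows <- function(chrom) {
  gr <- GenomicRanges::GRanges()
  gr
}

#' Predict a methylation probability track over candidate windows
#'
#' Runs the model over each candidate window sequence and records the
#' probability at the window's center coordinate.
#'
#' @param model a [MethFusionModel] whose input length equals the window
#'   length.
#' @param windows [GenomicRanges::GRanges] from [scanRegion()].
#' @param genome the same genome the windows were enumerated from.
#' @param batchSize forward batch size.
#' @return a [GenomicRanges::GRanges] of width-1 center positions with
#'   metadata `score` (probability) and `center0`.
#' @export
predictTrack <- function(model, windows, genome, batchSize = 64L) {
  if (!length(windows)) {
    return(GenomicRanges::GRanges())
  }
  wlen <- unique(GenomicRanges::width(windows))
  if (length(wlen) != 1L || wlen != model@config$seqLen)
    stop(sprintf("window length %s does not match model input length %d",
                 paste(wlen, collapse = ","), model@config$seqLen))
  chrom <- as.character(GenomicRanges::seqnames(windows))[1L]
  contig <- .loadContig(genome, chrom)
  seqs <- substring(contig, GenomicRanges::start(windows),
                    GenomicRanges::end(windows))
  pred <- predict(model, seqs, batchSize = batchSize)
  centers <- S4Vectors::mcols(windows)$center0
  gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = centers + 1L, width = 1L))
  S4Vectors::mcols(gr)$score <- pred$probability
  S4Vectors::mcols(gr)$center0 <- centers
  gr
}

#' Aggregate a probability track into fixed-width bin calls
#'
#' Bins of `binWidth` bases tile `[regionStart, regionEnd)` left-closed; a
#' bin is called positive iff any candidate inside it has probability >=
#' `threshold`.  Calls are therefore invariant to candidate ordering.
#'
#' @param track [GenomicRanges::GRanges] from [predictTrack()].
#' @param binWidth bin width in bases (default 100).
#' @param threshold probability call threshold (default 0.5).
#' @param regionStart,regionEnd 0-based half-open interval to tile; default
#'   the track's span rounded out to whole bins.
#' @return a [GenomicRanges::GRanges] of bins with metadata `call` (0/1) and
#'   `maxProb`.
#' @export
binAggregate <- function(track, binWidth = 100L, threshold = 0.5,
                         regionStart = NULL, regionEnd = NULL) {
  if (binWidth < 1L) stop("bin width must be positive")
  if (!length(track)) stop("empty track")
  centers <- S4Vectors::mcols(track)$center0
  p <- S4Vectors::mcols(track)$score
  regionStart <- regionStart %||% ((min(centers) %/% binWidth) * binWidth)
  regionEnd <- regionEnd %||% (((max(centers) %/% binWidth) + 1L) * binWidth)
  starts <- seq.int(regionStart, regionEnd - 1L, by = binWidth)
  binOf <- (centers - regionStart) %/% binWidth + 1L
  call <- logical(length(starts)); maxP <- rep(NA_real_, length(starts))
  for (b in unique(binOf)) {
    if (b < 1L || b > length(starts)) next
    pp <- p[binOf == b]
    maxP[b] <- max(pp)
    call[b] <- any(pp >= threshold)
  }
  chrom <- as.character(GenomicRanges::seqnames(track))[1L]
  gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = starts + 1L, width = binWidth))
  S4Vectors::mcols(gr)$call <- as.integer(call)
  S4Vectors::mcols(gr)$maxProb <- maxP
  gr
}

#' Write track and bin outputs
#'
#' `writeBedGraph()` writes the probability track as bedGraph (0-based
#' half-open on disk); `writeBinBed()` writes the positive bins as BED.
#' Tracks must be coordinate-sorted.
#'
#' @param track GRanges with a `score` column.
#' @param bins GRanges from [binAggregate()].
#' @param path output path.
#' @export
writeBedGraph <- function(track, path) {
  if (is.unsorted(GenomicRanges::start(track)))
    stop("track must be coordinate-sorted")
  gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(track),
                               IRanges::IRanges(GenomicRanges::start(track),
                                                GenomicRanges::end(track)))
  S4Vectors::mcols(gr)$score <- S4Vectors::mcols(track)$score
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname writeBedGraph
#' @export
writeBinBed <- function(bins, path) {
  pos <- bins[S4Vectors::mcols(bins)$call == 1L]
  gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(pos),
                               IRanges::IRanges(GenomicRanges::start(pos),
                                                GenomicRanges::end(pos)))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a bedGraph track back
#' @param path bedGraph path.
#' @return GRanges with `score` and `center0` columns.
#' @export
readBedGraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  S4Vectors::mcols(gr)$center0 <- GenomicRanges::start(gr) - 1L
  gr
}

#' Display coordinates in 1-based inclusive form
#'
#' Converts a 0-based half-open interval to the 1-based inclusive style used
#' in genome-browser labels (e.g. "Chr1: 187,000-192,000").
#'
#' @param chrom contig name.
#' @param start,end 0-based half-open interval.
#' @return a display string.
#' @export
formatRegion1 <- function(chrom, start, end) {
  sprintf("%s: %s-%s", chrom, format(start + 1L, big.mark = ","),
          format(end, big.mark = ","))
}
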