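## Synthetic benchmark-shaped data with planted ground truth: labeled
## fixed-length windows with a class-discriminative motif in the positives,
## and toy genomes with planted CpG methylation sites for scanner tests.

.BASES <- c("A", "C", "G", "T")

#' Default planted motif
#'
#' A 6-wide CG-rich PWM (consensus GCCGCG, 0.85 on the consensus base per
#' column, ~1.15 bits/column), emulating the CG-enriched patterns around
#' plant/fungal methylation sites.  When planted at the default central
#' position of a 41-bp window, its C/G pair falls on the window center, so
#' the same motif serves CpG-context fixtures.
#'
#' @param consensus consensus string (default "GCCGCG").
#' @param strength probability of the consensus base per column
#'   (default 0.85).
#' @return a width x 4 probability matrix (columns A, C, G, T).
#' @export
defaultMotifPWM <- function(consensus = "GCCGCG", strength = 0.85) {
  w <- nchar(consensus)
  m <- matrix((1 - strength) / 3, w, 4L,
              dimnames = list(NULL, .BASES))
  for (j in seq_len(w))
    m[j, substr(consensus, j, j)] <- strength
  m
}

#' Specification of a synthetic dataset
#'
#' Defines the study conditions for the planted-motif benchmark emulation:
#' balanced classes of equal-length windows; positives carry one motif
#' instance near the window center (uniform jitter), negatives are pure
#' background (unless `leakage > 0`); optionally every record's center is
#' forced into a cytosine context, as in site-centered benchmark data.
#'
#' @param seqLen window length in bases (default 41; 11/71/101 are the other
#'   benchmark lengths).
#' @param nPerClass records per class (default 500).
#' @param background base composition A/C/G/T, summing to 1 (default
#'   uniform).
#' @param motif planted PWM, width x 4 (default [defaultMotifPWM()]).
#' @param motifStart 0-based plant position before jitter; default centers
#'   the motif in the window (start 18 for 41 bp / width 6).
#' @param jitter maximum uniform placement jitter in bases (default 2).
#' @param leakage fraction of negatives that also receive a motif instance
#'   (default 0).
#' @param centerContext `"none"` (default), or force every record's center
#'   into `"C"`, `"CpG"`, `"CHG"`, or `"CHH"` context.
#' @param seed RNG seed; every draw of the generator is determined by it.
#' @return named list of class `"syntheticSpec"`.
#' @export
syntheticSpec <- function(seqLen = 41L, nPerClass = 500L,
                          background = c(A = 0.25, C = 0.25,
                                         G = 0.25, T = 0.25),
                          motif = defaultMotifPWM(),
                          motifStart = NULL, jitter = 2L, leakage = 0,
                          centerContext = c("none", "C", "CpG", "CHG", "CHH"),
                          seed = 1L) {
  if (methods::is(motif, "MotifPWM")) motif <- motif@prob
  stopifnot(abs(sum(background) - 1) < 1e-8, leakage >= 0, leakage <= 1,
            nrow(motif) <= seqLen)
  w <- nrow(motif)
  motifStart <- motifStart %||% as.integer(ceiling((seqLen - w) / 2))
  if (motifStart - jitter < 0L || motifStart + jitter + w > seqLen)
    stop("motif placement (with jitter) must stay inside the window")
  structure(list(seqLen = as.integer(seqLen),
                 nPerClass = as.integer(nPerClass),
                 background = background, motif = motif,
                 motifStart = as.integer(motifStart),
                 jitter = as.integer(jitter), leakage = leakage,
                 centerContext = match.arg(centerContext),
                 seed = as.integer(seed)),
            class = "syntheticSpec")
}

#' Sample a background sequence
#'
#' I.i.d. bases from a composition; consumes the current RNG stream.
#'
#' @param length sequence length.
#' @param composition A/C/G/T probabilities summing to 1.
#' @return a DNA string.
#' @export
sampleBackground <- function(length,
                             composition = c(A = 0.25, C = 0.25,
                                             G = 0.25, T = 0.25)) {
  stopifnot(abs(sum(composition) - 1) < 1e-8)
  paste(sample(.BASES, length, replace = TRUE, prob = composition),
        collapse = "")
}

#' Plant one motif instance in a sequence
#'
#' Replaces the bases at `[position, position + W)` (0-based) with a sample
#' from the PWM rows; the rest of the sequence is untouched.
#'
#' @param seq DNA string.
#' @param pwm width x 4 probability matrix (or [MotifPWM]).
#' @param position 0-based plant position.
#' @return the modified sequence.
#' @export
plantMotif <- function(seq, pwm, position) {
  if (methods::is(pwm, "MotifPWM")) pwm <- pwm@prob
  w <- nrow(pwm)
  if (position < 0L || position + w > nchar(seq))
    stop("motif does not fit at the requested position")
  inst <- vapply(seq_len(w), function(j)
    sample(.BASES, 1L, prob = pwm[j, ]), character(1))
  paste0(substr(seq, 1L, position),
         paste(inst, collapse = ""),
         substr(seq, position + w + 1L, nchar(seq)))
}

.forceContext <- function(seq, context) {
  if (context == "none") return(seq)
  L <- nchar(seq)
  c0 <- (L - 1L) %/% 2L                   # 0-based center
  sub <- function(s, i, b) {
    substr(s, i + 1L, i + 1L) <- b
    s
  }
  seq <- sub(seq, c0, "C")
  if (context == "CpG") seq <- sub(seq, c0 + 1L, "G")
  if (context == "CHG") {
    seq <- sub(seq, c0 + 1L, sample(c("A", "C", "T"), 1L))
    seq <- sub(seq, c0 + 2L, "G")
  }
  if (context == "CHH") {
    seq <- sub(seq, c0 + 1L, sample(c("A", "C", "T"), 1L))
    seq <- sub(seq, c0 + 2L, sample(c("A", "C", "T"), 1L))
  }
  seq
}

#' Generate a labeled planted-motif dataset
#'
#' Balanced classes: `nPerClass` positives with one motif instance planted at
#' `motifStart` + uniform jitter, `nPerClass` background negatives (a
#' `leakage` fraction of which also receive the motif).  The plant position
#' of every motif instance is recorded in the result's `meta` (`motifStart`,
#' 0-based; NA where nothing was planted) as ground truth for
#' interpretability tests.  Fully determined by `spec$seed`.
#'
#' Records that receive no motif are resampled (bounded retries) until they
#' contain no exact consensus hit, so with `leakage = 0` the negative class
#' is guaranteed free of chance consensus occurrences.
#'
#' @param spec a [syntheticSpec()].
#' @return a [MethDataSet] with `meta` columns `motifStart`.
#' @export
generateDataset <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  set.seed(spec$seed)
  n <- spec$nPerClass
  consensus <- pwmConsensus(spec$motif)
  seqs <- character(2L * n); starts <- rep(NA_integer_, 2L * n)
  lab <- rep(c(1L, 0L), each = n)
  for (i in seq_len(2L * n)) {
    plant <- lab[i] == 1L ||
      (spec$leakage > 0 && stats::runif(1) < spec$leakage)
    if (plant) {
      s <- sampleBackground(spec$seqLen, spec$background)
      off <- if (spec$jitter > 0)
        sample(seq(-spec$jitter, spec$jitter), 1L) else 0L
      st <- spec$motifStart + off
      s <- plantMotif(s, spec$motif, st)
      starts[i] <- st
    } else {
      for (try in 1:50) {
        s <- sampleBackground(spec$seqLen, spec$background)
        if (!grepl(consensus, s, fixed = TRUE)) break
      }
    }
    seqs[i] <- .forceContext(s, spec$centerContext)
  }
  ids <- sprintf("%s%d", ifelse(lab == 1L, "pos", "neg"),
                 c(seq_len(n), seq_len(n)))
  methDataSet(seqs, lab, meta = data.frame(motifStart = starts), ids = ids)
}

#' Generate a toy genome with planted methylation sites
#'
#' A background contig with `nSites` planted sites: at each site center the
#' motif is planted around the center and the center dinucleotide is forced
#' to CpG, so every truth site is a valid scan candidate.  Site centers keep
#' a minimum pairwise distance (default the window length) so planted
#' windows do not overlap; placement is retried a bounded number of times.
#'
#' @param contigLength contig length in bases (default 5000).
#' @param nSites number of planted sites (default 20).
#' @param window the scan window length the genome is meant for (default 71);
#'   sites keep `window %/% 2` clear of the contig ends.
#' @param motif planted PWM (default [defaultMotifPWM()]).
#' @param background base composition (default uniform).
#' @param minDist minimum distance between site centers (default `window`).
#' @param seed RNG seed.
#' @param chrom contig name (default "chrSim").
#' @return list with `genome` (a named [Biostrings::DNAStringSet]) and
#'   `sites` (a width-1 [GenomicRanges::GRanges] of the true site centers,
#'   with `center0` metadata).
#' @export
generateGenome <- function(contigLength = 5000L, nSites = 20L, window = 71L,
                           motif = defaultMotifPWM(),
                           background = c(A = 0.25, C = 0.25,
                                          G = 0.25, T = 0.25),
                           minDist = NULL, seed = 1L, chrom = "chrSim") {
  if (methods::is(motif, "MotifPWM")) motif <- motif@prob
  set.seed(seed)
  minDist <- minDist %||% as.integer(window)
  flank <- (window - 1L) %/% 2L
  lo <- flank + nrow(motif); hi <- contigLength - flank - nrow(motif) - 1L
  centers <- integer(0)
  for (try in seq_len(1000L)) {
    cand <- sample(lo:hi, 1L)
    if (all(abs(cand - centers) >= minDist)) centers <- c(centers, cand)
    if (length(centers) == nSites) break
  }
  if (length(centers) < nSites)
    stop("could not place sites without overlap after bounded retries")
  centers <- sort(centers)
  contig <- sampleBackground(contigLength, background)
  for (c0 in centers) {
    st <- c0 - 2L                          # motif C/G pair lands on center
    contig <- plantMotif(contig, motif, st)
    substr(contig, c0 + 1L, c0 + 2L) <- "CG"
  }
  genome <- Biostrings::DNAStringSet(contig)
  names(genome) <- chrom
  sites <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = centers + 1L, width = 1L))
  S4Vectors::mcols(sites)$center0 <- centers
  list(genome = genome, sites = sites)
}

#' Write a toy genome and its truth sites
#' @param gen list from [generateGenome()].
#' @param fastaPath,bedPath output paths.
#' @export
writeGenome <- function(gen, fastaPath, bedPath) {
  Biostrings::writeXStringSet(gen$genome, fastaPath)
  rtracklayer::export(gen$sites, bedPath, format = "BED")
  invisible(fastaPath)
}

#' Transfer-learning fixture
#'
#' Source condition: abundant CpG-context data with the default motif.
#' Target condition: scarce CHG-context data with a motif sharing a 4-base
#' core (CCGC) with the source motif but different flanks -- the shared-core
#' design that makes pretraining on the source informative for the target.
#'
#' @param nSource,nTarget records per class (defaults 500 and 200).
#' @param seed base seed; source and target use offset seeds.
#' @return list with `source` and `target` [syntheticSpec()]s.
#' @export
transferFixture <- function(nSource = 500L, nTarget = 200L, seed = 1L) {
  # the motif sits left of center so forcing the center context (which
  # rewrites the center dinucleotides) cannot overwrite motif bases
  list(
    source = syntheticSpec(nPerClass = nSource,
                           motif = defaultMotifPWM("GCCGCG"),
                           motifStart = 10L,
                           centerContext = "CpG", seed = seed),
    target = syntheticSpec(nPerClass = nTarget,
                           motif = defaultMotifPWM("TCCGCA"),
                           motifStart = 10L,
                           centerContext = "CHG", seed = seed + 1000L))
}

#' Conservation fixture for cross-condition grids
#'
#' Conditions A and B share the planted motif (different random draws);
#' condition C carries a disjoint, CG-poor motif.  Emulates the
#' cross-species design where accuracy transfers within a conserved motif
#' family but not across families.
#'
#' @param nPerClass records per class per condition (default 300).
#' @param seed base seed.
#' @return named list of three [syntheticSpec()]s (`A`, `B`, `C`).
#' @export
conservationFixture <- function(nPerClass = 300L, seed = 1L) {
  shared <- defaultMotifPWM("GCCGCG")
  disjoint <- defaultMotifPWM("TGATAA")
  list(A = syntheticSpec(nPerClass = nPerClass, motif = shared,
                         seed = seed),
       B = syntheticSpec(nPerClass = nPerClass, motif = shared,
                         seed = seed + 2000L),
       C = syntheticSpec(nPerClass = nPerClass, motif = disjoint,
                         seed = seed + 4000L))
}
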