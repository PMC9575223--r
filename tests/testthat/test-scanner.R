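test_that("cytosine context classification matches the rule table", {
  expect_equal(classifyContext("ACGT", 1), "CpG")
  expect_equal(classifyContext("ACAGT", 1), "CHG")
  expect_equal(classifyContext("ACTTT", 1), "CHH")
  expect_error(classifyContext("AAGT", 1), "not C")
  # exhaustive dinucleotide downstream contexts vs rule-table oracle
  bases <- c("A", "C", "G", "T")
  for (b1 in bases) for (b2 in bases) {
    got <- classifyContext(paste0("C", b1, b2), 0)
    want <- if (b1 == "G") "CpG"
    else if (b2 == "G") "CHG"
    else "CHH"
    expect_equal(got, want, label = paste0("C", b1, b2))
  }
  expect_equal(classifyContext("CNAT", 0), "other")
  expect_equal(classifyContext("CANT", 0), "other")
})

test_that("region scanning enumerates candidate windows exactly", {
  polyA <- Biostrings::DNAStringSet(paste(rep("A", 300), collapse = ""))
  names(polyA) <- "chrA"
  expect_equal(length(scanRegion(polyA, "chrA", 0, 300, window = 71)), 0L)

  gen <- generateGenome(contigLength = 500, nSites = 3, window = 71,
                        seed = 21)
  contig <- as.character(gen$genome[[1]])
  win <- scanRegion(gen$genome, "chrSim", 0, 500, window = 71,
                    cpgOnly = TRUE)
  expect_true(all(GenomicRanges::width(win) == 71L))
  # brute-force enumeration oracle over interior CpG cytosines
  flank <- 35
  truth <- integer()
  for (c0 in flank:(500 - flank - 1)) {
    if (substr(contig, c0 + 1, c0 + 1) == "C" &&
        substr(contig, c0 + 2, c0 + 2) == "G")
      truth <- c(truth, c0)
  }
  expect_identical(S4Vectors::mcols(win)$center0, truth)
  # center-C-only filter is a superset
  winC <- scanRegion(gen$genome, "chrSim", 0, 500, window = 71,
                     cpgOnly = FALSE)
  expect_true(all(truth %in% S4Vectors::mcols(winC)$center0))
  expect_true(all(S4Vectors::mcols(winC)$centerBase == "C"))
  expect_error(scanRegion(gen$genome, "chrSim", 0, 900), "outside contig")
  expect_error(scanRegion(gen$genome, "chrSim", 0, 500, window = 70), "odd")
})

test_that("prediction tracks are deterministic and center-anchored", {
  gen <- generateGenome(contigLength = 400, nSites = 2, window = 11,
                        seed = 5)
  win <- scanRegion(gen$genome, "chrSim", 0, 400, window = 11)
  m <- tinyModel(seqLen = 11, seed = 9)
  tr1 <- predictTrack(m, win, gen$genome)
  tr2 <- predictTrack(m, win, gen$genome)
  expect_identical(S4Vectors::mcols(tr1)$score, S4Vectors::mcols(tr2)$score)
  expect_equal(GenomicRanges::start(tr1) - 1L,
               S4Vectors::mcols(win)$center0)
  expect_equal(length(predictTrack(m, GenomicRanges::GRanges(), gen$genome)),
               0L)
  # window length contract
  win71 <- scanRegion(gen$genome, "chrSim", 0, 400, window = 15)
  if (length(win71))
    expect_error(predictTrack(m, win71, gen$genome), "input length")
})

test_that("bin aggregation matches a loop oracle and ignores order", {
  mk <- function(centers, p) {
    gr <- GenomicRanges::GRanges("chr",
      IRanges::IRanges(start = centers + 1L, width = 1L))
    S4Vectors::mcols(gr)$score <- p
    S4Vectors::mcols(gr)$center0 <- centers
    gr
  }
  # single candidate at 150 with p = 0.9
  bins <- binAggregate(mk(150L, 0.9), binWidth = 100, threshold = 0.5,
                       regionStart = 0, regionEnd = 400)
  expect_equal(S4Vectors::mcols(bins)$call, c(0L, 1L, 0L, 0L))
  expect_equal(GenomicRanges::start(bins), c(1L, 101L, 201L, 301L))
  # nothing above threshold: all negative
  bins0 <- binAggregate(mk(c(10L, 210L), c(0.2, 0.4)), binWidth = 100,
                        threshold = 0.5, regionStart = 0, regionEnd = 300)
  expect_true(all(S4Vectors::mcols(bins0)$call == 0L))
  # random track vs loop oracle; order invariance
  set.seed(77)
  centers <- sort(sample(0:999, 60))
  p <- runif(60)
  tr <- mk(centers, p)
  got <- binAggregate(tr, binWidth = 100, threshold = 0.6,
                      regionStart = 0, regionEnd = 1000)
  want <- integer(10)
  for (i in seq_along(centers)) {
    b <- centers[i] %/% 100 + 1
    if (p[i] >= 0.6) want[b] <- 1L
  }
  expect_equal(S4Vectors::mcols(got)$call, want)
  sh <- sample(60)
  got2 <- binAggregate(mk(centers[sh], p[sh]), binWidth = 100,
                       threshold = 0.6, regionStart = 0, regionEnd = 1000)
  expect_equal(S4Vectors::mcols(got2)$call, want)
  expect_error(binAggregate(tr, binWidth = 0), "positive")
})

test_that("bedGraph/BED outputs round-trip with 0-based half-open coords", {
  centers <- c(10L, 55L, 99L)
  gr <- GenomicRanges::GRanges("chrSim",
    IRanges::IRanges(start = centers + 1L, width = 1L))
  S4Vectors::mcols(gr)$score <- c(0.25, 0.5, 0.75)
  S4Vectors::mcols(gr)$center0 <- centers
  path <- tempfile(fileext = ".bedGraph")
  writeBedGraph(gr, path)
  # raw text is 0-based half-open
  raw <- read.table(path)
  expect_equal(raw$V2, centers)
  expect_equal(raw$V3, centers + 1L)
  back <- readBedGraph(path)
  expect_equal(S4Vectors::mcols(back)$center0, centers)
  expect_equal(S4Vectors::mcols(back)$score, c(0.25, 0.5, 0.75))
  # unsorted input is rejected
  expect_error(writeBedGraph(rev(gr), tempfile()), "sorted")
  # larger round trip
  set.seed(3)
  c2 <- sort(sample(0:5000, 1000))
  gr2 <- GenomicRanges::GRanges("chrSim",
    IRanges::IRanges(start = c2 + 1L, width = 1L))
  S4Vectors::mcols(gr2)$score <- round(runif(1000), 6)
  S4Vectors::mcols(gr2)$center0 <- c2
  p2 <- tempfile(fileext = ".bedGraph")
  writeBedGraph(gr2, p2)
  b2 <- readBedGraph(p2)
  expect_equal(S4Vectors::mcols(b2)$center0, c2)
  expect_equal(S4Vectors::mcols(b2)$score, S4Vectors::mcols(gr2)$score,
               tolerance = 1e-9)
  # BED bin calls
  bins <- binAggregate(gr2, binWidth = 500, threshold = 0.9,
                       regionStart = 0, regionEnd = 5000)
  bp <- tempfile(fileext = ".bed")
  writeBinBed(bins, bp)
  bedBack <- rtracklayer::import(bp, format = "BED")
  expect_equal(length(bedBack), sum(S4Vectors::mcols(bins)$call))
})

test_that("display coordinates convert to 1-based inclusive style", {
  expect_equal(formatRegion1("Chr1", 187000, 192000),
               "Chr1: 187,001-192,000")
})
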