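## Dataset I/O: FASTA-with-label-headers and TSV dialects, stratified
## splits, context filtering, duplicate removal, YAML manifests.

#' Construct a MethDataSet
#'
#' @param seqs character vector or [Biostrings::DNAStringSet] of
#'   equal-length sequences over A/C/G/T/N.
#' @param labels vector coercible to integer 0/1 (1 = methylated).
#' @param meta optional data.frame of per-record tags.
#' @param ids optional record identifiers (kept as sequence names).
#' @return a [MethDataSet].
#' @export
methDataSet <- function(seqs, labels, meta = NULL, ids = NULL) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(toupper(seqs))
  if (!is.null(ids)) names(seqs) <- ids
  if (is.null(names(seqs)) && length(seqs))
    names(seqs) <- sprintf("seq%d", seq_along(seqs))
  meta <- meta %||% data.frame()
  new("MethDataSet", sequences = seqs, labels = as.integer(labels),
      meta = meta)
}

.validateSeqChars <- function(seqs, ids) {
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("illegal characters in sequences: ",
         paste(utils::head(ids[bad], 5L), collapse = ", "))
}

#' Read a labeled dataset
#'
#' Two dialects: FASTA with the label as the last `|`-separated token of the
#' header (`>id|1`), or TSV with header `id`, `sequence`, `label`.  Sequences
#' are validated for a uniform length and a legal alphabet (A/C/G/T/N);
#' mixed lengths are an error listing the offending records.
#'
#' @param path input path.
#' @param format `"auto"` (by extension), `"fasta"`, or `"tsv"`.
#' @return a [MethDataSet].
#' @export
readDataset <- function(path, format = c("auto", "fasta", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  if (format == "fasta") {
    ss <- Biostrings::readDNAStringSet(path)
    hdr <- names(ss)
    parts <- strsplit(hdr, "|", fixed = TRUE)
    lab <- vapply(parts, function(p) p[length(p)], character(1))
    ids <- vapply(parts, function(p)
      paste(p[-length(p)], collapse = "|"), character(1))
    seqs <- toupper(as.character(ss))
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("id", "sequence", "label")
    if (!all(need %in% colnames(df)))
      stop("TSV must have columns id, sequence, label")
    ids <- as.character(df$id); seqs <- toupper(df$sequence)
    lab <- as.character(df$label)
  }
  if (!all(lab %in% c("0", "1")))
    stop("unknown label value(s): ",
         paste(utils::head(setdiff(unique(lab), c("0", "1")), 5L),
               collapse = ", "))
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    main <- as.integer(names(which.max(table(lens))))
    stop("mixed sequence lengths; offending records: ",
         paste(utils::head(ids[lens != main], 5L), collapse = ", "))
  }
  .validateSeqChars(seqs, ids)
  methDataSet(seqs, as.integer(lab), ids = ids)
}

#' Write a dataset
#'
#' @param ds a [MethDataSet].
#' @param path output path.
#' @param format `"fasta"` (headers `>id|label`) or `"tsv"`.
#' @export
writeDataset <- function(ds, path, format = c("fasta", "tsv")) {
  format <- match.arg(format)
  ids <- names(sequences(ds))
  if (format == "fasta") {
    ss <- sequences(ds)
    names(ss) <- paste(ids, labels(ds), sep = "|")
    Biostrings::writeXStringSet(ss, path)
  } else {
    utils::write.table(
      data.frame(id = ids, sequence = as.character(sequences(ds)),
                 label = labels(ds)),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Label-stratified train/validation/test split
#'
#' Seeded and reproducible; class ratios are preserved within one sample per
#' split.
#'
#' @param ds a [MethDataSet].
#' @param fractions named numeric vector summing to 1 (default
#'   `c(train = .8, validation = .1, test = .1)`).
#' @param seed RNG seed.
#' @return named list of integer index vectors (disjoint, covering).
#' @export
stratifiedSplit <- function(ds, fractions = c(train = 0.8, validation = 0.1,
                                              test = 0.1), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  nsplit <- sum(fractions > 0)
  y <- labels(ds)
  out <- stats::setNames(vector("list", length(fractions)), names(fractions))
  set.seed(seed)
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    if (length(idx) < nsplit)
      stop(sprintf("class %d has fewer samples (%d) than splits (%d)",
                   cls, length(idx), nsplit))
    sizes <- floor(fractions * length(idx))
    # distribute the remainder to the largest fractions
    rem <- length(idx) - sum(sizes)
    if (rem > 0) {
      add <- order(fractions, decreasing = TRUE)[seq_len(rem)]
      sizes[add] <- sizes[add] + 1L
    }
    at <- 0L
    for (s in seq_along(fractions)) {
      take <- idx[seq_len(sizes[s]) + at]
      out[[s]] <- sort(c(out[[s]], take))
      at <- at + sizes[s]
    }
  }
  out
}

#' Filter records by cytosine context
#'
#' Keeps records whose center base context (via [classifyContext()]) matches
#' `pattern`.  Records whose center base is not C are dropped with one
#' summarizing warning.
#'
#' @param ds a [MethDataSet] of odd-length windows centered on the candidate
#'   site.
#' @param pattern one of `"CpG"`, `"CHG"`, `"CHH"`, `"other"`.
#' @return the filtered [MethDataSet].
#' @export
filterByContext <- function(ds, pattern = c("CpG", "CHG", "CHH", "other")) {
  pattern <- match.arg(pattern)
  seqs <- as.character(sequences(ds))
  L <- nchar(seqs[1L])
  center <- (L - 1L) %/% 2L               # 0-based
  isC <- substr(seqs, center + 1L, center + 1L) == "C"
  if (any(!isC))
    warning(sprintf("dropped %d records whose center base is not C",
                    sum(!isC)))
  ctx <- rep(NA_character_, length(seqs))
  ctx[isC] <- vapply(which(isC), function(i)
    classifyContext(seqs[i], center), character(1))
  ds[which(!is.na(ctx) & ctx == pattern)]
}

#' Remove exact duplicate sequences
#'
#' Identity-based filter: keeps the first occurrence of each distinct
#' sequence.  (Similarity-based redundancy reduction at an identity
#' threshold, as done with clustering tools upstream of benchmark datasets,
#' is outside this package.)
#'
#' @param ds a [MethDataSet].
#' @return the deduplicated [MethDataSet].
#' @export
dedupDataset <- function(ds) {
  dup <- duplicated(as.character(sequences(ds)))
  if (any(dup))
    message(sprintf("dedupDataset: removed %d exact duplicates", sum(dup)))
  ds[which(!dup)]
}

#' Write a dataset manifest as YAML
#'
#' Records length, per-class counts, and any tag columns -- the dataset-level
#' facts a downstream consumer needs without reading the sequences.
#'
#' @param ds a [MethDataSet].
#' @param path output path.
#' @param extra optional named list merged into the manifest.
#' @export
writeManifest <- function(ds, path, extra = NULL) {
  m <- list(
    records = length(ds),
    length_bp = if (length(ds)) Biostrings::width(sequences(ds))[1L] else 0L,
    positives = sum(labels(ds) == 1L),
    negatives = sum(labels(ds) == 0L),
    tags = as.list(colnames(ds@meta)))
  if (!is.null(extra)) m <- c(m, extra)
  yaml::write_yaml(m, path)
  invisible(path)
}
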