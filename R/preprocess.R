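#' Size-class rule for small-RNA partitioning
#'
#' Defaults follow the canonical mosquito small-RNA size structure: a sharp
#' endo-siRNA class at 21 nt and a broad piRNA class at 24-31 nt (centred at
#' 28 nt), plus an open-ended >= 24 nt "pool" class used for
#' capture-recapture diversity estimation.
#'
#' @param sirnaLength exact siRNA length (default 21).
#' @param pirnaMin,pirnaMax inclusive piRNA length bounds (defaults 24, 31).
#' @param poolMin lower bound (no upper bound) of the pool class (default 24).
#' @return a validated list of class `SizeClassRule`.
#' @export
sizeClassRule <- function(sirnaLength = 21L, pirnaMin = 24L, pirnaMax = 31L,
                          poolMin = 24L) {
  stopifnot(sirnaLength < pirnaMin, pirnaMin <= pirnaMax, poolMin <= pirnaMin)
  structure(list(sirnaLength = as.integer(sirnaLength),
                 pirnaMin = as.integer(pirnaMin),
                 pirnaMax = as.integer(pirnaMax),
                 poolMin = as.integer(poolMin)),
            class = "SizeClassRule")
}

#' Strip a 3' adapter by suffix-prefix overlap
#'
#' The longest read suffix matching a prefix of the adapter is removed,
#' provided the overlap is at least `minOverlap` and the Hamming mismatch
#' count does not exceed `floor(overlap / mismatchPer)`. A read whose trimmed
#' length falls below `minLength` is rejected; a read with no qualifying
#' overlap is returned unchanged. The operation is idempotent on its own
#' output for adapter-free results.
#'
#' @param sequences character vector of raw reads (DNA alphabet).
#' @param adapter adapter sequence (length >= `minOverlap`).
#' @param minOverlap minimum suffix/prefix overlap (default 6).
#' @param mismatchPer one mismatch allowed per this many overlap bases
#'   (default 10, i.e. budget `floor(overlap/10)`).
#' @param minLength shortest acceptable trimmed read (default 16, the gel
#'   excision floor).
#' @return a data.frame with columns `sequence` (trimmed read, `NA` when
#'   rejected) and `status` (`trimmed`, `unchanged`, `rejected`).
#' @export
stripAdapter <- function(sequences, adapter, minOverlap = 6L,
                         mismatchPer = 10L, minLength = 16L) {
  adapter <- chartr("U", "T", toupper(adapter))
  stopifnot(nchar(adapter) >= minOverlap)
  sequences <- chartr("U", "T", toupper(as.character(sequences)))
  achars <- strsplit(adapter, "")[[1]]
  alen <- length(achars)
  one <- function(read) {
    rchars <- strsplit(read, "")[[1]]
    rlen <- length(rchars)
    # earliest adapter start position = longest suffix
    for (s in seq_len(max(0L, rlen - minOverlap + 1L))) {
      ov <- min(rlen - s + 1L, alen)
      mm <- sum(rchars[s:(s + ov - 1L)] != achars[seq_len(ov)])
      if (mm <= ov %/% mismatchPer) return(s - 1L)  # trimmed length
    }
    -1L
  }
  trimmedLen <- vapply(sequences, one, integer(1), USE.NAMES = FALSE)
  status <- ifelse(trimmedLen < 0L, "unchanged",
                   ifelse(trimmedLen < minLength, "rejected", "trimmed"))
  out <- sequences
  tr <- status == "trimmed"
  out[tr] <- substr(sequences[tr], 1L, trimmedLen[tr])
  out[status == "rejected"] <- NA_character_
  data.frame(sequence = out, status = status, stringsAsFactors = FALSE)
}

#' Remove sequences matching a reference set
#'
#' A sequence is removed iff it has at least one full-length alignment, on
#' either strand, to any reference at Hamming distance `<= maxMismatches`
#' (the pipeline's database-matching rule, used here for rRNA-like and
#' miRNA-like contaminant removal). The kept and removed libraries partition
#' the input multiset.
#'
#' @param library a [SmallRNALibrary-class].
#' @param referenceSet non-empty named [Biostrings::DNAStringSet].
#' @param maxMismatches mismatch budget (default 2).
#' @return list with `SmallRNALibrary` elements `kept` and `removed`.
#' @export
filterMatching <- function(library, referenceSet, maxMismatches = 2L) {
  stopifnot(length(referenceSet) > 0L)
  if (is.null(names(referenceSet)))
    names(referenceSet) <- paste0("ref", seq_along(referenceSet))
  gr <- alignFullLength(sequences(library), referenceSet, maxMismatches)
  matched <- unique(gr$seqId)
  list(kept = subsetLibrary(library,
                            setdiff(sequences(library), matched)),
       removed = subsetLibrary(library, matched))
}

#' Partition a library into size classes
#'
#' `sirna` holds reads of exactly the siRNA length, `pirna` the closed piRNA
#' length range, `pool_pirna` the open-ended >= `poolMin` class (a superset
#' of `pirna` used for pool-size estimation), and `other` the remainder;
#' `sirna + pirna + other` partitions the library.
#'
#' @param library a [SmallRNALibrary-class].
#' @param rule a [sizeClassRule()].
#' @return named list of `SmallRNALibrary`: `sirna`, `pirna`, `pool_pirna`,
#'   `other`.
#' @export
partitionBySize <- function(library, rule = sizeClassRule()) {
  len <- nchar(sequences(library))
  list(
    sirna = subsetLibrary(library, len == rule$sirnaLength),
    pirna = subsetLibrary(library,
                          len >= rule$pirnaMin & len <= rule$pirnaMax),
    pool_pirna = subsetLibrary(library, len >= rule$poolMin),
    other = subsetLibrary(library,
                          len != rule$sirnaLength &
                            (len < rule$pirnaMin | len > rule$pirnaMax)))
}

#' Preprocess a raw library
#'
#' Adapter stripping, length filtering (16-35 nt gel window) and contaminant
#' removal against optional rRNA-like and miRNA-like reference sets, with a
#' per-category removal report.
#'
#' @param library raw [SmallRNALibrary-class].
#' @param adapter 3' adapter sequence, or `NULL` to skip trimming.
#' @param rrnaRef,mirnaRef optional [Biostrings::DNAStringSet] contaminant
#'   references.
#' @param minLength,maxLength post-trim length window (defaults 16, 35).
#' @param maxMismatches contaminant-matching budget (default 2).
#' @return list: `library` (clean `SmallRNALibrary`) and `report`
#'   (data.frame of per-category read counts).
#' @export
preprocessLibrary <- function(library, adapter = NULL, rrnaRef = NULL,
                              mirnaRef = NULL, minLength = 16L,
                              maxLength = 35L, maxMismatches = 2L) {
  counts <- readCounts(library)
  report <- data.frame(category = character(), reads = integer())
  log1 <- function(cat, n)
    rbind(report, data.frame(category = cat, reads = as.integer(n)))
  report <- log1("input", sum(counts))
  if (!is.null(adapter)) {
    tr <- stripAdapter(names(counts), adapter, minLength = minLength)
    report <- log1("adapter_rejected", sum(counts[tr$status == "rejected"]))
    keep <- tr$status != "rejected"
    library <- SmallRNALibrary(tr$sequence[keep], counts[keep],
                               id = libId(library), species = library@species,
                               line = library@line,
                               replicateGroup = library@replicateGroup)
    counts <- readCounts(library)
  }
  len <- nchar(names(counts))
  out <- len < minLength | len > maxLength
  report <- log1("length_filtered", sum(counts[out]))
  library <- subsetLibrary(library, !out)
  for (nm in c("rrna", "mirna")) {
    ref <- if (nm == "rrna") rrnaRef else mirnaRef
    if (is.null(ref) || nSequences(library) == 0L) {
      report <- log1(paste0(nm, "_removed"), 0L)
      next
    }
    fl <- filterMatching(library, ref, maxMismatches)
    report <- log1(paste0(nm, "_removed"), nReads(fl$removed))
    library <- fl$kept
  }
  report <- log1("clean", nReads(library))
  list(library = library, report = report)
}
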