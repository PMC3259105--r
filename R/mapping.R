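#' @importFrom Biostrings vmatchPattern
NULL

#' Full-length ungapped alignment with a mismatch budget
#'
#' Returns every placement of each query on either strand of the references
#' at Hamming distance at most `maxMismatches` over the query's entire
#' length. This is the mapping policy of the pipeline: for small RNAs shorter
#' than a seed-aligner's seed, seed-based mapping collapses to exactly this
#' full-length rule. Reference `N` bases never match (they count as
#' mismatches). Reverse-strand placements compare the query against the
#' reference's reverse complement; their reported `fivePrime` coordinate is
#' the interval end.
#'
#' The implementation seeds candidate placements with exact matches of
#' `maxMismatches + 1` disjoint query segments (pigeonhole: one segment of
#' any qualifying placement must match exactly) and verifies each candidate
#' by Hamming distance. It is observationally identical to an exhaustive
#' window scan.
#'
#' @param sequences character vector of query sequences over {A,C,G,T}
#'   (duplicates are collapsed); non-ACGT input is an error.
#' @param references named [Biostrings::DNAStringSet].
#' @param maxMismatches integer >= 0 mismatch budget (default 2).
#' @return a `GRanges` with metadata columns `seqId` (query string),
#'   `mismatches` and `fivePrime`, sorted by contig, start, strand.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr = paste(rep("ACGT", 20), collapse = "")))
#' alignFullLength("ACGTACGTACGTACGTACGTACGT", g, 0)
#' @export
alignFullLength <- function(sequences, references, maxMismatches = 2L) {
  stopifnot(methods::is(references, "DNAStringSet"))
  if (is.null(names(references)))
    stop("references must be named")
  sequences <- unique(as.character(sequences))
  if (length(sequences) && any(grepl("[^ACGT]", sequences)))
    stop("query sequences must be over {A,C,G,T}")
  maxMismatches <- as.integer(maxMismatches)
  stopifnot(maxMismatches >= 0L)
  empty <- GRanges()
  mcols(empty) <- DataFrame(seqId = character(0), mismatches = integer(0),
                            fivePrime = integer(0))
  if (!length(sequences)) return(empty)

  lens <- nchar(sequences)
  reflens <- width(references)
  nseg <- maxMismatches + 1L
  w <- max(1L, min(lens) %/% nseg)
  fwd <- DNAStringSet(sequences)
  rvc <- reverseComplement(fwd)
  offs <- (seq_len(nseg) - 1L) * w

  res <- list()
  npat <- length(sequences)
  for (str in c("+", "-")) {
    pats <- if (str == "+") fwd else rvc
    pdicts <- lapply(seq_len(nseg), function(j)
      PDict(subseq(pats, start = offs[j] + 1L, width = w)))
    for (ci in seq_along(references)) {
      # candidate starts on this contig from exact segment matches
      patIdx <- integer(0)
      candStart <- integer(0)
      for (j in seq_len(nseg)) {
        m <- matchPDict(pdicts[[j]], references[[ci]])
        np <- S4Vectors::elementNROWS(m)
        if (sum(np) == 0L) next
        patIdx <- c(patIdx, rep.int(seq_along(np), np))
        candStart <- c(candStart,
                       unlist(Biostrings::startIndex(m),
                              use.names = FALSE) - offs[j])
      }
      if (!length(patIdx)) next
      keep <- !duplicated((as.numeric(candStart) - 1) * npat + patIdx) &
        candStart >= 1L & candStart + lens[patIdx] - 1L <= reflens[ci]
      patIdx <- patIdx[keep]
      candStart <- candStart[keep]
      if (!length(patIdx)) next
      # verify candidates in bulk, grouped by query length
      candLen <- lens[patIdx]
      for (L in unique(candLen)) {
        sel <- which(candLen == L)
        wins <- Biostrings::extractAt(
          references[[ci]], IRanges(candStart[sel], width = L))
        mm <- rowSums(as.matrix(wins) != as.matrix(pats[patIdx[sel]]))
        ok <- mm <= maxMismatches
        if (!any(ok)) next
        res[[length(res) + 1L]] <- GRanges(
          factor(rep(names(references)[ci], sum(ok)),
                 levels = names(references)),
          IRanges(candStart[sel][ok], width = L),
          strand = str,
          seqId = sequences[patIdx[sel][ok]],
          mismatches = as.integer(mm[ok]))
      }
    }
  }
  if (!length(res)) return(empty)
  gr <- do.call(c, unname(res))
  gr$fivePrime <- ifelse(as.character(strand(gr)) == "-", end(gr), start(gr))
  sortHits(gr)
}

#' Map a library to an assembly and classify uniqueness
#'
#' Runs [alignFullLength()] on every distinct sequence of the library and
#' classifies each as `unique` (exactly one hit in its minimum-mismatch
#' stratum), `multi` (several best-stratum hits) or `unmapped`. All hits are
#' retained (for density maps); the best stratum is flagged.
#'
#' @param library a [SmallRNALibrary-class].
#' @param assembly named [Biostrings::DNAStringSet].
#' @param maxMismatches mismatch budget (default 2).
#' @return a [MappingResult-class].
#' @export
mapLibrary <- function(library, assembly, maxMismatches = 2L) {
  seqs <- sequences(library)
  gr <- alignFullLength(seqs, assembly, maxMismatches)
  mmBySeq <- split(gr$mismatches, gr$seqId)
  minMM <- vapply(mmBySeq, min, integer(1))
  nBest <- mapply(function(mm, mn) sum(mm == mn), mmBySeq, minMM)
  nHits <- S4Vectors::elementNROWS(mmBySeq)
  gr$bestStratum <- gr$mismatches == unname(minMM[gr$seqId])
  status <- rep("unmapped", length(seqs))
  names(status) <- seqs
  hit <- names(mmBySeq)
  status[hit] <- ifelse(nBest[hit] == 1L, "unique", "multi")
  st <- DataFrame(
    sequence = seqs,
    nHits = ifelse(seqs %in% hit, as.integer(nHits[seqs]), 0L),
    nBestHits = ifelse(seqs %in% hit, as.integer(nBest[seqs]), 0L),
    status = unname(status))
  new("MappingResult", hits = gr, status = st,
      maxMismatches = as.integer(maxMismatches))
}

#' Split a library by genome mappability
#'
#' Partitions the library into the sequences that map to the assembly within
#' the mismatch budget and those that do not; the partition conserves the
#' read multiset.
#'
#' @param library a [SmallRNALibrary-class].
#' @param assembly named [Biostrings::DNAStringSet].
#' @param maxMismatches mismatch budget (default 2).
#' @param mapping optional precomputed [MappingResult-class] for `library`.
#' @return list with elements `mapped`, `unmapped` (both `SmallRNALibrary`)
#'   and `mapping` (the `MappingResult`).
#' @export
splitByGenomeMapping <- function(library, assembly, maxMismatches = 2L,
                                 mapping = NULL) {
  if (is.null(mapping))
    mapping <- mapLibrary(library, assembly, maxMismatches)
  st <- mappingStatus(mapping)
  mappedSeqs <- st$sequence[st$status != "unmapped"]
  list(mapped = subsetLibrary(library, mappedSeqs),
       unmapped = subsetLibrary(library,
                                setdiff(sequences(library), mappedSeqs)),
       mapping = mapping)
}
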