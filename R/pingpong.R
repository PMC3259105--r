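#' Enumerate opposite-strand 5'-overlap pairs
#'
#' All (plus, minus) hit pairs on the same contig that share at least one
#' genomic position are returned; a sequence may participate in many pairs.
#' The overlap length is the ping-pong convention
#' `minus fivePrime - plus fivePrime + 1`, i.e. the number of bases between
#' the two 5' ends inclusive; the amplification signature is exactly 10.
#' Pairs with overlap < 1 (the minus 5' end upstream of the plus 5' end) are
#' excluded.
#'
#' @param hitsGr `GRanges` of hits with `seqId` and `fivePrime` metadata
#'   columns (typically [uniqueHits()] of a piRNA-class mapping).
#' @param minLen only reads at least this long participate (default 24).
#' @return data.frame with one row per pair: `contig`, `plusSeq`, `minusSeq`,
#'   `plusFivePrime`, `minusFivePrime`, `overlap`.
#' @export
enumerateOverlapPairs <- function(hitsGr, minLen = 24L) {
  hitsGr <- hitsGr[width(hitsGr) >= minLen]
  plus <- hitsGr[as.character(strand(hitsGr)) == "+"]
  minus <- hitsGr[as.character(strand(hitsGr)) == "-"]
  empty <- data.frame(contig = character(), plusSeq = character(),
                      minusSeq = character(), plusFivePrime = integer(),
                      minusFivePrime = integer(), overlap = integer())
  if (!length(plus) || !length(minus)) return(empty)
  ov <- findOverlaps(granges(plus), granges(minus), ignore.strand = TRUE)
  if (!length(ov)) return(empty)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  overlap <- minus$fivePrime[si] - plus$fivePrime[qi] + 1L
  keep <- overlap >= 1L
  data.frame(
    contig = as.character(seqnames(plus))[qi[keep]],
    plusSeq = plus$seqId[qi[keep]],
    minusSeq = minus$seqId[si[keep]],
    plusFivePrime = plus$fivePrime[qi[keep]],
    minusFivePrime = minus$fivePrime[si[keep]],
    overlap = overlap[keep])
}

#' Histogram of 5'-overlap lengths
#'
#' @param pairs output of [enumerateOverlapPairs()].
#' @return named integer vector, overlap length -> pair count (empty for an
#'   empty pair set).
#' @export
overlapHistogram <- function(pairs) {
  if (!nrow(pairs)) return(stats::setNames(integer(0), character(0)))
  tab <- table(pairs$overlap)
  stats::setNames(as.integer(tab), names(tab))
}

#' Fraction of overlapping sequences with the signature overlap
#'
#' Numerator: distinct sequences participating in at least one pair of
#' exactly `signatureLen` overlap. Denominator: distinct sequences
#' participating in at least one pair of any overlap. With `weights`
#' (a named multiplicity vector) both sets are multiplicity-weighted
#' instead.
#'
#' @param pairs output of [enumerateOverlapPairs()].
#' @param signatureLen the ping-pong signature length (default 10).
#' @param weights optional named numeric vector of per-sequence read
#'   multiplicities.
#' @return a fraction in \[0, 1\], or `NA` (with a warning) when no sequence
#'   overlaps.
#' @export
signatureFraction <- function(pairs, signatureLen = 10L, weights = NULL) {
  if (!nrow(pairs)) {
    warning("no overlapping pairs: signature fraction undefined")
    return(NA_real_)
  }
  all <- unique(c(pairs$plusSeq, pairs$minusSeq))
  sig <- pairs$overlap == signatureLen
  hit <- unique(c(pairs$plusSeq[sig], pairs$minusSeq[sig]))
  if (is.null(weights)) length(hit) / length(all)
  else sum(weights[hit]) / sum(weights[all])
}

#' 5'-base composition of sequences in overlapping pairs
#'
#' For each overlap length, the relative frequency of the 5' base over the
#' distinct sequences participating in pairs of that length. T is reported
#' as U (RNA convention for outputs).
#'
#' @param pairs output of [enumerateOverlapPairs()].
#' @return numeric matrix with one row per overlap length present and
#'   columns `A`, `C`, `G`, `U`; each row sums to 1.
#' @export
baseComposition <- function(pairs) {
  lens <- sort(unique(pairs$overlap))
  mat <- matrix(0, nrow = length(lens), ncol = 4L,
                dimnames = list(as.character(lens), c("A", "C", "G", "U")))
  for (i in seq_along(lens)) {
    sel <- pairs$overlap == lens[i]
    seqs <- unique(c(pairs$plusSeq[sel], pairs$minusSeq[sel]))
    b5 <- chartr("T", "U", substr(seqs, 1L, 1L))
    tab <- table(factor(b5, levels = c("A", "C", "G", "U")))
    mat[i, ] <- as.numeric(tab) / sum(tab)
  }
  mat
}

#' Per-position base composition of a sequence set
#'
#' Relative nucleotide frequencies at each read position (frequencies at
#' position p are over the sequences at least p long). T is reported as U.
#'
#' @param seqs character vector of sequences.
#' @return numeric matrix positions x `A`,`C`,`G`,`U`; rows sum to 1.
#' @export
positionBaseMatrix <- function(seqs) {
  seqs <- as.character(seqs)
  maxLen <- max(nchar(seqs))
  mat <- matrix(0, nrow = maxLen, ncol = 4L,
                dimnames = list(seq_len(maxLen), c("A", "C", "G", "U")))
  for (p in seq_len(maxLen)) {
    b <- substr(seqs[nchar(seqs) >= p], p, p)
    tab <- table(factor(chartr("T", "U", b), levels = c("A", "C", "G", "U")))
    mat[p, ] <- as.numeric(tab) / sum(tab)
  }
  mat
}

#' U1/A10 flag for overlap pairs
#'
#' A pair carries the U1/A10 ping-pong mark when one mate begins with U (T)
#' and the other mate has A at its 10th position, each read in its own
#' 5'->3' orientation. Mates shorter than 10 nt on the A10 side yield
#' `FALSE`.
#'
#' @param pairs output of [enumerateOverlapPairs()].
#' @return logical vector, one element per pair.
#' @export
u1a10Flag <- function(pairs) {
  b1p <- substr(pairs$plusSeq, 1L, 1L)
  b1m <- substr(pairs$minusSeq, 1L, 1L)
  a10p <- nchar(pairs$plusSeq) >= 10L & substr(pairs$plusSeq, 10L, 10L) == "A"
  a10m <- nchar(pairs$minusSeq) >= 10L & substr(pairs$minusSeq, 10L, 10L) == "A"
  (b1p == "T" & a10m) | (b1m == "T" & a10p)
}

#' Build an overlap profile
#'
#' Convenience wrapper assembling the histogram, base-composition matrix and
#' signature fraction of a hit set into an [OverlapProfile-class].
#'
#' @inheritParams enumerateOverlapPairs
#' @inheritParams signatureFraction
#' @return an [OverlapProfile-class].
#' @export
overlapProfile <- function(hitsGr, minLen = 24L, signatureLen = 10L,
                           weights = NULL) {
  pairs <- enumerateOverlapPairs(hitsGr, minLen)
  sf <- if (nrow(pairs)) signatureFraction(pairs, signatureLen, weights)
        else NA_real_
  new("OverlapProfile",
      histogram = overlapHistogram(pairs),
      baseFreq = baseComposition(pairs),
      signatureFraction = sf,
      signatureLength = as.integer(signatureLen),
      nPairs = nrow(pairs))
}

#' Per-element small-RNA density map
#'
#' Maps a library onto one element (e.g. a TE consensus) and tabulates, per
#' element position, the number of distinct sequences whose 5' end falls
#' there on the sense and antisense strands, and the number of U1/A10
#' signature pairs whose 10-nt overlap midpoint falls there.
#'
#' @param element a length-1 named [Biostrings::DNAStringSet].
#' @param library a [SmallRNALibrary-class].
#' @param maxMismatches mapping budget onto the element (default 2).
#' @param minLen minimum read length for the pair analysis (default 24).
#' @return data.frame with columns `position`, `senseDepth`,
#'   `antisenseDepth`, `u1a10Pairs` (one row per element position).
#' @export
densityMap <- function(element, library, maxMismatches = 2L, minLen = 24L) {
  stopifnot(length(element) == 1L, !is.null(names(element)))
  L <- width(element)[1L]
  gr <- alignFullLength(sequences(library), element, maxMismatches)
  sense <- gr[as.character(strand(gr)) == "+"]
  anti <- gr[as.character(strand(gr)) == "-"]
  depth <- function(h) {
    d <- integer(L)
    if (length(h)) {
      keep <- !duplicated(paste(h$seqId, h$fivePrime))
      tab <- table(h$fivePrime[keep])
      d[as.integer(names(tab))] <- as.integer(tab)
    }
    d
  }
  pairs <- enumerateOverlapPairs(gr, minLen)
  u1a10 <- integer(L)
  if (nrow(pairs)) {
    flag <- u1a10Flag(pairs) & pairs$overlap == 10L
    mid <- pairs$plusFivePrime[flag] + 4L  # centre of the 10-nt overlap
    mid <- mid[mid >= 1L & mid <= L]
    tab <- table(mid)
    u1a10[as.integer(names(tab))] <- as.integer(tab)
  }
  data.frame(position = seq_len(L), senseDepth = depth(sense),
             antisenseDepth = depth(anti), u1a10Pairs = u1a10)
}
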