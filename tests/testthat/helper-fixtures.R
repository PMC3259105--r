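suppressPackageStartupMessages({
  library(Biostrings)
  library(GenomicRanges)
  library(IRanges)
})

# random genome as a named DNAStringSet
randGenome <- function(lengths, seed) {
  set.seed(seed)
  ss <- DNAStringSet(vapply(lengths, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    ""))
  names(ss) <- if (!is.null(names(lengths))) names(lengths)
               else paste0("ctg", seq_along(lengths))
  ss
}

# reads sampled from a genome (exact substrings, optionally mutated and
# strand-flipped)
sampleReads <- function(genome, n, lenRange = 24:31, pMutate = 0,
                        maxMut = 2L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    ci <- sample.int(length(genome), 1L)
    L <- if (length(lenRange) == 1L) lenRange else sample(lenRange, 1L)
    p <- sample.int(width(genome)[ci] - L, 1L)
    s <- as.character(subseq(genome[[ci]], p, p + L - 1L))
    if (pMutate > 0 && runif(1) < pMutate) {
      k <- sample.int(maxMut, 1L)
      pos <- sample.int(L, k)
      ch <- strsplit(s, "")[[1]]
      ch[pos] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
      s <- paste(ch, collapse = "")
    }
    if (runif(1) < 0.5) s
    else as.character(reverseComplement(DNAString(s)))
  }, "")
}

# exhaustive-scan mapping oracle via vmatchPattern (independent of the
# package's pigeonhole path)
oracleHits <- function(seqs, refs, mm) {
  out <- list()
  for (s in unique(seqs)) for (str in c("+", "-")) {
    pat <- if (str == "+") s
           else as.character(reverseComplement(DNAString(s)))
    m <- vmatchPattern(pat, refs, max.mismatch = mm, fixed = TRUE)
    for (ci in seq_along(refs)) {
      ir <- m[[ci]]
      ir <- ir[width(ir) == nchar(s) & start(ir) >= 1L &
               end(ir) <= width(refs)[ci]]
      if (length(ir))
        out[[length(out) + 1L]] <- data.frame(
          ctg = names(refs)[ci], start = start(ir), strand = str, seq = s)
    }
  }
  if (!length(out))
    return(data.frame(ctg = character(), start = integer(),
                      strand = character(), seq = character()))
  df <- unique(do.call(rbind, out))
  df <- df[order(df$ctg, df$start, df$strand, df$seq), , drop = FALSE]
  rownames(df) <- NULL
  df
}

hitsAsDf <- function(gr) {
  df <- unique(data.frame(ctg = as.character(seqnames(gr)),
                          start = start(gr),
                          strand = as.character(strand(gr)),
                          seq = gr$seqId))
  df <- df[order(df$ctg, df$start, df$strand, df$seq), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# GRanges of hits from explicit placements
hitGr <- function(contig, start, len, strand, seq = NULL) {
  gr <- GRanges(contig, IRanges(start, width = len), strand = strand)
  gr$seqId <- if (is.null(seq)) paste0("s", seq_along(gr)) else seq
  gr$fivePrime <- ifelse(as.character(strand(gr)) == "-", end(gr),
                         start(gr))
  gr
}

# O(n^2) all-pairs overlap oracle
oraclePairs <- function(gr, minLen = 24L) {
  gr <- gr[width(gr) >= minLen]
  plus <- gr[as.character(strand(gr)) == "+"]
  minus <- gr[as.character(strand(gr)) == "-"]
  out <- list()
  for (i in seq_along(plus)) for (j in seq_along(minus)) {
    if (as.character(seqnames(plus))[i] != as.character(seqnames(minus))[j])
      next
    if (start(minus)[j] > end(plus)[i] || end(minus)[j] < start(plus)[i])
      next  # no shared position
    ov <- minus$fivePrime[j] - plus$fivePrime[i] + 1L
    if (ov < 1L) next
    out[[length(out) + 1L]] <- data.frame(
      contig = as.character(seqnames(plus))[i],
      plusSeq = plus$seqId[i], minusSeq = minus$seqId[j],
      plusFivePrime = plus$fivePrime[i],
      minusFivePrime = minus$fivePrime[j], overlap = ov)
  }
  if (!length(out))
    return(data.frame(contig = character(), plusSeq = character(),
                      minusSeq = character(), plusFivePrime = integer(),
                      minusFivePrime = integer(), overlap = integer()))
  do.call(rbind, out)
}

sortPairs <- function(df) {
  df <- df[order(df$contig, df$plusSeq, df$minusSeq, df$plusFivePrime,
                 df$minusFivePrime, df$overlap), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# two-sided 99% binomial band half-width for an observed proportion
binomBand99 <- function(p, n) 2.576 * sqrt(p * (1 - p) / n)
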