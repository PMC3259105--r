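#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom BiocGenerics start end width strand
NULL

#' SmallRNALibrary: a collapsed small-RNA sequencing library
#'
#' Holds the distinct small-RNA sequences of one library together with their
#' read multiplicities. Sequences are stored in the DNA alphabet (U is
#' normalised to T on construction) and each distinct sequence appears exactly
#' once, with a multiplicity of at least 1.
#'
#' @slot id library identifier.
#' @slot species species label (free text).
#' @slot line mosquito line / transformation plasmid label.
#' @slot replicateGroup replicate-group label; libraries sequenced from the
#'   same line share a group and are never paired in capture-recapture
#'   estimation.
#' @slot reads a [S4Vectors::DataFrame] with columns `sequence` (character)
#'   and `count` (integer multiplicity).
#'
#' @seealso [SmallRNALibrary()] for the constructor,
#'   [readSmallRNA()] to build one from FASTA/FASTQ.
#' @export
setClass("SmallRNALibrary",
  slots = c(
    id = "character",
    species = "character",
    line = "character",
    replicateGroup = "character",
    reads = "DataFrame"
  )
)

setValidity("SmallRNALibrary", function(object) {
  rd <- object@reads
  msg <- character()
  if (!all(c("sequence", "count") %in% colnames(rd)))
    msg <- c(msg, "'reads' must have columns 'sequence' and 'count'")
  else {
    if (anyDuplicated(rd$sequence))
      msg <- c(msg, "duplicated sequence strings in one library")
    if (length(rd$count) && any(rd$count < 1L))
      msg <- c(msg, "multiplicities must be >= 1")
    if (length(rd$sequence) && any(grepl("[^ACGT]", rd$sequence)))
      msg <- c(msg, "sequences must be over {A,C,G,T}")
  }
  if (length(object@id) != 1L) msg <- c(msg, "'id' must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a SmallRNALibrary
#'
#' Identical sequence strings are collapsed into a single entry with summed
#' multiplicity; `U` is normalised to `T`. The result is independent of the
#' input order.
#'
#' @param sequences character vector of read sequences (RNA or DNA alphabet).
#' @param counts integer multiplicities, recycled to `length(sequences)`;
#'   default 1 per record.
#' @param id,species,line,replicateGroup library metadata strings.
#' @return a [SmallRNALibrary-class] object.
#' @examples
#' lib <- SmallRNALibrary(c("UACGUACGUACGUACGUACGUACG", "TACGTACGTACGTACGTACGTACG"))
#' nReads(lib)       # 2 reads
#' nSequences(lib)   # collapsed to 1 distinct sequence
#' @export
SmallRNALibrary <- function(sequences, counts = rep(1L, length(sequences)),
                            id = "lib", species = NA_character_,
                            line = NA_character_,
                            replicateGroup = id) {
  stopifnot(length(counts) == length(sequences))
  sequences <- toupper(chartr("U", "T", as.character(sequences)))
  counts <- as.integer(counts)
  keep <- counts > 0L
  sequences <- sequences[keep]
  counts <- counts[keep]
  agg <- rowsum(counts, group = sequences, reorder = TRUE)
  rd <- DataFrame(sequence = rownames(agg), count = as.integer(agg[, 1L]))
  rownames(rd) <- NULL
  new("SmallRNALibrary", id = id, species = species, line = line,
      replicateGroup = replicateGroup, reads = rd)
}

#' @describeIn SmallRNALibrary library identifier
#' @param x a `SmallRNALibrary`
#' @export
libId <- function(x) x@id

#' @describeIn SmallRNALibrary replicate-group label
#' @export
replicateGroup <- function(x) x@replicateGroup

#' @describeIn SmallRNALibrary distinct sequences (character vector)
#' @export
sequences <- function(x) x@reads$sequence

#' @describeIn SmallRNALibrary named integer vector of multiplicities
#' @export
readCounts <- function(x) {
  stats::setNames(x@reads$count, x@reads$sequence)
}

#' @describeIn SmallRNALibrary total read count (sum of multiplicities)
#' @export
nReads <- function(x) sum(x@reads$count)

#' @describeIn SmallRNALibrary number of distinct sequences
#' @export
nSequences <- function(x) nrow(x@reads)

#' Subset a library to a set of sequences
#'
#' @param x a [SmallRNALibrary-class]
#' @param keep character vector of sequences, or a logical/integer index over
#'   `sequences(x)`.
#' @return a new `SmallRNALibrary` with the same metadata.
#' @export
subsetLibrary <- function(x, keep) {
  if (is.character(keep)) keep <- x@reads$sequence %in% keep
  initialize(x, reads = x@reads[keep, , drop = FALSE])
}

setMethod("show", "SmallRNALibrary", function(object) {
  cat("SmallRNALibrary '", object@id, "' (", object@species, ", line ",
      object@line, ")\n", sep = "")
  cat("  ", nSequences(object), " distinct sequences / ",
      nReads(object), " reads\n", sep = "")
  if (nSequences(object) > 0) {
    w <- nchar(object@reads$sequence)
    cat("  length range: ", min(w), "-", max(w), " nt\n", sep = "")
  }
})

#' MappingResult: placements of a library on a reference
#'
#' The result of [mapLibrary()]: every full-length ungapped placement of every
#' distinct sequence within the mismatch budget, plus a per-sequence
#' uniqueness classification.
#'
#' @slot hits a [GenomicRanges::GRanges] with metadata columns `seqId`
#'   (the sequence string), `mismatches`, `fivePrime` (1-based genomic
#'   coordinate of the read's 5' base: `start` on `+`, `end` on `-`) and
#'   `bestStratum` (logical: hit belongs to that sequence's minimum-mismatch
#'   stratum).
#' @slot status a [S4Vectors::DataFrame] with columns `sequence`, `nHits`,
#'   `nBestHits`, `status` (one of `unique`, `multi`, `unmapped`).
#' @slot maxMismatches the mismatch budget used.
#' @export
setClass("MappingResult",
  slots = c(hits = "GRanges", status = "DataFrame", maxMismatches = "integer")
)

setValidity("MappingResult", function(object) {
  st <- object@status
  msg <- character()
  if (!all(c("sequence", "nHits", "nBestHits", "status") %in% colnames(st)))
    msg <- c(msg, "'status' must have sequence/nHits/nBestHits/status columns")
  else {
    bad <- (st$status == "unique" & st$nBestHits != 1L) |
           (st$status == "unmapped" & st$nHits != 0L) |
           (st$status == "multi" & st$nBestHits < 2L)
    if (any(bad)) msg <- c(msg, "status inconsistent with hit strata")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn MappingResult all retained hits (GRanges)
#' @param x a `MappingResult`
#' @export
hits <- function(x) x@hits

#' @describeIn MappingResult per-sequence status table
#' @export
mappingStatus <- function(x) x@status

#' @describeIn MappingResult best-stratum hits of uniquely mapping sequences
#' @export
uniqueHits <- function(x) {
  uq <- x@status$sequence[x@status$status == "unique"]
  h <- x@hits[x@hits$bestStratum & x@hits$seqId %in% uq]
  h
}

setMethod("show", "MappingResult", function(object) {
  st <- table(factor(object@status$status,
                     levels = c("unique", "multi", "unmapped")))
  cat("MappingResult: ", length(object@hits), " hits over ",
      nrow(object@status), " sequences (budget ", object@maxMismatches,
      " mismatches)\n", sep = "")
  cat("  unique: ", st[["unique"]], "  multi: ", st[["multi"]],
      "  unmapped: ", st[["unmapped"]], "\n", sep = "")
})

#' OverlapProfile: opposite-strand 5'-overlap statistics
#'
#' Summary of ping-pong geometry over a set of genomic hits: the histogram of
#' 5'-overlap lengths between plus- and minus-strand reads sharing at least
#' one genomic position, per-overlap-length 5'-base composition, and the
#' fraction of overlapping sequences engaged in the 10-nt signature overlap.
#'
#' @slot histogram named integer vector: overlap length -> pair count.
#' @slot baseFreq numeric matrix, one row per overlap length, columns
#'   `A`,`C`,`G`,`U`: relative 5'-base frequency of the distinct sequences
#'   participating in pairs of that overlap length (rows sum to 1).
#' @slot signatureFraction fraction of distinct overlapping sequences with at
#'   least one signature-length overlap (`NA` when no sequence overlaps).
#' @slot signatureLength the signature overlap length (10 by default).
#' @slot nPairs total number of pairs.
#' @export
setClass("OverlapProfile",
  slots = c(histogram = "integer", baseFreq = "matrix",
            signatureFraction = "numeric", signatureLength = "integer",
            nPairs = "integer")
)

setMethod("show", "OverlapProfile", function(object) {
  cat("OverlapProfile: ", object@nPairs, " opposite-strand pairs\n", sep = "")
  sf <- object@signatureFraction
  cat("  ", object@signatureLength, "-nt signature fraction: ",
      ifelse(is.na(sf), "undefined (no overlapping sequences)",
             sprintf("%.3f", sf)), "\n", sep = "")
  if (length(object@histogram)) {
    top <- sort(object@histogram, decreasing = TRUE)[1]
    cat("  modal overlap: ", names(top), " nt (", top, " pairs)\n", sep = "")
  }
})

#' PoolEstimate: capture-recapture estimate of sequence-pool diversity
#'
#' Per-pair Lincoln-Petersen estimates of the latent piRNA sequence-pool size
#' with their mean/min/max summary. Pairs with zero overlap are dropped (and
#' counted in `nDropped`).
#'
#' @slot pairs a [S4Vectors::DataFrame] with columns `libA`, `libB`, `nA`,
#'   `nB`, `k`, `estimate`.
#' @slot mean,minimum,maximum summary over the defined per-pair estimates.
#' @slot nPairs number of defined (k > 0) pair estimates.
#' @slot nDropped number of pairs dropped for k = 0.
#' @export
setClass("PoolEstimate",
  slots = c(pairs = "DataFrame", mean = "numeric", minimum = "numeric",
            maximum = "numeric", nPairs = "integer", nDropped = "integer")
)

setValidity("PoolEstimate", function(object) {
  if (object@nPairs > 0 &&
      !(object@minimum <= object@mean && object@mean <= object@maximum))
    "min <= mean <= max violated" else TRUE
})

#' @describeIn PoolEstimate per-pair estimate table
#' @param x a `PoolEstimate`
#' @export
pairEstimates <- function(x) x@pairs

#' @describeIn PoolEstimate mean of the per-pair estimates
#' @export
poolMean <- function(x) x@mean

#' @describeIn PoolEstimate range of the per-pair estimates
#' @export
poolRange <- function(x) c(minimum = x@minimum, maximum = x@maximum)

setMethod("show", "PoolEstimate", function(object) {
  cat("PoolEstimate over ", object@nPairs, " library pairs",
      if (object@nDropped) paste0(" (", object@nDropped, " dropped, k = 0)"),
      "\n", sep = "")
  cat(sprintf("  mean %.4g  (min %.4g, max %.4g)\n",
              object@mean, object@minimum, object@maximum))
})
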