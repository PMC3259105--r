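#' @importFrom GenomicRanges findOverlaps countOverlaps distanceToNearest
#'   coverage
#' @importFrom IRanges Views viewSums subsetByOverlaps
#' @importFrom stats sd rbinom rmultinom runif rlnorm
NULL

# half-up decimal rounding (printed-table convention; base round() is
# round-half-even)
roundHalfUp <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Windowed counts of uniquely mapping piRNAs
#'
#' Tiles each contig with non-overlapping windows of `windowSize` bp and
#' counts, per window, the number of distinct uniquely mapping sequences
#' whose 5' coordinate falls in the window (window index
#' `(fivePrime - 1) %/% windowSize`, 0-based). Counts are of distinct
#' sequences, not read multiplicities.
#'
#' @param uniqueHits `GRanges` of best-stratum hits of uniquely mapping
#'   piRNA-class sequences (see [uniqueHits()]), with `seqId` and
#'   `fivePrime` metadata columns.
#' @param windowSize window width in bp (default 5000).
#' @return data.frame with columns `contig`, `window` (0-based index) and
#'   `count`, containing only non-empty windows.
#' @export
windowCounts <- function(uniqueHits, windowSize = 5000L) {
  if (!length(uniqueHits))
    return(data.frame(contig = character(), window = integer(),
                      count = integer()))
  contig <- as.character(seqnames(uniqueHits))
  win <- (uniqueHits$fivePrime - 1L) %/% as.integer(windowSize)
  key <- paste(contig, win, sep = "\r")
  distinct <- !duplicated(paste(key, uniqueHits$seqId, sep = "\r"))
  tab <- table(key[distinct])
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(
    contig = vapply(parts, `[`, "", 1L),
    window = as.integer(vapply(parts, `[`, "", 2L)),
    count = as.integer(tab))
  out[order(out$contig, out$window), , drop = FALSE]
}

#' Call piRNA clusters from windowed counts
#'
#' Maximal runs of consecutive qualifying windows (count >=
#' `minUniquePirnas`) become one cluster; non-contiguous qualifying windows
#' separated by more than `mergeGapWindows` empty/sub-threshold windows are
#' not collapsed (default 0: only adjacent windows merge). Cluster
#' boundaries are refined to the furthest member-read extents (min start /
#' max end of reads assigned to the run's windows). Clusters are ranked by
#' distinct-sequence count, descending (ties by contig name, then start).
#'
#' @param counts output of [windowCounts()].
#' @param uniqueHits the hits the counts were computed from.
#' @param windowSize window width in bp (default 5000).
#' @param minUniquePirnas qualification threshold (default 10).
#' @param mergeGapWindows number of sub-threshold windows allowed inside a
#'   cluster (default 0).
#' @return `GRanges` of refined clusters with metadata columns
#'   `uniquePirnaCount`, `rank`, `firstWindow`, `lastWindow`.
#' @export
callClusters <- function(counts, uniqueHits, windowSize = 5000L,
                         minUniquePirnas = 10L, mergeGapWindows = 0L) {
  windowSize <- as.integer(windowSize)
  qual <- counts[counts$count >= minUniquePirnas, , drop = FALSE]
  if (!nrow(qual)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(uniquePirnaCount = integer(0), rank = integer(0),
                           firstWindow = integer(0), lastWindow = integer(0))
    return(gr)
  }
  hctg <- as.character(seqnames(uniqueHits))
  hwin <- (uniqueHits$fivePrime - 1L) %/% windowSize
  rows <- list()
  for (ctg in unique(qual$contig)) {
    w <- sort(qual$window[qual$contig == ctg])
    runStart <- c(TRUE, diff(w) > mergeGapWindows + 1L)
    runId <- cumsum(runStart)
    for (r in unique(runId)) {
      wr <- w[runId == r]
      member <- hctg == ctg & hwin >= wr[1L] & hwin <= wr[length(wr)]
      mh <- uniqueHits[member]
      rows[[length(rows) + 1L]] <- data.frame(
        contig = ctg,
        start = min(start(mh)), end = max(end(mh)),
        uniquePirnaCount = length(unique(mh$seqId)),
        firstWindow = wr[1L], lastWindow = wr[length(wr)])
    }
  }
  df <- do.call(rbind, rows)
  o <- order(-df$uniquePirnaCount, df$contig, df$start, method = "radix")
  df <- df[o, , drop = FALSE]
  gr <- GRanges(df$contig, IRanges(df$start, df$end))
  mcols(gr) <- DataFrame(uniquePirnaCount = df$uniquePirnaCount,
                         rank = seq_len(nrow(df)),
                         firstWindow = df$firstWindow,
                         lastWindow = df$lastWindow)
  gr
}

# window-span interval of a cluster run (membership is by 5' coordinate)
clusterWindowSpan <- function(clusters, windowSize = 5000L) {
  GRanges(seqnames(clusters),
          IRanges(clusters$firstWindow * windowSize + 1L,
                  (clusters$lastWindow + 1L) * windowSize))
}

#' Per-cluster strand bias, library support and exclusivity
#'
#' Annotates clusters with: `plusFraction` (distinct plus-strand member
#' sequences over all distinct members), per-library proportions of member
#' read occurrences (multiplicity-weighted, columns `prop.<libId>`, summing
#' to 1 per cluster), `exclusiveFraction` (distinct members seen in exactly
#' one library) and `nearestClusterBp` (gap to the nearest other refined
#' cluster on the same contig; `NA` when alone).
#'
#' Membership is by the 5' coordinate of a sequence's single unique hit
#' falling in the cluster's window span.
#'
#' @param clusters output of [callClusters()].
#' @param mappings named list of [MappingResult-class], one per library
#'   (piRNA size class).
#' @param libraries named list of the matching [SmallRNALibrary-class]
#'   objects (for read multiplicities); same names as `mappings`.
#' @param windowSize window width used for calling (default 5000).
#' @return the input `GRanges` with the additional metadata columns.
#' @export
summarizeClusters <- function(clusters, mappings, libraries,
                              windowSize = 5000L) {
  stopifnot(identical(names(mappings), names(libraries)))
  span <- clusterWindowSpan(clusters, windowSize)
  libIds <- names(mappings)
  # per-library unique hits as 5' points
  hitTabs <- lapply(libIds, function(id) {
    h <- uniqueHits(mappings[[id]])
    cnt <- readCounts(libraries[[id]])
    data.frame(lib = id, seq = h$seqId,
               contig = as.character(seqnames(h)),
               fp = h$fivePrime,
               strand = as.character(strand(h)),
               mult = as.integer(cnt[h$seqId]))
  })
  all <- do.call(rbind, hitTabs)
  pts <- GRanges(all$contig, IRanges(all$fp, width = 1L))
  ov <- findOverlaps(pts, span)
  all$cluster <- NA_integer_
  all$cluster[S4Vectors::queryHits(ov)] <- S4Vectors::subjectHits(ov)

  n <- length(clusters)
  plusFraction <- rep(NA_real_, n)
  exclusiveFraction <- rep(NA_real_, n)
  prop <- matrix(0, nrow = n, ncol = length(libIds),
                 dimnames = list(NULL, libIds))
  for (ci in seq_len(n)) {
    m <- all[!is.na(all$cluster) & all$cluster == ci, , drop = FALSE]
    if (!nrow(m)) next
    perSeqStrand <- m$strand[!duplicated(m$seq)]
    plusFraction[ci] <- mean(perSeqStrand == "+")
    occ <- tapply(m$mult, factor(m$lib, levels = libIds), sum,
                  default = 0L)
    prop[ci, ] <- occ / sum(occ)
    nLibs <- tapply(m$lib, m$seq, function(l) length(unique(l)))
    exclusiveFraction[ci] <- mean(nLibs == 1L)
  }
  nearest <- rep(NA_integer_, n)
  if (n > 1L) {
    dn <- distanceToNearest(clusters)
    nearest[S4Vectors::queryHits(dn)] <- mcols(dn)$distance
  }
  clusters$plusFraction <- plusFraction
  clusters$exclusiveFraction <- exclusiveFraction
  clusters$nearestClusterBp <- nearest
  mcols(clusters) <- cbind(mcols(clusters),
                           DataFrame(prop = I(prop)))
  clusters
}

#' Random-interval transposon-content null model for one cluster
#'
#' Compares the cluster's TE base coverage and TE element count with
#' `nSamples` random genomic intervals of exactly the cluster's length,
#' sampled uniformly over all valid (contig, offset) placements. Reports
#' z-scores (sample sd, n-1) and empirical two-sided p-values.
#'
#' @param cluster a length-1 `GRanges`.
#' @param teFeatures `GRanges` of TE annotations.
#' @param assembly named [Biostrings::DNAStringSet].
#' @param nSamples number of random intervals (default 1000, >= 2).
#' @param seed integer seed (mandatory: the null is Monte-Carlo).
#' @return one-row data.frame with observed/null-mean/sd/z/p for coverage
#'   and element count, plus `nSamples` and `seed`. When the null sd is 0
#'   the z-score is `NA` and `degenerate` is `TRUE`.
#' @export
teNullZscores <- function(cluster, teFeatures, assembly, nSamples = 1000L,
                          seed) {
  stopifnot(length(cluster) == 1L, nSamples >= 2L)
  L <- width(cluster)
  lens <- width(assembly)
  valid <- pmax(0L, lens - L + 1L)
  if (all(valid == 0L)) stop("no contig is at least as long as the cluster")
  teRed <- reduce(teFeatures, ignore.strand = TRUE)
  cov <- coverage(teRed)
  obsCover <- covFraction(cluster, cov, L)
  obsCount <- countOverlaps(cluster, teFeatures, ignore.strand = TRUE)
  set.seed(as.integer(seed))
  ctg <- sample.int(length(assembly), nSamples, replace = TRUE,
                    prob = valid / sum(valid))
  off <- floor(runif(nSamples) * valid[ctg]) + 1L
  rand <- GRanges(names(assembly)[ctg], IRanges(off, width = L))
  nullCover <- covFraction(rand, cov, L)
  nullCount <- countOverlaps(rand, teFeatures, ignore.strand = TRUE)
  zp <- function(obs, null) {
    s <- sd(null)
    z <- if (s > 0) (obs - mean(null)) / s else NA_real_
    lo <- (sum(null <= obs) + 1) / (length(null) + 1)
    hi <- (sum(null >= obs) + 1) / (length(null) + 1)
    c(z = z, p = min(1, 2 * min(lo, hi)), degenerate = as.numeric(s == 0))
  }
  zc <- zp(obsCover, nullCover)
  zn <- zp(obsCount, nullCount)
  data.frame(
    teCoverage = obsCover, nullMeanCoverage = mean(nullCover),
    nullSdCoverage = sd(nullCover), zCoverage = zc[["z"]],
    pCoverage = zc[["p"]],
    teElementCount = as.integer(obsCount), nullMeanCount = mean(nullCount),
    nullSdCount = sd(nullCount), zCount = zn[["z"]], pCount = zn[["p"]],
    degenerate = zc[["degenerate"]] == 1 || zn[["degenerate"]] == 1,
    nSamples = as.integer(nSamples), seed = as.integer(seed))
}

# fraction of each interval's bases covered by an RleList coverage
covFraction <- function(gr, cov, L) {
  ctg <- as.character(seqnames(gr))
  out <- numeric(length(gr))
  for (ct in unique(ctg)) {
    i <- ctg == ct
    if (!ct %in% names(cov)) next
    rl <- cov[[ct]]
    s <- pmin(start(gr)[i], length(rl))
    e <- pmin(end(gr)[i], length(rl))
    out[i] <- viewSums(Views(rl, s, e))
  }
  out / width(gr)
}

#' Genome and piRNA coverage of the called clusters
#'
#' @param clusters refined cluster `GRanges`.
#' @param assembly named [Biostrings::DNAStringSet].
#' @param uniqueHits `GRanges` of unique piRNA hits (the input to the scan).
#' @return list with `genomeFraction` (total cluster span over total
#'   assembly length) and `pirnaFraction` (distinct uniquely mapping
#'   sequences with 5' inside a cluster, over all distinct uniquely mapping
#'   sequences). Both 0 when there are no clusters.
#' @export
coverageSummary <- function(clusters, assembly, uniqueHits) {
  if (!length(clusters))
    return(list(genomeFraction = 0, pirnaFraction = 0))
  genomeFraction <- sum(width(reduce(clusters))) / sum(width(assembly))
  pts <- GRanges(seqnames(uniqueHits), IRanges(uniqueHits$fivePrime, width = 1L))
  inside <- countOverlaps(pts, clusters) > 0L
  pirnaFraction <- length(unique(uniqueHits$seqId[inside])) /
    length(unique(uniqueHits$seqId))
  list(genomeFraction = genomeFraction, pirnaFraction = pirnaFraction)
}

#' Cluster report table (printed-table conventions)
#'
#' One row per cluster with 1-based inclusive start/stop, size in kb
#' (half-up rounded), distinct-sequence count, distance to the nearest
#' cluster in kb, per-library proportions and the fraction of members unique
#' to one library.
#'
#' @param clusters output of [summarizeClusters()].
#' @return data.frame ordered by rank.
#' @export
clusterTable <- function(clusters) {
  df <- data.frame(
    clusterId = clusters$rank,
    contig = as.character(seqnames(clusters)),
    start = start(clusters), stop = end(clusters),
    sizeKb = roundHalfUp(width(clusters) / 1000),
    uniquePirnas = clusters$uniquePirnaCount)
  if (!is.null(clusters$nearestClusterBp))
    df$nearestClusterKb <- roundHalfUp(clusters$nearestClusterBp / 1000)
  if (!is.null(clusters$exclusiveFraction))
    df$pctExclusiveOneLibrary <- roundHalfUp(100 * clusters$exclusiveFraction)
  if (!is.null(clusters$plusFraction))
    df$plusFraction <- roundHalfUp(clusters$plusFraction, 3L)
  df[order(df$clusterId), , drop = FALSE]
}
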