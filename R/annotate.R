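#' Classify mapped sequences by annotation target
#'
#' A sequence is `gene` if at least one retained hit overlaps a gene feature
#' by >= 1 bp, `TE` likewise for transposon features, `both` when both hold,
#' and `neither` otherwise; the categories partition the mapped set. A
#' per-length-class contingency table is attached.
#'
#' @param mapping a [MappingResult-class].
#' @param geneFeatures,teFeatures `GRanges` annotations (strand ignored for
#'   overlap).
#' @return list with `category` (named character vector per mapped sequence)
#'   and `table` (length x category counts of distinct sequences).
#' @export
classifyTargets <- function(mapping, geneFeatures, teFeatures) {
  h <- hits(mapping)
  inGene <- countOverlaps(h, geneFeatures, ignore.strand = TRUE) > 0L
  inTe <- countOverlaps(h, teFeatures, ignore.strand = TRUE) > 0L
  seqGene <- unique(h$seqId[inGene])
  seqTe <- unique(h$seqId[inTe])
  mapped <- mappingStatus(mapping)
  mapped <- mapped$sequence[mapped$status != "unmapped"]
  cat <- ifelse(mapped %in% seqGene,
                ifelse(mapped %in% seqTe, "both", "gene"),
                ifelse(mapped %in% seqTe, "TE", "neither"))
  names(cat) <- mapped
  lens <- nchar(mapped)
  tab <- table(length = lens,
               category = factor(cat, levels = c("gene", "TE", "both",
                                                 "neither")))
  list(category = cat, table = tab)
}

#' Genome base occupancy by annotation category
#'
#' Classifies every assembly base as gene-only, TE-only, both or neither;
#' the four fractions sum to 1.
#'
#' @param geneFeatures,teFeatures `GRanges` annotations.
#' @param assembly named [Biostrings::DNAStringSet].
#' @return named numeric vector `gene`, `TE`, `both`, `neither`.
#' @export
genomeOccupancy <- function(geneFeatures, teFeatures, assembly) {
  total <- sum(as.numeric(width(assembly)))
  g <- reduce(geneFeatures, ignore.strand = TRUE)
  t <- reduce(teFeatures, ignore.strand = TRUE)
  bothGr <- GenomicRanges::intersect(g, t, ignore.strand = TRUE)
  both <- sum(as.numeric(width(bothGr)))
  gene <- sum(as.numeric(width(g))) - both
  te <- sum(as.numeric(width(t))) - both
  c(gene = gene, TE = te, both = both,
    neither = total - gene - te - both) / total
}

#' Tally sequences matching TE family consensus sequences
#'
#' Each distinct sequence counts toward a family when it matches the family
#' consensus full-length on either strand within the mismatch budget; a
#' sequence matching several families counts once per family, and once
#' toward the TE total. Both read-multiplicity-weighted and
#' distinct-sequence tallies are reported, with percentages of the library
#' total (half-up, 2 decimals) recomputed from the emitted counts.
#'
#' @param library a size-class [SmallRNALibrary-class] (e.g. the piRNA
#'   class).
#' @param teConsensus named [Biostrings::DNAStringSet] of family consensus
#'   sequences.
#' @param classes character vector parallel to `teConsensus` assigning each
#'   family to `retrotransposon`, `DNA`, `MITE` or `other`.
#' @param maxMismatches matching budget (default 2).
#' @return list with `families` (per-family data.frame) and `classes`
#'   (Total/TE/per-class data.frame with `reads`, `distinct`, `pctReads`,
#'   `pctDistinct`).
#' @export
tallyTeFamilies <- function(library, teConsensus, classes,
                            maxMismatches = 2L) {
  stopifnot(length(classes) == length(teConsensus),
            !is.null(names(teConsensus)))
  counts <- readCounts(library)
  gr <- alignFullLength(sequences(library), teConsensus, maxMismatches)
  fam <- names(teConsensus)
  hitFam <- unique(data.frame(seq = gr$seqId,
                              family = as.character(seqnames(gr))))
  perFam <- do.call(rbind, lapply(fam, function(f) {
    s <- hitFam$seq[hitFam$family == f]
    data.frame(family = f, class = classes[match(f, fam)],
               reads = as.integer(sum(counts[s])),
               distinct = length(s))
  }))
  teSeqs <- unique(hitFam$seq)
  clsLevels <- c("retrotransposon", "DNA", "MITE", "other")
  perClass <- do.call(rbind, lapply(clsLevels, function(cl) {
    s <- unique(hitFam$seq[classes[match(hitFam$family, fam)] == cl])
    data.frame(category = cl, reads = as.integer(sum(counts[s])),
               distinct = length(s))
  }))
  top <- data.frame(
    category = c("Total", "TE"),
    reads = as.integer(c(sum(counts), sum(counts[teSeqs]))),
    distinct = c(length(counts), length(teSeqs)))
  cls <- rbind(top, perClass)
  cls$pctReads <- roundHalfUp(100 * cls$reads / cls$reads[1L], 2L)
  cls$pctDistinct <- roundHalfUp(100 * cls$distinct / cls$distinct[1L], 2L)
  list(families = perFam, classes = cls)
}

#' Sense/antisense orientation of hits relative to features
#'
#' Each (hit, feature) overlap on a stranded feature contributes one
#' orientation occurrence: sense when hit and feature strands agree.
#' Unstranded features are excluded with a warning. Fractions are reported
#' both read-weighted and over distinct occurrences.
#'
#' @param mapping a [MappingResult-class].
#' @param features stranded `GRanges`.
#' @param counts optional named multiplicity vector (defaults to 1 per
#'   sequence).
#' @return named numeric vector: `senseReads`, `antisenseReads`,
#'   `senseDistinct`, `antisenseDistinct` (fractions; `NaN` when no
#'   overlap).
#' @export
senseAntisense <- function(mapping, features, counts = NULL) {
  unstranded <- as.character(strand(features)) == "*"
  if (any(unstranded)) {
    warning(sum(unstranded), " unstranded feature(s) excluded")
    features <- features[!unstranded]
  }
  h <- hits(mapping)
  ov <- findOverlaps(h, features, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  sense <- as.character(strand(h))[qi] == as.character(strand(features))[si]
  seqs <- h$seqId[qi]
  if (is.null(counts)) counts <- stats::setNames(rep(1, length(unique(seqs))),
                                                 unique(seqs))
  # one occurrence per (sequence, orientation)
  occ <- !duplicated(paste(seqs, sense))
  w <- counts[seqs[occ]]
  s <- sense[occ]
  c(senseReads = sum(w[s]) / sum(w),
    antisenseReads = sum(w[!s]) / sum(w),
    senseDistinct = mean(s),
    antisenseDistinct = mean(!s))
}

#' Rank genes by density of uniquely mapping piRNAs
#'
#' A gene's count is the number of distinct uniquely mapping sequences whose
#' 5' coordinate lies inside the annotated gene span (UTRs + introns +
#' exons); density is count/length (reported half-up at 1 decimal). Genes
#' overlapping a cluster by >= 1 bp are flagged. Zero-length genes are
#' rejected.
#'
#' @param geneFeatures `GRanges` with a `name` metadata column.
#' @param uniqueHitsGr `GRanges` of unique piRNA hits (with `seqId`,
#'   `fivePrime`).
#' @param clusters refined cluster `GRanges` (may be empty).
#' @return data.frame sorted by density descending: `gene`, `lengthBp`,
#'   `uniquePirnas`, `density`, `strandPercent` ("+/-" of distinct hits),
#'   `inCluster`.
#' @export
rankGeneDensity <- function(geneFeatures, uniqueHitsGr, clusters = GRanges()) {
  stopifnot(all(width(geneFeatures) >= 1L))
  pts <- GRanges(seqnames(uniqueHitsGr),
                 IRanges(uniqueHitsGr$fivePrime, width = 1L))
  ov <- findOverlaps(pts, geneFeatures, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  inCl <- countOverlaps(geneFeatures, clusters, ignore.strand = TRUE) > 0L
  rows <- lapply(seq_along(geneFeatures), function(g) {
    sel <- si == g
    seqs <- uniqueHitsGr$seqId[qi[sel]]
    keep <- !duplicated(seqs)
    strands <- as.character(strand(uniqueHitsGr))[qi[sel]][keep]
    n <- sum(keep)
    len <- width(geneFeatures)[g]
    plus <- if (n) roundHalfUp(100 * mean(strands == "+")) else 0
    data.frame(
      gene = geneFeatures$name[g], lengthBp = len, uniquePirnas = n,
      density = roundHalfUp(n / len, 1L),
      strandPercent = if (n) paste0(plus, "/", 100 - plus) else "0/0",
      inCluster = inCl[g])
  })
  df <- do.call(rbind, rows)
  df[order(-df$density, -df$uniquePirnas, df$gene, method = "radix"), ,
     drop = FALSE]
}

#' Detect piRNAs derived from introduced (transgene) sequences
#'
#' Candidates are piRNA-class sequences with zero genome hits at the
#' configured budget; a candidate is retained iff it matches a
#' transformation plasmid exactly (0 mismatches, full length, either
#' strand), treating each plasmid as circular. Sequences matching more than
#' one plasmid are flagged ambiguous and parenthesised in the count matrix.
#' The result is invariant to plasmid record order.
#'
#' @param library piRNA-class [SmallRNALibrary-class].
#' @param mapping the library's genome [MappingResult-class].
#' @param plasmids named [Biostrings::DNAStringSet] of plasmid sequences.
#' @param circular treat plasmids as circular (default TRUE).
#' @return list with `hits` (data.frame: `sequence`, `plasmid`, `position`,
#'   `strand`, `ambiguous`) and `counts` (data.frame per plasmid:
#'   `unambiguous`, `ambiguous`, `display` like `"6(2)"`).
#' @export
detectTransgenePirnas <- function(library, mapping, plasmids,
                                  circular = TRUE) {
  st <- mappingStatus(mapping)
  cand <- st$sequence[st$status == "unmapped"]
  cand <- intersect(cand, sequences(library))
  plasmids <- plasmids[order(names(plasmids))]
  refs <- plasmids
  if (circular && length(refs)) {
    ext <- max(c(2L, nchar(cand))) - 1L
    refs <- DNAStringSet(paste0(as.character(plasmids),
                                substr(as.character(plasmids), 1L, ext)))
    names(refs) <- names(plasmids)
  }
  gr <- if (length(cand)) alignFullLength(cand, refs, maxMismatches = 0L)
        else GRanges()
  if (length(gr)) {
    # fold circular-extension placements back onto the plasmid origin
    plen <- width(plasmids)[match(as.character(seqnames(gr)),
                                  names(plasmids))]
    pos <- ((start(gr) - 1L) %% plen) + 1L
    hitDf <- data.frame(sequence = gr$seqId,
                        plasmid = as.character(seqnames(gr)),
                        position = pos,
                        strand = as.character(strand(gr)))
    hitDf <- unique(hitDf)
    nPlasmids <- tapply(hitDf$plasmid, hitDf$sequence,
                        function(p) length(unique(p)))
    hitDf$ambiguous <- unname(nPlasmids[hitDf$sequence] > 1L)
    hitDf <- hitDf[order(hitDf$plasmid, hitDf$position, hitDf$sequence), ,
                   drop = FALSE]
  } else {
    hitDf <- data.frame(sequence = character(), plasmid = character(),
                        position = integer(), strand = character(),
                        ambiguous = logical())
  }
  counts <- do.call(rbind, lapply(names(plasmids), function(p) {
    sub <- hitDf[hitDf$plasmid == p, , drop = FALSE]
    una <- length(unique(sub$sequence[!sub$ambiguous]))
    amb <- length(unique(sub$sequence[sub$ambiguous]))
    data.frame(plasmid = p, unambiguous = una, ambiguous = amb,
               display = if (amb) sprintf("%d(%d)", una, amb)
                         else as.character(una))
  }))
  rownames(hitDf) <- NULL
  list(hits = hitDf, counts = counts)
}
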