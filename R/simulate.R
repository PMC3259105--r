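#' Configuration for the synthetic small-RNA study generator
#'
#' The defaults encode the study conditions the package is validated
#' against: a 1 Mb single-contig genome carrying 10 piRNA clusters laid out
#' on the 5-kb scan grid and covering ~20% of the genome; a latent piRNA
#' pool emitting 84% of its sequences from clusters (the genome-scale
#' cluster/background emission contrast, ~20x per bp); a bimodal read-length
#' structure (21-nt siRNA background plus a 24-31 nt piRNA class with mode
#' 28 nt); 5'-U probability 0.8; per-cluster strand bias 0.9; and a 10-nt
#' ping-pong partner structure in which 19.5% of partnered sequences carry
#' the exact signature offset. Abundance is log-normal (sigma 1) to exercise
#' the duplicate-exclusion rule; `"uniform"` is used for estimator-recovery
#' checks.
#'
#' @param contigLengths named integer vector of contig lengths.
#' @param windowSize scan resolution in bp; planted cluster bounds are
#'   multiples of it.
#' @param nClusters number of planted clusters.
#' @param clusterLengthWindows integer vector of allowed cluster lengths in
#'   windows.
#' @param clusterFraction fraction of primary pool sequences emitted from
#'   clusters.
#' @param poolSize latent pool size N (distinct sequences).
#' @param pirnaLengths,pirnaLengthProbs piRNA length distribution.
#' @param pU1 probability a pool sequence is placed with a 5' U.
#' @param strandBias probability a cluster-emitted sequence lies on its
#'   cluster's majority strand (beta in \[0.5, 1\]).
#' @param pPartner probability a cluster-emitted sequence receives an
#'   opposite-strand overlap partner.
#' @param pPingpong probability a partner sits at the exact 10-nt 5'
#'   overlap (else a random non-signature offset).
#' @param abundanceModel,sigma latent abundance model of the pool.
#' @param nTeFamilies,teLengthRange,teClassMix,teCopies,tirLength,teOrientationBias,teInClusters
#'   TE library spec: families, consensus length range, class mix, copies
#'   per family, MITE terminal-inverted-repeat length, insertion
#'   orientation bias (probability of plus), and whether insertions may
#'   fall inside clusters.
#' @param nGenes,geneLengthRange gene annotation spec.
#' @param nLibraries,replicateGroups,depth library layout (defaults: seven
#'   libraries in five replicate groups, mirroring a two-replicates +
#'   three-singleton design that yields 19 non-replicate pairs).
#' @param sirnaRate fraction of library reads drawn as 21-nt genomic
#'   background (the endo-siRNA peak).
#' @param contaminantRate fraction of library reads drawn from rRNA-like
#'   contaminant references.
#' @param nContaminantRefs,contaminantRefLength contaminant reference spec.
#' @param adapter,adapterRate 3' adapter sequence and the fraction of reads
#'   emitted raw (insert + adapter, truncated to `rawReadLength`).
#' @param rawReadLength raw-mode read length.
#' @param nPlasmids,plasmidLength,transgeneRate transformation-plasmid spec
#'   and the fraction of pool sequences drawn from plasmids (absent from
#'   the genome).
#' @return a validated list of class `SimConfig`.
#' @export
simConfig <- function(contigLengths = c(contig1 = 1000000L),
                      windowSize = 5000L,
                      nClusters = 10L,
                      clusterLengthWindows = 3:6,
                      clusterFraction = 0.84,
                      poolSize = 1500L,
                      pirnaLengths = 24:31,
                      pirnaLengthProbs = c(0.04, 0.06, 0.10, 0.16, 0.30,
                                           0.18, 0.10, 0.06),
                      pU1 = 0.8,
                      strandBias = 0.9,
                      pPartner = 0.4,
                      pPingpong = 0.195,
                      abundanceModel = c("lognormal", "uniform"),
                      sigma = 1,
                      nTeFamilies = 5L,
                      teLengthRange = c(300L, 1500L),
                      teClassMix = c(retrotransposon = 0.4, DNA = 0.2,
                                     MITE = 0.2, other = 0.2),
                      teCopies = c(2L, 6L),
                      tirLength = 30L,
                      teOrientationBias = 0.5,
                      teInClusters = FALSE,
                      nGenes = 20L,
                      geneLengthRange = c(1000L, 5000L),
                      nLibraries = 7L,
                      replicateGroups = c("A", "A", "B", "B", "C", "D", "E"),
                      depth = 20000L,
                      sirnaRate = 0.2,
                      contaminantRate = 0.05,
                      nContaminantRefs = 3L,
                      contaminantRefLength = 1500L,
                      adapter = "TCGTATGCCGTCTTCTGCTTG",
                      adapterRate = 0,
                      rawReadLength = 42L,
                      nPlasmids = 2L,
                      plasmidLength = 3000L,
                      transgeneRate = 0.01) {
  abundanceModel <- match.arg(abundanceModel)
  cfg <- as.list(environment())
  probs <- c(cfg$clusterFraction, cfg$pU1, cfg$strandBias, cfg$pPartner,
             cfg$pPingpong, cfg$sirnaRate, cfg$contaminantRate,
             cfg$adapterRate, cfg$transgeneRate)
  stopifnot(all(probs >= 0 & probs <= 1),
            cfg$strandBias >= 0.5,
            cfg$poolSize >= 1L,
            length(cfg$pirnaLengthProbs) == length(cfg$pirnaLengths),
            abs(sum(cfg$pirnaLengthProbs) - 1) < 1e-9,
            length(cfg$replicateGroups) == cfg$nLibraries,
            cfg$windowSize > max(cfg$pirnaLengths))
  structure(cfg, class = "SimConfig")
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# sample() treats a length-1 x as 1:x; never do that
sampleFrom <- function(x, n = 1L) {
  if (length(x) == 1L) rep(x, n) else sample(x, n, replace = TRUE)
}

#' Build a synthetic genome with TE, gene and cluster annotations
#'
#' Generates random contigs; plants non-overlapping, window-grid-aligned
#' piRNA cluster intervals (each assigned a majority strand); inserts TE
#' family copies (MITE families carry terminal inverted repeats: the
#' reverse complement of the left repeat equals the right repeat) at
#' recorded positions/orientations; draws gene intervals; and emits
#' contaminant references and transformation plasmids. Fully determined by
#' `seed`.
#'
#' @param config a [simConfig()].
#' @param seed integer seed.
#' @return list: `assembly` (DNAStringSet), `teFeatures`, `geneFeatures`
#'   (GRanges), `teConsensus` (DNAStringSet), `teClasses`,
#'   `contaminantRef`, `plasmids` (DNAStringSet) and `truth` (cluster
#'   GRanges with `cluster`, `majorityStrand`, `strandBias`).
#' @export
buildGenome <- function(config, seed) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(as.integer(seed))
  W <- config$windowSize
  contigs <- vapply(config$contigLengths, randomDna, "")
  names(contigs) <- names(config$contigLengths)

  # clusters: grid-aligned, >= 1 empty window between them and contig ends
  nWin <- config$contigLengths %/% W
  clusterRows <- list()
  occupied <- lapply(nWin, function(n) rep(FALSE, n))
  lens <- sampleFrom(config$clusterLengthWindows, config$nClusters)
  for (i in seq_len(config$nClusters)) {
    placed <- FALSE
    for (try in 1:2000) {
      ci <- sample.int(length(contigs), 1L,
                       prob = as.numeric(config$contigLengths))
      if (nWin[ci] < lens[i] + 2L) next
      w0 <- sample.int(nWin[ci] - lens[i] - 1L, 1L)  # first window, 1-based
      span <- max(1L, w0 - 1L):min(nWin[ci], w0 + lens[i])
      if (any(occupied[[ci]][span])) next
      occupied[[ci]][span] <- TRUE
      clusterRows[[i]] <- data.frame(
        contig = names(contigs)[ci],
        start = (w0 - 1L) * W + 1L, end = (w0 - 1L + lens[i]) * W)
      placed <- TRUE
      break
    }
    if (!placed) stop("cluster spec cannot fit in the genome")
  }
  cl <- do.call(rbind, clusterRows)
  truth <- GRanges(factor(cl$contig, levels = names(contigs)),
                   IRanges(cl$start, cl$end))
  truth$cluster <- seq_len(config$nClusters)
  truth$majorityStrand <- sample(c("+", "-"), config$nClusters,
                                 replace = TRUE)
  truth$strandBias <- config$strandBias

  # TE library and insertions
  teLens <- sampleFrom(seq(config$teLengthRange[1L],
                           config$teLengthRange[2L]), config$nTeFamilies)
  teCls <- sample(names(config$teClassMix), config$nTeFamilies,
                  replace = TRUE, prob = config$teClassMix)
  cons <- character(config$nTeFamilies)
  for (f in seq_len(config$nTeFamilies)) {
    if (teCls[f] == "MITE") {
      tir <- randomDna(config$tirLength)
      mid <- randomDna(max(0L, teLens[f] - 2L * config$tirLength))
      cons[f] <- paste0(tir, mid,
                        as.character(reverseComplement(DNAString(tir))))
    } else cons[f] <- randomDna(teLens[f])
  }
  names(cons) <- sprintf("TEfam%02d", seq_len(config$nTeFamilies))
  teRows <- list()
  blocked <- truth  # keep insertions clear of clusters unless allowed
  for (f in seq_len(config$nTeFamilies)) {
    nCopies <- sampleFrom(seq(config$teCopies[1L], config$teCopies[2L]))
    L <- nchar(cons[f])
    for (cp in seq_len(nCopies)) {
      for (try in 1:2000) {
        ci <- sample.int(length(contigs), 1L,
                         prob = as.numeric(config$contigLengths))
        pos <- sample.int(config$contigLengths[ci] - L + 1L, 1L)
        cand <- GRanges(factor(names(contigs)[ci], levels = names(contigs)),
                        IRanges(pos, pos + L - 1L))
        if (!config$teInClusters &&
            length(findOverlaps(cand, blocked))) next
        ori <- if (runif(1) < config$teOrientationBias) "+" else "-"
        ins <- if (ori == "+") cons[f]
               else as.character(reverseComplement(DNAString(cons[f])))
        substr(contigs[ci], pos, pos + L - 1L) <- ins
        blocked <- c(blocked, cand)
        teRows[[length(teRows) + 1L]] <- data.frame(
          contig = names(contigs)[ci], start = pos, end = pos + L - 1L,
          strand = ori, name = names(cons)[f], class = teCls[f])
        break
      }
    }
  }
  te <- do.call(rbind, teRows)
  teFeatures <- GRanges(factor(te$contig, levels = names(contigs)),
                        IRanges(te$start, te$end),
                        strand = te$strand, kind = "TE", name = te$name,
                        class = te$class)

  # genes: uniform intervals, random strand
  geneRows <- lapply(seq_len(config$nGenes), function(g) {
    L <- sampleFrom(seq(config$geneLengthRange[1L],
                        config$geneLengthRange[2L]))
    ci <- sample.int(length(contigs), 1L,
                     prob = as.numeric(config$contigLengths))
    pos <- sample.int(config$contigLengths[ci] - L + 1L, 1L)
    data.frame(contig = names(contigs)[ci], start = pos, end = pos + L - 1L,
               strand = sample(c("+", "-"), 1L),
               name = sprintf("gene%03d", g))
  })
  gn <- do.call(rbind, geneRows)
  geneFeatures <- GRanges(factor(gn$contig, levels = names(contigs)),
                          IRanges(gn$start, gn$end),
                          strand = gn$strand, kind = "gene", name = gn$name)

  contam <- DNAStringSet(vapply(seq_len(config$nContaminantRefs),
                                function(i)
                                  randomDna(config$contaminantRefLength),
                                ""))
  names(contam) <- sprintf("rRNA%02d", seq_len(config$nContaminantRefs))
  plasmids <- DNAStringSet(vapply(seq_len(config$nPlasmids),
                                  function(i) randomDna(config$plasmidLength),
                                  ""))
  names(plasmids) <- sprintf("plasmid%02d", seq_len(config$nPlasmids))

  list(assembly = DNAStringSet(contigs), teFeatures = teFeatures,
       geneFeatures = geneFeatures, teConsensus = DNAStringSet(cons),
       teClasses = stats::setNames(teCls, names(cons)),
       contaminantRef = contam, plasmids = plasmids, truth = truth)
}

# complement of single characters
compBase <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# 5' base of a placement: contig string, 5' coordinate, strand
fivePrimeBase <- function(contigStr, fp, strandChar) {
  b <- substr(contigStr, fp, fp)
  if (strandChar == "+") b else unname(compBase[b])
}

# character-level reverse complement (avoids per-read S4 dispatch)
revcompChr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# extract a read from a contig string given 5' coordinate, length, strand
extractRead <- function(contigStr, fp, len, strandChar) {
  if (strandChar == "+") substr(contigStr, fp, fp + len - 1L)
  else revcompChr(substr(contigStr, fp - len + 1L, fp))
}

#' Build the latent piRNA pool
#'
#' Draws `poolSize` distinct genomic (or plasmid) substrings: cluster
#' emissions with per-cluster strand bias, uniform background, and
#' plasmid-derived transgene sequences; controls the 5'-base class (U vs
#' non-U) by local window shifting; and attaches opposite-strand partners
#' with the configured signature-offset probability. Records per-sequence
#' origin and pool-level realized statistics (the generator truth).
#'
#' @param config a [simConfig()].
#' @param genome output of [buildGenome()].
#' @param seed integer seed.
#' @return list: `pool` (data.frame: `sequence`, `origin`, `cluster`,
#'   `contig`, `fivePrime`, `strand`, `length`, `isPartner`,
#'   `partnerOffset`), `weights` (latent abundances) and `realized`
#'   (list: `u1Fraction`, `clusterFraction`, `majorityStrandFraction`,
#'   `signatureFraction`).
#' @export
buildPool <- function(config, genome, seed) {
  set.seed(as.integer(seed))
  contigs <- as.character(genome$assembly)
  clen <- nchar(contigs)
  truth <- genome$truth
  nCl <- length(truth)
  clLen <- width(truth)

  drawLen <- function(n) {
    if (length(config$pirnaLengths) == 1L) return(rep(config$pirnaLengths, n))
    sample(config$pirnaLengths, n, replace = TRUE,
           prob = config$pirnaLengthProbs)
  }

  # place one read: returns c(contig-index, fivePrime) honouring the target
  # 5'-base class by shifting, or NA on failure
  place <- function(ci, lo, hi, len, strandChar, wantU) {
    for (try in 1:40) {
      if (strandChar == "+") {
        fp <- lo + sample.int(hi - lo - len + 2L, 1L) - 1L
      } else {
        fp <- lo + len - 1L + sample.int(hi - lo - len + 2L, 1L) - 1L
      }
      b <- fivePrimeBase(contigs[ci], fp, strandChar)
      if (b == "N") next
      if ((b == "T") == wantU) return(fp)
    }
    NA_integer_
  }

  truthContig <- as.character(seqnames(truth))
  truthStart <- start(truth)
  truthEnd <- end(truth)
  truthMaj <- truth$majorityStrand
  nPrim <- config$poolSize
  cap <- 3L * nPrim
  vSeq <- character(cap); vOrigin <- character(cap)
  vCluster <- integer(cap); vContig <- character(cap)
  vFp <- integer(cap); vStrand <- character(cap); vLen <- integer(cap)
  vPartner <- logical(cap); vOffset <- rep(NA_integer_, cap)
  ri <- 0L
  addRow <- function(sequence, origin, cluster, contig, fivePrime, strand,
                     length, isPartner, partnerOffset) {
    ri <<- ri + 1L
    vSeq[ri] <<- sequence; vOrigin[ri] <<- origin
    vCluster[ri] <<- cluster; vContig[ri] <<- contig
    vFp[ri] <<- fivePrime; vStrand[ri] <<- strand; vLen[ri] <<- length
    vPartner[ri] <<- isPartner; vOffset[ri] <<- partnerOffset
  }
  origin <- sample(c("transgene", "cluster", "background"), nPrim,
                   replace = TRUE,
                   prob = c(config$transgeneRate,
                            (1 - config$transgeneRate) *
                              config$clusterFraction,
                            (1 - config$transgeneRate) *
                              (1 - config$clusterFraction)))
  plasmidStr <- as.character(genome$plasmids)
  for (i in seq_len(nPrim)) {
    len <- drawLen(1L)
    wantU <- runif(1) < config$pU1
    if (origin[i] == "transgene" && length(plasmidStr)) {
      pi <- sample.int(length(plasmidStr), 1L)
      strandChar <- sample(c("+", "-"), 1L)
      fp <- place(1L, 1L, nchar(plasmidStr[pi]), len, strandChar, wantU)
      if (is.na(fp)) next
      seqStr <- extractRead(plasmidStr[pi], fp, len, strandChar)
      addRow(seqStr, "transgene", NA_integer_,
             names(genome$plasmids)[pi], fp, strandChar, len, FALSE,
             NA_integer_)
      next
    }
    if (origin[i] == "cluster") {
      cli <- sample.int(nCl, 1L, prob = clLen)
      ci <- match(truthContig[cli], names(contigs))
      lo <- truthStart[cli]
      hi <- truthEnd[cli]
      maj <- truthMaj[cli]
      strandChar <- if (runif(1) < config$strandBias) maj
                    else setdiff(c("+", "-"), maj)
    } else {
      ci <- sample.int(length(contigs), 1L, prob = clen)
      lo <- 1L
      hi <- clen[ci]
      strandChar <- sample(c("+", "-"), 1L)
      cli <- NA_integer_
    }
    fp <- place(ci, lo, hi, len, strandChar, wantU)
    if (is.na(fp)) next
    seqStr <- extractRead(contigs[ci], fp, len, strandChar)
    if (grepl("N", seqStr)) next
    addRow(seqStr, origin[i], cli, names(contigs)[ci], fp, strandChar,
           len, FALSE, NA_integer_)
    # opposite-strand partner with 10-nt signature offset w.p. pPingpong
    if (origin[i] == "cluster" && runif(1) < config$pPartner) {
      plen <- drawLen(1L)
      d <- if (runif(1) < config$pPingpong) 10L
           else sample(setdiff(seq(2L, len), 10L), 1L)
      if (strandChar == "+") {
        pfp <- fp + d - 1L
        pstrand <- "-"
        ok <- pfp - plen + 1L >= 1L && pfp <= clen[ci]
      } else {
        pfp <- fp - d + 1L
        pstrand <- "+"
        ok <- pfp >= 1L && pfp + plen - 1L <= clen[ci]
      }
      if (ok) {
        pseq <- extractRead(contigs[ci], pfp, plen, pstrand)
        if (!grepl("N", pseq))
          addRow(pseq, "partner", cli, names(contigs)[ci], pfp, pstrand,
                 plen, TRUE, d)
      }
    }
  }
  keep <- seq_len(ri)
  pool <- data.frame(
    sequence = vSeq[keep], origin = vOrigin[keep], cluster = vCluster[keep],
    contig = vContig[keep], fivePrime = vFp[keep], strand = vStrand[keep],
    length = vLen[keep], isPartner = vPartner[keep],
    partnerOffset = vOffset[keep], stringsAsFactors = FALSE)
  # the pool is the set of distinct generated substrings: poolSize primary
  # draws plus their partners, collapsed to distinct sequences
  pool <- pool[!duplicated(pool$sequence), , drop = FALSE]
  rownames(pool) <- NULL

  w <- if (config$abundanceModel == "uniform") rep(1, nrow(pool))
       else rlnorm(nrow(pool), 0, config$sigma)

  # realized (pool-level) truth
  genomic <- pool$origin != "transgene"
  gpool <- pool[genomic, , drop = FALSE]
  poolGr <- GRanges(factor(gpool$contig, levels = names(contigs)),
                    IRanges(ifelse(gpool$strand == "+", gpool$fivePrime,
                                   gpool$fivePrime - gpool$length + 1L),
                            width = gpool$length),
                    strand = gpool$strand,
                    seqId = gpool$sequence, fivePrime = gpool$fivePrime)
  pairs <- enumerateOverlapPairs(poolGr, minLen = min(config$pirnaLengths))
  sigF <- if (nrow(pairs)) signatureFraction(pairs) else NA_real_
  clSeqs <- gpool[!is.na(gpool$cluster), , drop = FALSE]
  onMaj <- clSeqs$strand ==
    truth$majorityStrand[clSeqs$cluster]
  realized <- list(
    u1Fraction = mean(substr(pool$sequence, 1L, 1L) == "T"),
    clusterFraction = mean(!is.na(gpool$cluster) & !gpool$isPartner) /
      mean(!gpool$isPartner),
    majorityStrandFraction = mean(onMaj[!clSeqs$isPartner]),
    signatureFraction = sigF)
  list(pool = pool, weights = w, realized = realized)
}

#' Sample a sequencing library from the latent pool
#'
#' Multinomially draws `depth` reads over pool abundances, mixed with the
#' configured 21-nt genomic siRNA background and contaminant reads; in raw
#' mode a fraction of reads is emitted as insert + adapter truncated to the
#' raw read length.
#'
#' @param poolBuild output of [buildPool()].
#' @param genome output of [buildGenome()].
#' @param config a [simConfig()].
#' @param depth number of reads (>= 1).
#' @param seed integer seed.
#' @param id,replicateGroup library metadata.
#' @return list: `library` (a [SmallRNALibrary-class]) and `truth`
#'   (per-library spike counts and sampled pool indices).
#' @export
sampleLibrary <- function(poolBuild, genome, config, depth = config$depth,
                          seed, id, replicateGroup = id) {
  stopifnot(depth >= 1L)
  set.seed(as.integer(seed))
  pool <- poolBuild$pool
  contigs <- as.character(genome$assembly)
  clen <- nchar(contigs)
  split3 <- rmultinom(1L, depth,
                      c(sirna = config$sirnaRate,
                        contam = config$contaminantRate,
                        pool = 1 - config$sirnaRate -
                          config$contaminantRate))[, 1L]
  cnt <- rmultinom(1L, split3[["pool"]], poolBuild$weights)[, 1L]
  idx <- which(cnt > 0L)
  seqs <- pool$sequence[idx]
  mult <- cnt[idx]
  # 21-nt siRNA background: random genomic substrings
  if (split3[["sirna"]] > 0L) {
    n <- split3[["sirna"]]
    ci <- sample.int(length(contigs), n, replace = TRUE, prob = clen)
    pos <- floor(runif(n) * (clen[ci] - 21L)) + 1L
    s <- vapply(seq_len(n), function(i)
      substr(contigs[ci[i]], pos[i], pos[i] + 20L), "")
    flip <- runif(n) < 0.5
    s[flip] <- as.character(reverseComplement(DNAStringSet(s[flip])))
    seqs <- c(seqs, s)
    mult <- c(mult, rep(1L, n))
  }
  if (split3[["contam"]] > 0L) {
    n <- split3[["contam"]]
    refs <- as.character(genome$contaminantRef)
    ri <- sample.int(length(refs), n, replace = TRUE)
    lens <- sample(16:35, n, replace = TRUE)
    pos <- vapply(seq_len(n), function(i)
      sample.int(nchar(refs[ri[i]]) - lens[i] + 1L, 1L), integer(1))
    cs <- vapply(seq_len(n), function(i)
      substr(refs[ri[i]], pos[i], pos[i] + lens[i] - 1L), "")
    seqs <- c(seqs, cs)
    mult <- c(mult, rep(1L, n))
  }
  nAdapter <- 0L
  if (config$adapterRate > 0) {
    raw <- runif(length(seqs)) < config$adapterRate
    nAdapter <- sum(mult[raw])
    seqs[raw] <- substr(paste0(seqs[raw], config$adapter), 1L,
                        config$rawReadLength)
  }
  lib <- SmallRNALibrary(seqs, mult, id = id, species = "synthetic",
                         line = "synthetic", replicateGroup = replicateGroup)
  list(library = lib,
       truth = list(poolIdx = idx, poolReads = sum(cnt),
                    nSirna = split3[["sirna"]],
                    nContaminant = split3[["contam"]],
                    nAdapter = nAdapter, depth = depth))
}

#' Simulate a complete small-RNA study
#'
#' Genome, latent pool and all libraries in one call, each stage seeded
#' deterministically from `seed`.
#'
#' @param config a [simConfig()].
#' @param seed integer master seed (library i uses `seed + 10 + i`).
#' @return list: `genome`, `poolBuild`, `libraries` (named list of
#'   [SmallRNALibrary-class]), `libraryTruth`, `config`, `seed`.
#' @export
simulateStudy <- function(config = simConfig(), seed = 1L) {
  seed <- as.integer(seed)
  genome <- buildGenome(config, seed)
  poolBuild <- buildPool(config, genome, seed + 1L)
  libs <- list()
  libTruth <- list()
  for (i in seq_len(config$nLibraries)) {
    id <- sprintf("lib%d", i)
    sl <- sampleLibrary(poolBuild, genome, config, config$depth,
                        seed = seed + 10L + i, id = id,
                        replicateGroup = config$replicateGroups[i])
    libs[[id]] <- sl$library
    libTruth[[id]] <- sl$truth
  }
  list(genome = genome, poolBuild = poolBuild, libraries = libs,
       libraryTruth = libTruth, config = config, seed = seed)
}

#' Write a simulated study to disk in standard formats
#'
#' Emits the genome and TE consensus as FASTA, annotations as GFF3, planted
#' clusters as BED, libraries as FASTA and the truth as JSON.
#'
#' @param sim output of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeXStringSet(sim$genome$assembly, file.path(dir, "genome.fasta"))
  writeXStringSet(sim$genome$teConsensus,
                  file.path(dir, "te_consensus.fasta"))
  writeXStringSet(sim$genome$plasmids, file.path(dir, "plasmids.fasta"))
  rtracklayer::export(sim$genome$teFeatures, file.path(dir, "te.gff3"),
                      format = "gff3")
  rtracklayer::export(sim$genome$geneFeatures, file.path(dir, "genes.gff3"),
                      format = "gff3")
  rtracklayer::export(sim$genome$truth, file.path(dir, "clusters_truth.bed"),
                      format = "bed")
  for (id in names(sim$libraries))
    writeLibraryFasta(sim$libraries[[id]],
                      file.path(dir, paste0(id, ".fasta")))
  jsonlite::write_json(
    list(realized = sim$poolBuild$realized,
         poolSize = nrow(sim$poolBuild$pool),
         seed = sim$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
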