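test_that("window bucketing is by 5' coordinate with half-open boundaries", {
  # 12 distinct sequences with 5' in the first window
  gr <- hitGr("c1", start = seq(10, 4900, length.out = 12), len = 26,
              strand = "+")
  wc <- windowCounts(gr, 5000)
  expect_equal(wc$count[wc$window == 0], 12L)
  # 1-based position 5001 is the first base of window 1
  gr2 <- hitGr("c1", start = c(5000, 5001), len = 26, strand = "+",
               seq = c("a", "b"))
  wc2 <- windowCounts(gr2, 5000)
  expect_setequal(wc2$window, c(0L, 1L))
  expect_equal(sum(wc2$count), 2L)
  # counts are distinct sequences, not multiplicities or hits
  gr3 <- hitGr("c1", start = c(100, 100, 200), len = 24, strand = "+",
               seq = c("x", "x", "y"))
  expect_equal(windowCounts(gr3, 5000)$count, 2L)
  # per-contig sum equals distinct sequences on the contig
  set.seed(61)
  gr4 <- hitGr("c1", start = sample(1:49000, 300), len = 25, strand = "+")
  expect_equal(sum(windowCounts(gr4, 5000)$count), 300L)
})

test_that("window counts equal brute-force bucketing on random placements", {
  set.seed(62)
  for (rep in 1:5) {
    n <- 200
    ctg <- sample(c("u", "v"), n, TRUE)
    fp <- sample(1:30000, n, TRUE)
    gr <- GRanges(ctg, IRanges(fp, width = 27), strand = "+")
    gr$seqId <- paste0("s", sample(1:150, n, TRUE))
    gr$fivePrime <- fp
    wc <- windowCounts(gr, 5000)
    # brute force recount
    df <- unique(data.frame(ctg, w = (fp - 1) %/% 5000, s = gr$seqId))
    brute <- aggregate(s ~ ctg + w, df, function(x) length(unique(x)))
    brute <- brute[order(brute$ctg, brute$w), ]
    expect_equal(wc$count, brute$s)
    expect_equal(wc$window, brute$w)
  }
})

test_that("cluster calling merges adjacent windows only and refines boundaries", {
  # windows 3,4,5 qualify; window 7 qualifies separately (6 empty)
  mkRun <- function(win, n, off = 0)
    hitGr("c1", start = win * 5000 + seq(50, 4500, length.out = n) + off,
          len = 26, strand = "+",
          seq = sprintf("w%d_%d", win, seq_len(n)))
  gr <- c(mkRun(3, 12), mkRun(4, 15), mkRun(5, 11), mkRun(7, 13))
  wc <- windowCounts(gr, 5000)
  cl <- callClusters(wc, gr, 5000, 10)
  expect_equal(length(cl), 2L)
  big <- cl[cl$firstWindow == 3]
  expect_equal(big$lastWindow, 5L)
  expect_equal(big$uniquePirnaCount, 38L)
  # refined bounds equal the furthest member-read extents
  member <- gr[(gr$fivePrime - 1) %/% 5000 %in% 3:5]
  expect_equal(start(big), min(start(member)))
  expect_equal(end(big), max(end(member)))
  # two qualifying windows separated by one empty window stay separate
  sep <- c(mkRun(0, 12), mkRun(2, 12))
  clSep <- callClusters(windowCounts(sep, 5000), sep, 5000, 10)
  expect_equal(length(clSep), 2L)
  # ... unless a merge gap is allowed
  clGap <- callClusters(windowCounts(sep, 5000), sep, 5000, 10,
                        mergeGapWindows = 1)
  expect_equal(length(clGap), 1L)
  # sub-threshold windows never seed clusters
  few <- mkRun(9, 9)
  clFew <- callClusters(windowCounts(few, 5000), few, 5000, 10)
  expect_equal(length(clFew), 0L)
  # ranking: descending unique count
  expect_equal(cl$uniquePirnaCount, sort(cl$uniquePirnaCount,
                                         decreasing = TRUE))
})

test_that("printed coordinate convention reproduces reported cluster sizes", {
  ref <- referenceTable("clusters")
  kb <- clusterSizeKb(ref$start, ref$stop)
  expect_equal(kb, ref$printedSizeKb)
  expect_equal(min(kb), 6L)
  expect_equal(max(kb), 184L)
})

test_that("cluster summaries: strand fraction, exclusivity, nearest distance", {
  genome <- randGenome(c(k1 = 40000L), seed = 63)
  # plant one cluster of plus-strand reads in windows 0-1
  reads <- vapply(seq(100, 9000, by = 120), function(p)
    as.character(subseq(genome[[1]], p, p + 25)), "")
  libA <- SmallRNALibrary(reads[1:40], id = "A")
  libB <- SmallRNALibrary(reads[c(1:8, 41:75)], id = "B")
  mapA <- mapLibrary(libA, genome)
  mapB <- mapLibrary(libB, genome)
  combined <- mergeLibraries(libA, libB)
  uh <- uniqueHits(mapLibrary(combined, genome))
  cl <- callClusters(windowCounts(uh, 5000), uh, 5000, 10)
  cl <- summarizeClusters(cl, list(A = mapA, B = mapB),
                          list(A = libA, B = libB), 5000)
  expect_equal(cl$plusFraction, 1.0)
  shared <- 8; total <- 75
  expect_equal(cl$exclusiveFraction, (total - shared) / total)
  expect_equal(unname(rowSums(cl$prop)), 1)

  # nearest distance between [1,1000] and [3001,4000] is 2000
  c2 <- GRanges(c("z", "z"), IRanges(c(1, 3001), c(1000, 4000)))
  c2$rank <- 1:2; c2$uniquePirnaCount <- c(5L, 5L)
  c2$firstWindow <- c(0L, 0L); c2$lastWindow <- c(0L, 0L)
  d <- GenomicRanges::distanceToNearest(c2)
  expect_equal(S4Vectors::mcols(d)$distance, c(2000L, 2000L))
})

test_that("exclusive fraction matches the direct count oracle", {
  # 1 sequence in 2 libraries + 5 singletons = 5/6 exclusive
  genome <- randGenome(c(g = 20000L), seed = 64)
  pos <- seq(200, 4800, length.out = 12)
  reads <- vapply(pos, function(p)
    as.character(subseq(genome[[1]], p, p + 25)), "")
  libA <- SmallRNALibrary(reads[1:3], id = "A")   # shares reads[1]
  libB <- SmallRNALibrary(reads[c(1, 4:6)], id = "B")
  allLib <- mergeLibraries(libA, libB)
  uh <- uniqueHits(mapLibrary(allLib, genome))
  cl <- callClusters(windowCounts(uh, 5000), uh, 5000, 5)
  cl <- summarizeClusters(cl, list(A = mapLibrary(libA, genome),
                                   B = mapLibrary(libB, genome)),
                          list(A = libA, B = libB), 5000)
  expect_equal(cl$exclusiveFraction, 5 / 6)
})

test_that("TE-content null model: degenerate sd, sign, reproducibility, moments", {
  genome <- randGenome(c(n1 = 30000L, n2 = 20000L), seed = 65)
  cluster <- GRanges("n1", IRanges(2001, 4000))
  # TEs tiling the whole genome -> coverage 1 everywhere, sd 0
  tiling <- GRanges(rep(names(genome), each = 4),
                    IRanges(c(1, 7501, 15001, 22501, 1, 5001, 10001, 15001),
                            c(7500, 15000, 22500, 30000, 5000, 10000, 15000,
                              20000)))
  zs <- teNullZscores(cluster, tiling, genome, nSamples = 50, seed = 1)
  expect_equal(zs$teCoverage, 1.0)
  expect_equal(zs$nullMeanCoverage, 1.0)
  expect_true(is.na(zs$zCoverage))
  expect_true(zs$degenerate)

  # cluster devoid of TEs in a half-covered genome -> negative z
  te <- GRanges("n1", IRanges(seq(5001, 28000, by = 2000), width = 1000))
  zs2 <- teNullZscores(cluster, te, genome, nSamples = 400, seed = 2)
  expect_equal(zs2$teCoverage, 0)
  expect_lt(zs2$zCoverage, 0)

  # bit-for-bit reproducibility given (seed, nSamples)
  zs3 <- teNullZscores(cluster, te, genome, nSamples = 400, seed = 2)
  expect_identical(zs2, zs3)

  # null moments agree with a large independent re-sample
  zs4 <- teNullZscores(cluster, te, genome, nSamples = 4000, seed = 3)
  zs5 <- teNullZscores(cluster, te, genome, nSamples = 4000, seed = 99)
  expect_lt(abs(zs4$nullMeanCoverage - zs5$nullMeanCoverage),
            4 * zs4$nullSdCoverage / sqrt(4000) * 2)
  expect_error(teNullZscores(GRanges("n1", IRanges(1, 50000)), te, genome,
                             50, 1), "long")
})

test_that("coverage summary fractions", {
  genome <- randGenome(c(one = 10000L), seed = 66)
  uh <- hitGr("one", start = seq(100, 9800, by = 200), len = 25,
              strand = "+")
  full <- GRanges("one", IRanges(1, 10000))
  full$rank <- 1L; full$uniquePirnaCount <- length(uh)
  full$firstWindow <- 0L; full$lastWindow <- 1L
  cs <- coverageSummary(full, genome, uh)
  expect_equal(cs$genomeFraction, 1.0)
  expect_equal(cs$pirnaFraction, 1.0)
  none <- coverageSummary(GRanges(), genome, uh)
  expect_equal(none$genomeFraction, 0)
  expect_equal(none$pirnaFraction, 0)
})
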