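test_that("library construction collapses duplicates and normalises U to T", {
  lib <- SmallRNALibrary(c("TACGTACGTACGTACGTACGTACG",
                           "TACGTACGTACGTACGTACGTACG",
                           "UACGUACGUACGUACGUACGUACG"))
  expect_equal(nSequences(lib), 1L)
  expect_equal(nReads(lib), 3L)
  expect_equal(sequences(lib), "TACGTACGTACGTACGTACGTACG")

  # order independence
  a <- SmallRNALibrary(c("AAAAAAAAAAAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCCCCCCCCCCC"),
                       c(2L, 5L))
  b <- SmallRNALibrary(c("CCCCCCCCCCCCCCCCCCCCCCCC", "AAAAAAAAAAAAAAAAAAAAAAAA"),
                       c(5L, 2L))
  expect_identical(readCounts(a), readCounts(b))
})

test_that("FASTA/FASTQ reading, empty input, and write round-trip", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">r1", "TACGTACGTACGTACGTACGTACG",
               ">r2", "TACGTACGTACGTACGTACGTACG",
               ">r3", "UACGAACGUACGAACGUACGAACG"), fa)
  lib <- readSmallRNA(fa, "FASTA", libraryId = "L1")
  expect_equal(nSequences(lib), 2L)
  expect_equal(unname(readCounts(lib)["TACGTACGTACGTACGTACGTACG"]), 2L)

  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@q1", "UACGAACGUACGAACGUACGAACG", "+",
               strrep("I", 24)), fq)
  lq <- readSmallRNA(fq, "FASTQ")
  expect_equal(sequences(lq), "TACGAACGTACGAACGTACGAACG")

  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_warning(le <- readSmallRNA(empty, "FASTA"), "empty")
  expect_equal(nSequences(le), 0L)

  # round trip preserves the (sequence, multiplicity) multiset
  out <- tempfile(fileext = ".fasta")
  writeLibraryFasta(lib, out)
  back <- readSmallRNA(out, "FASTA", libraryId = "L1")
  # multiplicities are encoded in headers, one record per distinct sequence;
  # expand via counts for the multiset comparison
  expect_setequal(sequences(back), sequences(lib))
})

test_that("feature reading converts coordinates and resolves TE classes", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("chr1", "src", "dispersed_repeat", "11", "20", ".",
                     "+", ".", "Name=Ty3_gypsy", sep = "\t")), gff)
  fx <- readFeatures(gff, "GFF3", kind = "TE",
                     classMap = c(Ty3_gypsy = "retrotransposon"))
  expect_equal(start(fx), 11L)   # GRanges stays 1-based inclusive
  expect_equal(end(fx), 20L)
  expect_equal(width(fx), 10L)
  expect_equal(fx$class, "retrotransposon")

  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20\tmite1\t0\t+", bed)
  fb <- readFeatures(bed, "BED", kind = "TE", classMap = character())
  expect_equal(start(fb), 11L)   # BED 0-based half-open -> same interval
  expect_equal(end(fb), 20L)
  expect_equal(fb$class, "other")

  # GFF3 -> internal -> GFF3 is involutive on start/end
  out <- tempfile(fileext = ".gff3")
  rtracklayer::export(fx, out, format = "gff3")
  fx2 <- readFeatures(out, "GFF3", kind = "TE",
                      classMap = c(Ty3_gypsy = "retrotransposon"))
  expect_equal(start(fx2), start(fx))
  expect_equal(end(fx2), end(fx))
})

test_that("SAM ingestion applies strand and 5'-end conventions", {
  genome <- randGenome(c(chr1 = 400L), seed = 11)
  fwd <- as.character(subseq(genome[[1]], 101, 128))
  rev <- as.character(reverseComplement(DNAString(
    as.character(subseq(genome[[1]], 101, 128)))))
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:chr1\tLN:400",
    paste("f1", 0, "chr1", 101, 255, "28M", "*", 0, 0, fwd,
          strrep("I", 28), "NM:i:0", sep = "\t"),
    paste("r1", 16, "chr1", 101, 255, "28M", "*", 0, 0, fwd,
          strrep("I", 28), "NM:i:0", sep = "\t"),
    paste("bad", 0, "chr1", 151, 255, "10M2D16M", "*", 0, 0,
          substr(fwd, 1, 26), strrep("I", 26), sep = "\t")), sam)
  expect_warning(gr <- ingestSam(sam, genome), "skipped")
  expect_equal(length(gr), 2L)
  plus <- gr[as.character(strand(gr)) == "+"]
  minus <- gr[as.character(strand(gr)) == "-"]
  expect_equal(start(plus), 101L)
  expect_equal(plus$fivePrime, 101L)
  expect_equal(minus$fivePrime, 128L)  # 5' of a minus hit is the interval end
  expect_equal(minus$seqId, rev)       # read reported in its own orientation

  # contig missing from the assembly is an error
  expect_error(ingestSam(sam, genome["chr1"][0]), "contig")
})

test_that("SAM ingestion agrees with the built-in mapper on its own output", {
  genome <- randGenome(c(c1 = 3000L, c2 = 1500L), seed = 12)
  reads <- sampleReads(genome, 40, seed = 13)
  gr <- alignFullLength(reads, genome, 2)
  # serialise the mapper's hits as SAM and re-ingest
  minus <- as.character(strand(gr)) == "-"
  samSeq <- gr$seqId
  samSeq[minus] <- as.character(reverseComplement(DNAStringSet(samSeq[minus])))
  lines <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", names(genome), width(genome)),
             sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d",
                     paste0("q", seq_along(gr)),
                     ifelse(minus, 16L, 0L),
                     as.character(seqnames(gr)), start(gr), width(gr),
                     samSeq, strrep("I", width(gr)), gr$mismatches))
  sam <- tempfile(fileext = ".sam")
  writeLines(lines, sam)
  back <- ingestSam(sam, genome)
  expect_identical(hitsAsDf(back), hitsAsDf(gr))
  expect_identical(back$fivePrime[order(start(back), back$seqId)],
                   gr$fivePrime[order(start(gr), gr$seqId)])
})

test_that("report writing is deterministic and JSON converts coordinates", {
  tab <- data.frame(contig = "supercont1.518", start = 151663L,
                    stop = 158105L, n = 4164L)
  f1 <- tempfile(); f2 <- tempfile()
  writeReport(tab, f1, "TSV")
  writeReport(tab, f2, "TSV")
  expect_identical(readLines(f1), readLines(f2))
  # TSV keeps printed 1-based inclusive coordinates
  expect_match(readLines(f1)[2], "151663\t158105")

  fj <- tempfile(fileext = ".json")
  writeReport(tab, fj, "JSON")
  js <- jsonlite::read_json(fj)
  expect_equal(js[[1]]$start, 151662L)  # 0-based half-open in JSON

  fe <- tempfile()
  writeReport(tab[0, ], fe, "TSV")
  expect_equal(length(readLines(fe)), 1L)  # header-only
})
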