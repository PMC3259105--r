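#' @importFrom Biostrings readDNAStringSet DNAStringSet writeXStringSet
#'   reverseComplement DNAString neditStartingAt subseq PDict matchPDict
#' @importFrom GenomicRanges GRanges seqnames granges reduce
#' @importFrom IRanges IRanges
NULL

#' Read a small-RNA library from FASTA or FASTQ
#'
#' Records are collapsed into distinct sequences with summed multiplicities
#' and U is normalised to T (see [SmallRNALibrary()]). Records containing
#' characters outside the unambiguous RNA/DNA alphabet are rejected with an
#' error naming the record index.
#'
#' @param path input file path.
#' @param format `"FASTA"` or `"FASTQ"` (case-insensitive).
#' @param libraryId library identifier.
#' @param ... further metadata passed to [SmallRNALibrary()]
#'   (`species`, `line`, `replicateGroup`).
#' @return a [SmallRNALibrary-class]. An empty file yields an empty library
#'   with a warning.
#' @export
readSmallRNA <- function(path, format = c("FASTA", "FASTQ"),
                         libraryId = sub("\\.[^.]*$", "", basename(path)),
                         ...) {
  format <- match.arg(toupper(format[1L]), c("FASTA", "FASTQ"))
  # BStringSet tolerates RNA records; the constructor normalises U -> T
  ss <- Biostrings::readBStringSet(path, format = tolower(format))
  if (length(ss) == 0L) {
    warning("empty ", format, " file: ", path)
    return(SmallRNALibrary(character(), integer(), id = libraryId, ...))
  }
  seqs <- as.character(ss)
  bad <- grep("[^ACGTU]", seqs)
  if (length(bad))
    stop("malformed record(s) with ambiguous bases at index: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  SmallRNALibrary(seqs, id = libraryId, ...)
}

#' Write a library as FASTA
#'
#' Each distinct sequence is written once, with the header
#' `<id>_<i>_x<count>` carrying its multiplicity, in lexicographic sequence
#' order (deterministic).
#'
#' @param library a [SmallRNALibrary-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLibraryFasta <- function(library, path) {
  rd <- library@reads
  ss <- DNAStringSet(rd$sequence)
  names(ss) <- sprintf("%s_%d_x%d", libId(library), seq_len(nrow(rd)),
                       rd$count)
  writeXStringSet(ss, path)
  invisible(path)
}

#' Read gene or transposon annotation as a GRanges
#'
#' GFF3 input (1-based inclusive) and BED input (0-based half-open) are both
#' returned as standard `GRanges` (1-based inclusive). Features whose end
#' precedes their start are rejected with a warning. TE class is resolved
#' through `classMap`; unresolved families become `"other"`.
#'
#' @param path annotation file.
#' @param format `"GFF3"` or `"BED"`; default guessed from the extension.
#' @param kind `"gene"` or `"TE"`.
#' @param classMap named character vector mapping TE family names to classes
#'   (`retrotransposon`, `DNA`, `MITE`, `other`); ignored for genes.
#' @return a `GRanges` with metadata columns `kind`, `name` and (for TEs)
#'   `class`.
#' @export
readFeatures <- function(path, format = NULL, kind = c("gene", "TE"),
                         classMap = character()) {
  kind <- match.arg(kind)
  if (is.null(format))
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "BED" else "GFF3"
  format <- match.arg(toupper(format), c("GFF3", "BED"))
  gr <- if (format == "BED") rtracklayer::import(path, format = "bed")
        else rtracklayer::import(path, format = "gff3")
  bad <- width(gr) < 1L
  if (any(bad)) {
    warning(sum(bad), " feature(s) with end <= start rejected")
    gr <- gr[!bad]
  }
  nm <- if (!is.null(gr$Name)) as.character(gr$Name)
        else if (!is.null(gr$name)) as.character(gr$name)
        else if (!is.null(gr$ID)) as.character(gr$ID)
        else rep(NA_character_, length(gr))
  out <- granges(gr)
  mcols(out) <- DataFrame(kind = kind, name = nm)
  if (kind == "TE") {
    cls <- unname(classMap[nm])
    cls[is.na(cls)] <- "other"
    out$class <- cls
  }
  out
}

#' Resolve the class of a TE family name
#'
#' @param family character vector of family names.
#' @param classMap named character vector family -> class.
#' @return character vector of classes; unresolved families map to `"other"`.
#' @export
teClass <- function(family, classMap) {
  cls <- unname(classMap[family])
  cls[is.na(cls)] <- "other"
  cls
}

#' Ingest externally produced alignments from a SAM file
#'
#' Alternative front end to the built-in mapper: reads full-length ungapped
#' placements from SAM. Records with indel/clip/splice CIGAR operations are
#' skipped with a counted warning (the pipeline's contract is ungapped
#' full-length matching); the `NM` tag is used as the mismatch count when
#' present and recomputed against `assembly` otherwise.
#'
#' @param path SAM file (text).
#' @param assembly named [Biostrings::DNAStringSet] of the reference; every
#'   SAM contig must be present.
#' @return a `GRanges` with metadata columns `seqId` (read sequence, as
#'   aligned to the plus strand of the reference read in its own 5'->3'
#'   orientation), `mismatches` and `fivePrime`.
#' @export
ingestSam <- function(path, assembly) {
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("seq", "flag"), tag = "NM",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  if (!all(GenomeInfoDb::seqlevels(ga) %in% names(assembly)))
    stop("SAM header contains contigs absent from the assembly")
  cig <- GenomicAlignments::cigar(ga)
  ok <- grepl("^[0-9]+M$", cig)
  if (any(!ok))
    warning(sum(!ok), " record(s) with non-M CIGAR operations skipped")
  ga <- ga[ok]
  gr <- GRanges(as.character(GenomeInfoDb::seqnames(ga)),
                IRanges(start(ga), end(ga)),
                strand = as.character(strand(ga)))
  seqs <- as.character(mcols(ga)$seq)
  minus <- as.character(strand(gr)) == "-"
  # BAM stores the plus-strand image; report the read in its own orientation
  seqs[minus] <- as.character(reverseComplement(DNAStringSet(seqs[minus])))
  nm <- mcols(ga)$NM
  if (any(is.na(nm))) {
    idx <- which(is.na(nm))
    nm[idx] <- vapply(idx, function(i) {
      ref <- assembly[[as.character(seqnames(gr)[i])]]
      pat <- if (minus[i]) reverseComplement(DNAString(seqs[i]))
             else DNAString(seqs[i])
      neditStartingAt(pat, ref, starting.at = start(gr)[i],
                      with.indels = FALSE)
    }, integer(1))
  }
  gr$seqId <- seqs
  gr$mismatches <- as.integer(nm)
  gr$fivePrime <- ifelse(minus, end(gr), start(gr))
  sortHits(gr)
}

# deterministic hit ordering: contig name, start, strand, sequence
sortHits <- function(gr) {
  o <- order(as.character(seqnames(gr)), start(gr),
             as.character(strand(gr)), gr$seqId, method = "radix")
  gr[o]
}

#' Write a report table deterministically
#'
#' TSV reports carry genomic coordinates 1-based inclusive (matching printed
#' tables); JSON reports emit 0-based half-open coordinates. Rows are written
#' in their current order (producers sort before calling); two writes of the
#' same table are byte-identical.
#'
#' @param table a data.frame; rows must share one schema.
#' @param path output file.
#' @param dialect `"TSV"` or `"JSON"`.
#' @return `path`, invisibly.
#' @export
writeReport <- function(table, path, dialect = c("TSV", "JSON")) {
  dialect <- match.arg(toupper(dialect[1L]), c("TSV", "JSON"))
  table <- as.data.frame(table)
  if (dialect == "TSV") {
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    if ("start" %in% colnames(table) && is.numeric(table$start))
      table$start <- table$start - 1L  # 0-based half-open in JSON
    jsonlite::write_json(table, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(path)
}
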