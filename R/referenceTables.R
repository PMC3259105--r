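#' Bundled reference tabulations from the mosquito piRNA literature
#'
#' Three small published reference tables are shipped with the package and
#' used to check that its reporting conventions (half-up rounding of
#' percentages at 2 decimals, cluster sizes at whole kb, gene densities at
#' 1 decimal; 1-based inclusive printed coordinates) reproduce printed
#' values from their printed counts:
#'
#' * `"clusters"` — genomic coordinates and printed sizes (kb) of the top
#'   30 *Ae. aegypti* piRNA clusters;
#' * `"teTally"` — read and distinct-sequence counts of piRNA/siRNA classes
#'   matching TE consensus databases, with printed percentages, for
#'   *Ae. aegypti* and *D. melanogaster*;
#' * `"geneDensity"` — the top 30 *Ae. aegypti* genes by density of
#'   uniquely mapping piRNAs, with printed densities.
#'
#' @param which one of `"clusters"`, `"teTally"`, `"geneDensity"`.
#' @return the requested table as a data.frame.
#' @examples
#' head(referenceTable("clusters"))
#' @export
referenceTable <- function(which = c("clusters", "teTally", "geneDensity")) {
  which <- match.arg(which)
  file <- switch(which,
                 clusters = "reference_cluster_coordinates.tsv",
                 teTally = "reference_te_tally.tsv",
                 geneDensity = "reference_gene_density.tsv")
  path <- system.file("extdata", file, package = "piRNAkit",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Cluster size in kb from printed coordinates
#'
#' The reporting convention for cluster sizes: length of the 1-based
#' inclusive printed interval, half-up rounded to whole kb.
#'
#' @param start,stop printed 1-based inclusive coordinates.
#' @return integer size in kb.
#' @export
clusterSizeKb <- function(start, stop) {
  as.integer(roundHalfUp((stop - start + 1) / 1000))
}

#' Gene piRNA density from printed counts
#'
#' The reporting convention for gene densities: distinct uniquely mapping
#' piRNAs per gene base, half-up rounded to 1 decimal.
#'
#' @param count distinct uniquely mapping piRNAs in the gene span.
#' @param lengthBp gene length in bp.
#' @return density at 1 decimal.
#' @export
geneDensity <- function(count, lengthBp) {
  stopifnot(all(lengthBp >= 1))
  roundHalfUp(count / lengthBp, 1L)
}
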