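#' Run the full analysis on a simulated study and write the report bundle
#'
#' Orchestrates every stage on generator output: preprocessing (contaminant
#' removal and, in raw mode, adapter stripping), size-class partitioning,
#' genome mapping, cluster discovery with the TE-content null model,
#' ping-pong profiling, target/TE/gene annotation, transgene detection and
#' pool-size estimation. Writes eight fixed-name report files plus a run
#' manifest to `outDir`; the bundle is deterministic given (config, seed).
#'
#' @param config a [simConfig()].
#' @param outDir output directory.
#' @param seed integer master seed.
#' @param nNullSamples Monte-Carlo samples for the per-cluster TE null
#'   (default 1000).
#' @return (invisibly) a list with the in-memory results: `sim`, `clean`,
#'   `mappings`, `clusters`, `nullStats`, `profile`, `teTally`,
#'   `geneDensity`, `transgene`, `poolEstimate`, `coverage`, `manifest`.
#' @export
runEndToEnd <- function(config = simConfig(), outDir, seed = 1L,
                        nNullSamples = 1000L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateStudy(config, seed)
  assembly <- sim$genome$assembly
  rule <- sizeClassRule()

  clean <- list()
  pirnaLibs <- list()
  mappings <- list()
  for (id in names(sim$libraries)) {
    pp <- preprocessLibrary(
      sim$libraries[[id]],
      adapter = if (config$adapterRate > 0) config$adapter else NULL,
      rrnaRef = sim$genome$contaminantRef)
    clean[[id]] <- pp$library
    parts <- partitionBySize(pp$library, rule)
    pirnaLibs[[id]] <- parts$pirna
    mappings[[id]] <- mapLibrary(parts$pirna, assembly)
  }

  # combined piRNA analysis across libraries
  combined <- do.call(mergeLibraries, c(unname(pirnaLibs),
                                        list(id = "combined")))
  combinedMap <- mapLibrary(combined, assembly)
  uh <- uniqueHits(combinedMap)

  wc <- windowCounts(uh, config$windowSize)
  clusters <- callClusters(wc, uh, config$windowSize)
  clusters <- summarizeClusters(clusters, mappings, pirnaLibs,
                                config$windowSize)
  cov <- coverageSummary(clusters, assembly, uh)
  nullStats <- if (length(clusters))
    do.call(rbind, lapply(seq_along(clusters), function(i)
      cbind(clusterId = clusters$rank[i],
            teNullZscores(clusters[i], sim$genome$teFeatures, assembly,
                          nNullSamples, seed = seed + 1000L + i))))
  else NULL

  profile <- overlapProfile(uh, minLen = rule$poolMin)

  targets <- classifyTargets(combinedMap, sim$genome$geneFeatures,
                             sim$genome$teFeatures)
  occupancy <- genomeOccupancy(sim$genome$geneFeatures,
                               sim$genome$teFeatures, assembly)
  teTally <- tallyTeFamilies(combined, sim$genome$teConsensus,
                             sim$genome$teClasses)
  geneDensity <- rankGeneDensity(sim$genome$geneFeatures, uh, clusters)
  transgene <- detectTransgenePirnas(combined, combinedMap,
                                     sim$genome$plasmids)

  poolLibs <- lapply(names(clean), function(id) {
    parts <- partitionBySize(clean[[id]], rule)
    sp <- splitByGenomeMapping(parts$pool_pirna, assembly)
    sp$mapped
  })
  poolEstimate <- suppressWarnings(
    estimatePool(poolLibs, replicateGroups = config$replicateGroups,
                 poolMin = rule$poolMin))

  # report bundle (fixed names, deterministic content)
  sizeTab <- as.data.frame(targets$table)
  writeReport(sizeTab, file.path(outDir, "size_target_table.tsv"), "TSV")
  writeReport(clusterTable(clusters), file.path(outDir, "clusters.tsv"),
              "TSV")
  if (!is.null(nullStats))
    writeReport(nullStats, file.path(outDir, "cluster_null.tsv"), "TSV")
  else writeReport(data.frame(), file.path(outDir, "cluster_null.tsv"),
                   "TSV")
  writeReport(teTally$classes, file.path(outDir, "te_tally.tsv"), "TSV")
  writeReport(transgene$counts, file.path(outDir, "transgene_matrix.tsv"),
              "TSV")
  writeReport(geneDensity, file.path(outDir, "gene_density.tsv"), "TSV")
  hist <- data.frame(overlap = as.integer(names(profile@histogram)),
                     pairs = as.integer(profile@histogram))
  writeReport(hist, file.path(outDir, "overlap_profile.tsv"), "TSV")
  jsonlite::write_json(
    list(mean = poolMean(poolEstimate),
         minimum = unname(poolRange(poolEstimate)[1L]),
         maximum = unname(poolRange(poolEstimate)[2L]),
         nPairs = poolEstimate@nPairs),
    file.path(outDir, "pool_estimate.json"), auto_unbox = TRUE, digits = NA)

  manifest <- list(
    seed = seed,
    config = config[setdiff(names(config), "abundanceModel")],
    abundanceModel = config$abundanceModel,
    nLibraries = length(sim$libraries),
    genomeFractionInClusters = cov$genomeFraction,
    pirnaFractionFromClusters = cov$pirnaFraction,
    occupancy = as.list(occupancy),
    outputs = c("size_target_table.tsv", "clusters.tsv", "cluster_null.tsv",
                "te_tally.tsv", "transgene_matrix.tsv", "gene_density.tsv",
                "overlap_profile.tsv", "pool_estimate.json"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(sim = sim, clean = clean, mappings = mappings,
                 clusters = clusters, nullStats = nullStats,
                 profile = profile, teTally = teTally,
                 geneDensity = geneDensity, transgene = transgene,
                 poolEstimate = poolEstimate, coverage = cov,
                 occupancy = occupancy, manifest = manifest))
}

#' Merge libraries into one combined library
#'
#' Multiplicities of shared sequences are summed.
#'
#' @param ... [SmallRNALibrary-class] objects.
#' @param id identifier of the merged library.
#' @return a [SmallRNALibrary-class].
#' @export
mergeLibraries <- function(..., id = "combined") {
  libs <- list(...)
  SmallRNALibrary(
    unlist(lapply(libs, sequences), use.names = FALSE),
    unlist(lapply(libs, function(l) unname(readCounts(l)))),
    id = id)
}

#' Verify that report percentages recompute from their counts
#'
#' Recomputes every percentage column of a tally report (first row = total)
#' from the count columns, half-up at 2 decimals, and lists mismatches.
#'
#' @param report data.frame with columns `reads`, `distinct`, `pctReads`,
#'   `pctDistinct` whose first row is the total.
#' @return list: `pass` (logical) and `discrepancies` (data.frame of
#'   row/column/reported/recomputed for every mismatch).
#' @export
checkPercentages <- function(report) {
  stopifnot(all(c("reads", "distinct", "pctReads", "pctDistinct") %in%
                colnames(report)))
  expReads <- roundHalfUp(100 * report$reads / report$reads[1L], 2L)
  expDist <- roundHalfUp(100 * report$distinct / report$distinct[1L], 2L)
  one <- function(bad, col, reported, recomputed) {
    if (!any(bad)) return(NULL)
    data.frame(row = which(bad), column = col, reported = reported[bad],
               recomputed = recomputed[bad])
  }
  disc <- rbind(one(expReads != report$pctReads, "pctReads",
                    report$pctReads, expReads),
                one(expDist != report$pctDistinct, "pctDistinct",
                    report$pctDistinct, expDist))
  if (is.null(disc))
    disc <- data.frame(row = integer(), column = character(),
                       reported = numeric(), recomputed = numeric())
  list(pass = nrow(disc) == 0L, discrepancies = disc)
}
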