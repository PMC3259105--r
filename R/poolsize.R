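#' Eligible-sequence overlap between two libraries
#'
#' Eligibility for pool-size estimation: length >= `poolMin` and, when
#' `excludeDuplicated` (the default), a within-library multiplicity of
#' exactly 1 — highly duplicated sequences inflate the recapture overlap
#' and bias the estimate downward, so duplicated sequences are excluded
#' from the library in which they are duplicated. The caller supplies
#' genome-filtered libraries (see [splitByGenomeMapping()]). Symmetric in
#' its arguments.
#'
#' @param libA,libB [SmallRNALibrary-class] objects.
#' @param poolMin minimum eligible length (default 24).
#' @param excludeDuplicated exclude multiplicity > 1 sequences per library
#'   (default TRUE).
#' @return list with `nA`, `nB` (eligible distinct counts) and `k` (shared
#'   eligible sequences).
#' @export
pairOverlapCounts <- function(libA, libB, poolMin = 24L,
                              excludeDuplicated = TRUE) {
  elig <- function(lib) {
    cnt <- readCounts(lib)
    cnt <- cnt[nchar(names(cnt)) >= poolMin]
    if (excludeDuplicated) cnt <- cnt[cnt == 1L]
    names(cnt)
  }
  a <- elig(libA)
  b <- elig(libB)
  list(nA = length(a), nB = length(b), k = length(intersect(a, b)))
}

#' Lincoln-Petersen estimate
#'
#' The two-sample capture-recapture estimator `N = nA * nB / k`. With
#' `chapman = TRUE` the bias-corrected Chapman variant
#' `(nA+1)(nB+1)/(k+1) - 1` is returned instead (offered for comparison,
#' not the default).
#'
#' @param nA,nB eligible counts of the two samples.
#' @param k shared count.
#' @param chapman use the Chapman correction (default FALSE).
#' @return the estimate; `NA` with a warning when `k` is 0 (plain
#'   estimator only).
#' @export
lpEstimate <- function(nA, nB, k, chapman = FALSE) {
  if (chapman) return((nA + 1) * (nB + 1) / (k + 1) - 1)
  if (k == 0) {
    warning("zero overlap: estimate undefined for this pair")
    return(NA_real_)
  }
  nA * nB / k
}

#' Estimate pool size over all non-replicate library pairs
#'
#' Evaluates [lpEstimate()] on every unordered pair of libraries whose
#' replicate groups differ, and summarises the defined estimates by
#' mean/min/max. Pairs with zero overlap are dropped with a warning; an
#' error is raised when every pair is dropped. Invariant to library order.
#'
#' @param libraries list of [SmallRNALibrary-class] (genome-filtered).
#' @param replicateGroups optional character vector of group labels
#'   (defaults to each library's `replicateGroup` slot).
#' @param poolMin,excludeDuplicated see [pairOverlapCounts()].
#' @param chapman see [lpEstimate()].
#' @return a [PoolEstimate-class].
#' @export
estimatePool <- function(libraries, replicateGroups = NULL, poolMin = 24L,
                         excludeDuplicated = TRUE, chapman = FALSE) {
  if (is.null(replicateGroups))
    replicateGroups <- vapply(libraries, replicateGroup, "")
  stopifnot(length(replicateGroups) == length(libraries))
  ids <- vapply(libraries, libId, "")
  o <- order(ids)  # order-invariant evaluation
  libraries <- libraries[o]
  replicateGroups <- replicateGroups[o]
  ids <- ids[o]
  n <- length(libraries)
  rows <- list()
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (replicateGroups[i] == replicateGroups[j]) next
    po <- pairOverlapCounts(libraries[[i]], libraries[[j]], poolMin,
                            excludeDuplicated)
    est <- if (po$k == 0) NA_real_ else po$nA * po$nB / po$k
    rows[[length(rows) + 1L]] <- DataFrame(
      libA = ids[i], libB = ids[j], nA = po$nA, nB = po$nB, k = po$k,
      estimate = est)
  }
  if (!length(rows)) stop("no non-replicate library pairs to evaluate")
  pairs <- do.call(rbind, rows)
  dropped <- sum(is.na(pairs$estimate))
  if (dropped) warning(dropped, " pair(s) dropped (zero overlap)")
  est <- pairs$estimate[!is.na(pairs$estimate)]
  if (!length(est)) stop("all pairs dropped: pool size inestimable")
  new("PoolEstimate", pairs = pairs, mean = mean(est), minimum = min(est),
      maximum = max(est), nPairs = length(est),
      nDropped = as.integer(dropped))
}

#' In-silico validation of the pool-size estimator
#'
#' Simulates libraries by drawing reads (with the configured abundance
#' skew) from a latent pool of `truePoolSize` distinct sequences, runs
#' [estimatePool()] on each replicate, and reports bias and dispersion.
#' Simulation is at the pool-index level: the estimator consumes only
#' eligibility sets, so sequence identity is irrelevant and integer ids
#' stand in for sequences.
#'
#' @param truePoolSize latent pool size N.
#' @param librarySizes integer vector of per-library read depths (>= 2
#'   libraries; all treated as non-replicates).
#' @param abundanceModel `"uniform"` or `"lognormal"`.
#' @param sigma log-normal sd (default 1; ignored for uniform).
#' @param reps number of simulation replicates (default 50).
#' @param seed integer seed.
#' @param excludeDuplicated apply the duplicate-exclusion rule (default
#'   TRUE).
#' @return list: `estimates` (per-rep mean estimates), `meanEstimate`,
#'   `meanRelBias`, `minimum`, `maximum`, `rangeCoverage` (fraction of reps
#'   whose per-pair min-max range contains N).
#' @export
validateEstimator <- function(truePoolSize, librarySizes,
                              abundanceModel = c("uniform", "lognormal"),
                              sigma = 1, reps = 50L, seed = 1L,
                              excludeDuplicated = TRUE) {
  abundanceModel <- match.arg(abundanceModel)
  stopifnot(reps >= 1L, length(librarySizes) >= 2L)
  # encode pool indices as fixed-length ACGT strings (base-4 digits)
  idToSeq <- function(ids, len = 28L) {
    m <- matrix("A", nrow = length(ids), ncol = len)
    x <- ids
    for (p in len:1) {
      m[, p] <- c("A", "C", "G", "T")[x %% 4L + 1L]
      x <- x %/% 4L
    }
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  set.seed(as.integer(seed))
  estimates <- numeric(reps)
  covered <- logical(reps)
  for (r in seq_len(reps)) {
    w <- if (abundanceModel == "uniform") rep(1, truePoolSize)
         else rlnorm(truePoolSize, 0, sigma)
    libs <- lapply(seq_along(librarySizes), function(i) {
      draw <- sample.int(truePoolSize, librarySizes[i], replace = TRUE,
                         prob = w)
      cnt <- tabulate(draw, nbins = truePoolSize)
      ids <- which(cnt > 0L)
      SmallRNALibrary(idToSeq(ids), cnt[ids], id = sprintf("sim%02d", i))
    })
    pe <- suppressWarnings(
      estimatePool(libs, replicateGroups = as.character(seq_along(libs)),
                   poolMin = 0L, excludeDuplicated = excludeDuplicated))
    estimates[r] <- poolMean(pe)
    covered[r] <- pe@minimum <= truePoolSize && truePoolSize <= pe@maximum
  }
  list(estimates = estimates, meanEstimate = mean(estimates),
       meanRelBias = mean(estimates) / truePoolSize - 1,
       minimum = min(estimates), maximum = max(estimates),
       rangeCoverage = mean(covered))
}
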