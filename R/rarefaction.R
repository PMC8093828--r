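## Fixed tail of the downsampling ladder; the first level is data-dependent.
.LADDER_TAIL <- c(12500L, 10000L, 7500L, 5000L, 2500L, 1000L, 500L,
                  400L, 300L, 200L, 100L, 50L)

#' Build the downsampling ladder for a table
#'
#' The first level equals the shallowest retained sample's depth. A dataset
#' sequenced far deeper than usual would make its first level incomparable
#' with other datasets, so when the shallowest sample exceeds twice `cap`
#' (default 15,000) the first level is pulled back to `cap`. The remaining
#' levels are the fixed tail 12500, 10000, 7500, 5000, 2500, 1000, 500,
#' 400, 300, 200, 100, 50. Tail levels at or above the first level are
#' dropped, so a table whose shallowest sample is exactly 15,000 reads
#' yields 13 unique levels and shallower (synthetic) tables yield
#' proportionally fewer.
#'
#' @param x an [AsvExperiment] that has passed the depth filter.
#' @param cap upper bound on the first ladder level.
#' @return a [DepthLadder].
#' @export
buildLadder <- function(x, cap = 15000) {
  stopifnot(is(x, "AsvExperiment"))
  .assertCount(cap, "cap", positive = TRUE)
  min_total <- min(sampleDepths(x))
  if (min_total < min(.LADDER_TAIL))
    stop("shallowest sample (", min_total,
         " reads) is below the smallest ladder level (",
         min(.LADDER_TAIL), ")", call. = FALSE)
  first <- as.integer(if (min_total > 2 * cap) cap else min_total)
  new("DepthLadder",
      levels = c(first, .LADDER_TAIL[.LADDER_TAIL < first]),
      includesFull = TRUE)
}

#' Rarefy one sample's counts without replacement
#'
#' Draws a uniform random subset of `depth` reads from the sample's reads —
#' a multivariate hypergeometric draw — implemented as sequential per-ASV
#' conditional hypergeometric draws (O(ASVs) cost, distributionally
#' identical to drawing the subset read-by-read). The result sums exactly
#' to `depth` and never exceeds the original counts componentwise.
#'
#' @param counts non-negative integer vector of per-ASV read counts.
#' @param depth target number of reads; must not exceed `sum(counts)`.
#' @param seed integer seed; the draw is reproducible from it.
#' @return integer vector of rarefied counts (same length as `counts`).
#' @export
rarefySample <- function(counts, depth, seed) {
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("'counts' must be non-negative integers", call. = FALSE)
  .assertCount(depth, "depth")
  total <- sum(counts)
  if (depth > total)
    stop("cannot draw ", depth, " reads from a sample with ", total,
         " reads (sampling with replacement is never done)", call. = FALSE)
  if (depth == total) return(as.integer(counts))
  out <- integer(length(counts))
  .withSeed(seed, {
    rest <- total
    left <- as.integer(depth)
    for (i in seq_along(counts)) {
      if (left == 0L) break
      ni <- counts[i]
      rest <- rest - ni
      if (ni == 0L) next
      if (rest == 0L) {        # everything remaining must be drawn
        out[i] <- left
        left <- 0L
        break
      }
      x <- rhyper(1L, m = ni, n = rest, k = left)
      out[i] <- x
      left <- left - x
    }
  })
  out
}

#' Rarefy every sample of a table to a common depth
#'
#' Applies [rarefySample()] independently per sample with a sub-seed
#' derived from `(seed, sample index)`; labels and the ASV axis are
#' preserved (all-zero ASV rows are allowed after rarefaction).
#'
#' @param x an [AsvExperiment] in which every sample total is >= `depth`.
#' @param depth target per-sample depth.
#' @param seed master seed for the per-sample sub-streams.
#' @return an `AsvExperiment` whose sample totals all equal `depth`.
#' @export
rarefyTable <- function(x, depth, seed) {
  stopifnot(is(x, "AsvExperiment"))
  m <- asvCounts(x)
  out <- m
  for (j in seq_len(ncol(m)))
    out[, j] <- rarefySample(m[, j], depth, .subSeed(seed, 7L, j))
  res <- AsvExperiment(out, labels = as.character(classLabels(x)))
  metadata(res) <- metadata(x)
  metadata(res)$rarefied_depth <- as.integer(depth)
  res
}

#' Bias-corrected Chao1 richness estimate
#'
#' `S_obs + f1 * (f1 - 1) / (2 * (f2 + 1))`, where `f1` and `f2` are the
#' numbers of singleton and doubleton ASVs. The bias-corrected form is
#' defined even when no doubletons exist, and never falls below the
#' observed richness.
#'
#' @param abundances non-negative integer vector of per-ASV read counts
#'   (pooled over the samples of interest).
#' @return the Chao1 estimate (a single number).
#' @export
chao1 <- function(abundances) {
  if (!length(abundances))
    stop("'abundances' is empty", call. = FALSE)
  if (any(abundances < 0) || any(abundances != floor(abundances)))
    stop("'abundances' must be non-negative integers", call. = FALSE)
  s_obs <- sum(abundances > 0)
  f1 <- sum(abundances == 1)
  f2 <- sum(abundances == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Observed richness as a percentage of the Chao1 estimate
#'
#' @param observed_richness observed number of ASVs (> 0).
#' @param chao1_estimate a Chao1 estimate `>= observed_richness`.
#' @return coverage in percent (100 = complete).
#' @export
coverageFraction <- function(observed_richness, chao1_estimate) {
  if (chao1_estimate <= 0) stop("Chao1 estimate must be > 0", call. = FALSE)
  if (observed_richness <= 0)
    stop("observed richness must be > 0", call. = FALSE)
  if (chao1_estimate < observed_richness)
    stop("Chao1 estimate cannot be below the observed richness",
         call. = FALSE)
  100 * observed_richness / chao1_estimate
}

#' Dataset-level sampling coverage
#'
#' Pools counts over all samples and reports observed richness, the
#' bias-corrected Chao1 estimate, and observed/Chao1 coverage in percent.
#'
#' @param x an [AsvExperiment].
#' @return a one-row data.frame with `observed`, `chao1`, `coverage_pct`.
#' @export
datasetCoverage <- function(x) {
  stopifnot(is(x, "AsvExperiment"))
  pooled <- rowSums(asvCounts(x))
  est <- chao1(pooled)
  data.frame(observed = sum(pooled > 0), chao1 = est,
             coverage_pct = coverageFraction(sum(pooled > 0), est))
}

#' Sampling-coverage trajectory along a depth ladder
#'
#' The pooled full-depth table's bias-corrected Chao1 estimate is taken as
#' the theoretical total richness (100% coverage); the full table and each
#' rarefied ladder level then contribute their pooled observed richness as
#' a percentage of that fixed total. Coverage is therefore non-increasing
#' as depth decreases.
#'
#' @param x an [AsvExperiment].
#' @param depths rarefaction depths (e.g. `ladderLevels(buildLadder(x))`).
#' @param seed seed for the per-level rarefactions.
#' @return data.frame with one row for the full table (`depth = NA`) and
#'   one per level: `depth`, `observed`, `coverage_pct`.
#' @export
coverageTrajectory <- function(x, depths, seed = 1) {
  stopifnot(is(x, "AsvExperiment"))
  total <- chao1(rowSums(asvCounts(x)))
  obs <- vapply(depths, function(d)
    sum(rowSums(asvCounts(rarefyTable(x, d, seed = .subSeed(seed, 13L, d)))) > 0),
    numeric(1))
  full_obs <- sum(rowSums(asvCounts(x)) > 0)
  data.frame(depth = c(NA_integer_, as.integer(depths)),
             observed = c(full_obs, obs),
             chao1_full = total,
             coverage_pct = 100 * c(full_obs, obs) / total)
}

#' Exact expected rarefaction curve
#'
#' Expected number of ASVs observed in a without-replacement subsample of
#' each probe depth `d`:
#' `E[S_d] = sum_a (1 - choose(N - n_a, d) / choose(N, d))`,
#' evaluated on the log scale (`lchoose`) so large read totals do not
#' overflow. This is the analytic counterpart of repeatedly rarefying and
#' counting.
#'
#' @param counts non-negative integer vector of per-ASV counts (one sample
#'   or a pooled dataset).
#' @param probe_depths integer depths at which to evaluate the curve; none
#'   may exceed `sum(counts)`.
#' @return data.frame with columns `depth` and `expected_richness`.
#' @export
rarefactionCurve <- function(counts, probe_depths) {
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("'counts' must be non-negative integers", call. = FALSE)
  total <- sum(counts)
  if (any(probe_depths > total))
    stop("probe depth exceeds the sample total (", total, ")",
         call. = FALSE)
  if (any(probe_depths < 0))
    stop("probe depths must be non-negative", call. = FALSE)
  n_a <- counts[counts > 0]
  expected <- vapply(probe_depths, function(d) {
    if (d == 0) return(0)
    sum(1 - exp(lchoose(total - n_a, d) - lchoose(total, d)))
  }, numeric(1))
  data.frame(depth = as.integer(probe_depths),
             expected_richness = expected)
}
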