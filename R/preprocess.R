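#' Filter rare ASVs by total read count
#'
#' Retains the ASVs whose read count summed over all samples is at least
#' `min_total_reads` (default 50, the usual noise floor for denoised
#' amplicon tables). The sample axis and the relative order of retained
#' ASVs are unchanged. Applied once, on the full-depth table: rarefied
#' tables inherit the retained ASV set so the feature space is constant
#' across ladder levels.
#'
#' @param x an [AsvExperiment].
#' @param min_total_reads minimum summed read count for an ASV to be kept.
#' @return the filtered `AsvExperiment`.
#' @export
filterLowAbundanceAsvs <- function(x, min_total_reads = 50) {
  stopifnot(is(x, "AsvExperiment"))
  .assertCount(min_total_reads, "min_total_reads")
  keep <- rowSums(asvCounts(x)) >= min_total_reads
  if (!any(keep))
    stop("no ASV reaches ", min_total_reads,
         " total reads; the filtered table would be empty", call. = FALSE)
  x[keep, ]
}

#' Filter samples below a sequencing-depth threshold
#'
#' Discards samples whose total read count is below `min_depth` (default
#' 15,000). If the filter would eliminate every sample of some class the
#' classification task can no longer be posed, and an error names the lost
#' class. Discarded sample ids are recorded in
#' `metadata(.)$discarded_samples`.
#'
#' @param x an [AsvExperiment].
#' @param min_depth minimum per-sample read total.
#' @return the filtered `AsvExperiment`.
#' @export
filterShallowSamples <- function(x, min_depth = 15000) {
  stopifnot(is(x, "AsvExperiment"))
  .assertCount(min_depth, "min_depth")
  if (min_depth == 0) return(x)
  depths <- sampleDepths(x)
  keep <- depths >= min_depth
  if (!any(keep))
    stop("all samples fall below ", min_depth, " reads", call. = FALSE)
  before <- levels(classLabels(x))
  after <- unique(as.character(classLabels(x))[keep])
  lost <- setdiff(before, after)
  if (length(lost))
    stop("depth filter eliminates every sample of class: ",
         paste(lost, collapse = ", "), call. = FALSE)
  out <- x[, keep]
  metadata(out)$discarded_samples <- colnames(x)[!keep]
  out
}

#' Transform counts to per-sample relative abundances
#'
#' Divides each ASV's read count by the sample's total read count, the
#' standard compensation for unequal sequencing depth before classifier
#' training.
#'
#' @param x an [AsvExperiment]; every sample total must be positive (the
#'   depth filter guarantees this in the standard pipeline).
#' @return a [RelAbundanceExperiment]; each sample's values sum to 1
#'   within 1e-9.
#' @export
toRelativeAbundance <- function(x) {
  stopifnot(is(x, "AsvExperiment"))
  m <- asvCounts(x)
  tot <- colSums(m)
  if (any(tot == 0))
    stop("sample(s) with zero total reads: ",
         paste(colnames(m)[tot == 0], collapse = ", "), call. = FALSE)
  rel <- sweep(m, 2L, tot, "/")
  se <- SummarizedExperiment(assays = list(relabund = rel),
                             colData = colData(x))
  new("RelAbundanceExperiment", se)
}
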