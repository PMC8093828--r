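#' AsvExperiment: an ASV count table with per-sample class labels
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' `"counts"` assay of non-negative integer ASV read counts (ASVs as rows,
#' samples as columns) and a `class_label` factor in `colData` giving the
#' categorical class of each sample (e.g. a biotic-index category, a
#' production phase, a geographic origin).
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @export
setClass("AsvExperiment", contains = "SummarizedExperiment")

setValidity("AsvExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% names(assays(object)))
    return("assay 'counts' is required")
  m <- assay(object, "counts")
  if (!is.numeric(m))
    msg <- c(msg, "counts must be numeric")
  else {
    if (any(is.na(m))) msg <- c(msg, "counts contain NA")
    else {
      if (any(m < 0)) msg <- c(msg, "counts contain negative values")
      if (any(m != floor(m))) msg <- c(msg, "counts contain non-integers")
    }
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "ASV ids (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  if (!"class_label" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'class_label' column")
  if (length(msg)) msg else TRUE
})

#' @describeIn AsvExperiment Constructor. `counts` is an ASVs x samples
#'   matrix (rownames = ASV ids, colnames = sample ids); `labels` one class
#'   per sample.
#' @param counts ASVs x samples non-negative integer matrix.
#' @param labels character or factor vector of per-sample class labels.
#' @return an `AsvExperiment`.
#' @export
AsvExperiment <- function(counts, labels) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("ASV_%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("S%03d", seq_len(ncol(counts)))
  if (length(labels) != ncol(counts))
    stop("'labels' must have one entry per sample (column)", call. = FALSE)
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(class_label = factor(labels),
                        row.names = colnames(counts)))
  new("AsvExperiment", se)
}

#' RelAbundanceExperiment: per-sample relative abundances
#'
#' Same axes as [AsvExperiment] but with a `"relabund"` assay whose columns
#' (samples) each sum to 1; produced by [toRelativeAbundance()].
#'
#' @export
setClass("RelAbundanceExperiment", contains = "SummarizedExperiment")

setValidity("RelAbundanceExperiment", function(object) {
  if (!"relabund" %in% names(assays(object)))
    return("assay 'relabund' is required")
  m <- assay(object, "relabund")
  if (any(m < 0) || any(m > 1))
    return("relative abundances must lie in [0, 1]")
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-9))
    return("each sample's relative abundances must sum to 1 (tol 1e-9)")
  if (!"class_label" %in% colnames(colData(object)))
    return("colData must contain a 'class_label' column")
  TRUE
})

#' DepthLadder: the ordered set of rarefaction target depths
#'
#' @slot levels strictly decreasing positive integer depths; the first level
#'   is tied to the shallowest retained sample (capped), the remainder are
#'   the fixed tail 12500, 10000, 7500, 5000, 2500, 1000, 500, 400, 300,
#'   200, 100, 50 (levels not below the first are dropped).
#' @slot includesFull whether the full-depth model is part of the sweep.
#' @export
setClass("DepthLadder",
         representation(levels = "integer", includesFull = "logical"))

setValidity("DepthLadder", function(object) {
  lv <- object@levels
  if (!length(lv)) return("ladder has no levels")
  if (any(lv <= 0)) return("ladder levels must be positive")
  if (any(diff(lv) >= 0)) return("ladder levels must be strictly decreasing")
  TRUE
})

#' ModelGridResult: all RF grid records evaluated at one depth level
#'
#' @slot depth target rarefaction depth; `NA` for the full-depth model.
#' @slot records one row per grid configuration: `mtry`, `run`, `seed`,
#'   `oob_error`, `accuracy`, `kappa`.
#' @export
setClass("ModelGridResult",
         representation(depth = "numeric", records = "data.frame"))

setValidity("ModelGridResult", function(object) {
  need <- c("mtry", "run", "seed", "oob_error", "accuracy", "kappa")
  if (!all(need %in% names(object@records)))
    return(paste("records must contain columns:", paste(need, collapse = ", ")))
  if (any(object@records$kappa > 1 + 1e-12, na.rm = TRUE))
    return("kappa cannot exceed 1")
  TRUE
})

#' DepthDecision: the minimum-depth verdict of a sweep
#'
#' @slot benchmarkBand agreement band of the full model's summary kappa
#'   (`"poor"`, `"moderate"` or `"almost_perfect"`).
#' @slot benchmarkKappa,benchmarkAccuracy full-model summary statistics.
#' @slot minDepth smallest ladder depth whose band (and every deeper
#'   level's band) still matches the benchmark; `NA` if not reached.
#' @slot reached whether any contiguous run of passing levels exists.
#' @slot levelSummary per-level table: depth, median kappa, mean OOB error,
#'   band, pass flag, best-model statistics.
#' @export
setClass("DepthDecision",
         representation(benchmarkBand = "character",
                        benchmarkKappa = "numeric",
                        benchmarkAccuracy = "numeric",
                        minDepth = "numeric",
                        reached = "logical",
                        levelSummary = "data.frame"))

#' SeparabilityReport: diagnostics of class-boundary hardness
#'
#' @slot gini Gini coefficient of the class-frequency distribution.
#' @slot cv per-feature coefficient of variation of class means (features
#'   with zero grand mean excluded).
#' @slot nExcludedFeatures number of features excluded from the CV.
#' @slot sharedAsv,sharedReads shared / per-class-exclusive feature
#'   fractions under ASV-count and read-count weighting.
#' @slot ordination per-sample NMDS coordinates with class labels.
#' @slot stress NMDS stress of the retained solution.
#' @slot ellipseOverlap symmetric matrix of pairwise confidence-ellipse
#'   overlap fractions (unit diagonal).
#' @slot confidence ellipse confidence level.
#' @export
setClass("SeparabilityReport",
         representation(gini = "numeric",
                        cv = "numeric",
                        nExcludedFeatures = "integer",
                        sharedAsv = "list",
                        sharedReads = "list",
                        ordination = "data.frame",
                        stress = "numeric",
                        ellipseOverlap = "matrix",
                        confidence = "numeric"))
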