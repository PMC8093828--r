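#' @rdname AsvExperiment
#' @aliases asvCounts,AsvExperiment-method
#' @export
setMethod("asvCounts", "AsvExperiment", function(x) assay(x, "counts"))

#' @rdname AsvExperiment
#' @export
setMethod("classLabels", "AsvExperiment",
          function(x) droplevels(factor(colData(x)$class_label)))

#' @rdname RelAbundanceExperiment-class
#' @export
setMethod("classLabels", "RelAbundanceExperiment",
          function(x) droplevels(factor(colData(x)$class_label)))

#' @rdname AsvExperiment
#' @export
setMethod("sampleDepths", "AsvExperiment",
          function(x) colSums(assay(x, "counts")))

#' @rdname RelAbundanceExperiment-class
#' @export
setMethod("relAbundance", "RelAbundanceExperiment",
          function(x) assay(x, "relabund"))

#' @rdname DepthLadder-class
#' @export
setMethod("ladderLevels", "DepthLadder", function(x) x@levels)

#' @rdname ModelGridResult-class
#' @export
setMethod("gridRecords", "ModelGridResult", function(x) x@records)

#' @rdname ModelGridResult-class
#' @export
setMethod("medianKappa", "ModelGridResult",
          function(x) median(x@records$kappa))

#' @rdname ModelGridResult-class
#' @export
setMethod("meanOobError", "ModelGridResult",
          function(x) mean(x@records$oob_error))

#' Best grid model: maximum kappa, ties broken by lower OOB error then
#' lower mtry.
#' @rdname ModelGridResult-class
#' @export
setMethod("bestModel", "ModelGridResult", function(x) {
  r <- x@records
  o <- order(-r$kappa, r$oob_error, r$mtry)
  r[o[1L], , drop = FALSE]
})

#' @rdname DepthDecision-class
#' @export
setMethod("minDepth", "DepthDecision", function(x) x@minDepth)

#' @rdname DepthDecision-class
#' @export
setMethod("levelSummary", "DepthDecision", function(x) x@levelSummary)

#' @rdname SeparabilityReport-class
#' @export
setMethod("ellipseOverlap", "SeparabilityReport", function(x) x@ellipseOverlap)

#' @rdname SeparabilityReport-class
#' @export
setMethod("featureCvValues", "SeparabilityReport", function(x) x@cv)

#' @describeIn AsvExperiment compact display.
#' @param object an object.
#' @export
setMethod("show", "AsvExperiment", function(object) {
  lab <- classLabels(object)
  cat("AsvExperiment:", nrow(object), "ASVs x", ncol(object), "samples\n")
  cat("  depth range:",
      paste(range(sampleDepths(object)), collapse = " - "), "reads\n")
  cat("  classes:",
      paste(sprintf("%s (n=%d)", levels(lab), tabulate(lab)),
            collapse = ", "), "\n")
})

#' @rdname DepthLadder-class
#' @param object an object.
#' @export
setMethod("show", "DepthLadder", function(object) {
  cat("DepthLadder with", length(object@levels), "levels",
      if (object@includesFull) "(+ full model)" else "", "\n")
  cat(" ", paste(object@levels, collapse = ", "), "\n")
})

#' @rdname ModelGridResult-class
#' @param object an object.
#' @export
setMethod("show", "ModelGridResult", function(object) {
  d <- if (is.na(object@depth)) "full" else format(object@depth)
  cat(sprintf(
    "ModelGridResult [depth %s]: %d models, median kappa %.3f (%s), mean OOB error %.3f\n",
    d, nrow(object@records), medianKappa(object),
    kappaBand(medianKappa(object)), meanOobError(object)))
})

#' @rdname DepthDecision-class
#' @param object an object.
#' @export
setMethod("show", "DepthDecision", function(object) {
  cat("DepthDecision\n")
  cat(sprintf("  benchmark: %s (kappa %.3f, accuracy %.1f%%)\n",
              object@benchmarkBand, object@benchmarkKappa,
              100 * object@benchmarkAccuracy))
  cat("  minimum depth meeting benchmark:",
      if (object@reached) format(object@minDepth) else "not reached", "\n")
})

#' @rdname SeparabilityReport-class
#' @param object an object.
#' @export
setMethod("show", "SeparabilityReport", function(object) {
  ov <- object@ellipseOverlap
  off <- ov[upper.tri(ov)]
  cat("SeparabilityReport\n")
  cat(sprintf("  class-frequency Gini: %.4f\n", object@gini))
  cat(sprintf("  feature CV: median %.3f over %d features (%d excluded)\n",
              median(object@cv), length(object@cv),
              object@nExcludedFeatures))
  cat(sprintf("  ASVs shared by all classes: %.1f%% (reads: %.1f%%)\n",
              100 * object@sharedAsv$shared_all,
              100 * object@sharedReads$shared_all))
  cat(sprintf("  NMDS stress %.3f; mean pairwise ellipse overlap %.3f\n",
              object@stress, mean(off)))
})
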