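#' Configure an end-to-end depth-benchmarking run
#'
#' Collects every knob of [runPipeline()] into one validated object. A
#' master seed is mandatory: every stochastic stage (rarefaction, model
#' fits, ordination) derives its own sub-stream from it, so a run is a
#' pure function of (inputs, config, seed) — never of the wall clock.
#'
#' @param counts_path,metadata_path input files (see [readAsvTable()]);
#'   leave `NULL` when passing a ready-made table to [runPipeline()].
#' @param label_column metadata column carrying the class label.
#' @param min_total_reads ASV filter threshold (default 50).
#' @param min_sample_depth sample filter threshold (default 15,000).
#' @param ladder_cap cap on the first ladder level (default 15,000).
#' @param n_trees,offsets,n_runs RF grid settings.
#' @param gate decision gate, see [minDepthForTarget()].
#' @param diagnostics run [separabilityReport()] as part of the pipeline.
#' @param seed master seed (mandatory).
#' @param out_dir output directory for the report bundle.
#' @return a `pipelineConfig` list.
#' @export
pipelineConfig <- function(counts_path = NULL, metadata_path = NULL,
                           label_column = "label",
                           min_total_reads = 50, min_sample_depth = 15000,
                           ladder_cap = 15000, n_trees = 6000,
                           offsets = -3:3, n_runs = 3,
                           gate = c("median", "best"), diagnostics = TRUE,
                           seed, out_dir) {
  gate <- match.arg(gate)
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  if (missing(out_dir)) stop("'out_dir' is mandatory", call. = FALSE)
  .assertCount(min_total_reads, "min_total_reads")
  .assertCount(min_sample_depth, "min_sample_depth", positive = TRUE)
  .assertCount(ladder_cap, "ladder_cap", positive = TRUE)
  .assertCount(n_trees, "n_trees", positive = TRUE)
  structure(list(counts_path = counts_path, metadata_path = metadata_path,
                 label_column = label_column,
                 min_total_reads = as.integer(min_total_reads),
                 min_sample_depth = as.integer(min_sample_depth),
                 ladder_cap = as.integer(ladder_cap),
                 n_trees = as.integer(n_trees),
                 offsets = as.integer(offsets),
                 n_runs = as.integer(n_runs), gate = gate,
                 diagnostics = isTRUE(diagnostics),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipelineConfig")
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the complete benchmarking pipeline and write a report bundle
#'
#' Stages: read (or accept) the ASV table, apply the ASV and sample depth
#' filters, build the ladder, run the full-model and per-level grid sweeps,
#' extract the depth decision, and (optionally) compute the separability
#' diagnostics. Writes to `config$out_dir`: `level_records.tsv` (every grid
#' model at every level), `level_summary.tsv`, `depth_decision.json`,
#' `coverage.tsv`, `separability.json` (when enabled) and `manifest.json`
#' recording the configuration, seed, package version and an MD5 checksum
#' of every output. Any stage failure aborts with the stage name and a
#' partial manifest. Rerunning with the same inputs, config and seed
#' reproduces byte-identical outputs.
#'
#' @param config a [pipelineConfig()].
#' @param table optionally a ready-made [AsvExperiment] (bypasses file
#'   input).
#' @return invisibly, a list with `table`, `sweep`, `decision`,
#'   `separability` and `files`.
#' @export
runPipeline <- function(config, table = NULL) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  manifest <- list(
    package = "ampliDepth",
    version = as.character(packageVersion("ampliDepth")),
    seed = config$seed,
    config = config[setdiff(names(config), c("counts_path",
                                             "metadata_path"))],
    inputs = list(counts = config$counts_path,
                  metadata = config$metadata_path))
  stage <- "input"
  tryCatch({
    if (is.null(table)) {
      table <- readAsvTable(config$counts_path, config$metadata_path,
                            label_column = config$label_column)
    }
    stage <- "preprocess"
    table <- filterLowAbundanceAsvs(table, config$min_total_reads)
    table <- filterShallowSamples(table, config$min_sample_depth)

    stage <- "ladder"
    ladder <- buildLadder(table, cap = config$ladder_cap)

    stage <- "coverage"
    cov <- coverageTrajectory(table, ladderLevels(ladder),
                              seed = .subSeed(config$seed, 4L))
    files["coverage"] <- .writeTsv(cov, file.path(config$out_dir,
                                                  "coverage.tsv"))

    stage <- "sweep"
    sw <- depthSweep(table, ladder = ladder, n_trees = config$n_trees,
                     offsets = config$offsets, n_runs = config$n_runs,
                     seed = config$seed, gate = config$gate)
    all_rec <- do.call(rbind, c(
      list(cbind(depth = "full", gridRecords(sw$full))),
      lapply(sw$levels, function(r)
        cbind(depth = format(r@depth), gridRecords(r)))))
    files["level_records"] <-
      .writeTsv(all_rec, file.path(config$out_dir, "level_records.tsv"))
    files["level_summary"] <-
      .writeTsv(levelSummary(sw$decision),
                file.path(config$out_dir, "level_summary.tsv"))
    dec <- sw$decision
    dec_json <- list(
      benchmark_band = dec@benchmarkBand,
      benchmark_kappa = dec@benchmarkKappa,
      benchmark_accuracy = dec@benchmarkAccuracy,
      min_depth = if (dec@reached) dec@minDepth else "not reached",
      ladder = ladderLevels(ladder))
    files["depth_decision"] <- file.path(config$out_dir,
                                         "depth_decision.json")
    jsonlite::write_json(dec_json, files["depth_decision"],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    sep <- NULL
    if (config$diagnostics) {
      stage <- "diagnostics"
      sep <- separabilityReport(table, seed = .subSeed(config$seed, 5L))
      ov <- ellipseOverlap(sep)
      sep_json <- list(
        gini = sep@gini,
        cv_median = median(featureCvValues(sep)),
        cv_quantiles = as.list(quantile(featureCvValues(sep),
                                        c(0.25, 0.5, 0.75, 0.9))),
        n_cv_excluded = sep@nExcludedFeatures,
        shared_asv = sep@sharedAsv,
        shared_reads = sep@sharedReads,
        nmds_stress = sep@stress,
        mean_ellipse_overlap = mean(ov[upper.tri(ov)]),
        ellipse_overlap = as.data.frame(ov))
      files["separability"] <- file.path(config$out_dir,
                                         "separability.json")
      jsonlite::write_json(sep_json, files["separability"],
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }

    stage <- "manifest"
    manifest$outputs <- lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f))))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(table = table, sweep = sw, decision = sw$decision,
                   separability = sep, files = files))
  }, error = function(e) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    manifest$outputs <- lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f))))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
}
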