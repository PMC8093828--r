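#' Read an ASV count table and sample metadata from disk
#'
#' The TSV layout is the common amplicon export: ASVs as rows, a first
#' column of ASV ids, a header row of sample ids (`transpose = TRUE` for
#' sample-row files). Metadata is a TSV with a `sample_id` column and a
#' label column. Counts are validated strictly: duplicated ids, negative
#' or non-integer values are rejected with the offending row and column
#' named, and every sample in the count table must appear in the metadata.
#' BIOM (JSON) input is supported when the `biomformat` package is
#' available.
#'
#' @param counts_path path to the count table (TSV, or BIOM with
#'   `format = "biom"`).
#' @param metadata_path path to the sample metadata TSV.
#' @param label_column metadata column carrying the class label.
#' @param format `"tsv"` or `"biom"`.
#' @param transpose set `TRUE` if the TSV has samples as rows.
#' @return a validated [AsvExperiment].
#' @export
readAsvTable <- function(counts_path, metadata_path,
                         label_column = "label", format = c("tsv", "biom"),
                         transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(counts_path))
    stop("count table not found: ", counts_path, call. = FALSE)
  if (!file.exists(metadata_path))
    stop("metadata not found: ", metadata_path, call. = FALSE)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("BIOM input requires the 'biomformat' package", call. = FALSE)
    b <- biomformat::read_biom(counts_path)
    m <- as.matrix(biomformat::biom_data(b))
  } else {
    df <- read.delim(counts_path, check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (ncol(df) < 2)
      stop("malformed count table: need an id column plus >= 1 sample",
           call. = FALSE)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- ids
  }
  if (transpose) m <- t(m)
  if (anyDuplicated(rownames(m)))
    stop("duplicated ASV ids: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(m)))
    stop("duplicated sample ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]),
               collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(m) | m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf(
      "invalid count at ASV '%s', sample '%s' (value %s): counts must be non-negative integers",
      rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
      format(m[bad[1, , drop = FALSE]])), call. = FALSE)
  meta <- read.delim(metadata_path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta))
    stop("metadata must contain a 'sample_id' column", call. = FALSE)
  if (!label_column %in% names(meta))
    stop("metadata has no column '", label_column, "'", call. = FALSE)
  missing <- setdiff(colnames(m), meta$sample_id)
  if (length(missing))
    stop("samples absent from metadata: ",
         paste(missing, collapse = ", "), call. = FALSE)
  labels <- meta[[label_column]][match(colnames(m), meta$sample_id)]
  AsvExperiment(m, labels = labels)
}

#' Write an ASV table and its metadata as TSV
#'
#' The inverse of [readAsvTable()]: `counts_path` gets the ASV-row matrix
#' with an `asv_id` first column, `metadata_path` gets `sample_id` and
#' `label` columns. A write-then-read round trip reproduces the table
#' exactly.
#'
#' @param x an [AsvExperiment].
#' @param counts_path,metadata_path output paths.
#' @return invisibly, the two paths.
#' @export
writeAsvTable <- function(x, counts_path, metadata_path) {
  stopifnot(is(x, "AsvExperiment"))
  m <- asvCounts(x)
  df <- data.frame(asv_id = rownames(m), m, check.names = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  meta <- data.frame(sample_id = colnames(m),
                     label = as.character(classLabels(x)))
  write.table(meta, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(counts_path, metadata_path))
}
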