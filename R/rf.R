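#' Cohen's kappa for two categorical labelings
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)`, with `p_o`
#' the observed agreement fraction and `p_e` the chance agreement from the
#' product of the marginal class frequencies. Returns exactly 1 on perfect
#' agreement and is invariant under any bijective relabeling applied to
#' both vectors. When both vectors are constant and identical (`p_e = 1`)
#' the value is defined as 1 by convention and a warning is raised.
#'
#' @param y_true,y_pred equal-length vectors of class labels.
#' @return Cohen's kappa (a single number <= 1).
#' @examples
#' cohenKappa(rep(c("a", "b"), 3), rep(c("a", "b"), 3))  # 1
#' @export
cohenKappa <- function(y_true, y_pred) {
  if (!length(y_true)) stop("empty label vectors", call. = FALSE)
  if (length(y_true) != length(y_pred))
    stop("label vectors differ in length", call. = FALSE)
  lev <- union(as.character(y_true), as.character(y_pred))
  t_ <- factor(as.character(y_true), levels = lev)
  p_ <- factor(as.character(y_pred), levels = lev)
  if (all(t_ == p_)) {
    if (length(lev) == 1L)
      warning("both labelings are constant and equal; kappa set to 1 ",
              "by convention", call. = FALSE)
    return(1)
  }
  n <- length(t_)
  cm <- table(t_, p_)
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  (p_o - p_e) / (1 - p_e)
}

.BAND_LEVELS <- c("poor", "moderate", "almost_perfect")

#' Agreement band of a kappa value
#'
#' Kappa above 0.8 indicates almost perfect agreement, below 0.6 poor
#' agreement, and the closed interval `[0.6, 0.8]` moderate agreement
#' (both boundaries are moderate, per the strict `> 0.8` and `< 0.6`
#' rules).
#'
#' @param kappa a finite kappa value.
#' @return ordered factor with levels `poor < moderate < almost_perfect`.
#' @export
kappaBand <- function(kappa) {
  if (any(!is.finite(kappa))) stop("kappa must be finite", call. = FALSE)
  band <- ifelse(kappa > 0.8, "almost_perfect",
                 ifelse(kappa < 0.6, "poor", "moderate"))
  factor(band, levels = .BAND_LEVELS, ordered = TRUE)
}

#' Default mtry for classification
#'
#' The square root of the feature count, rounded down (minimum 1) — the
#' recommended default number of candidate features per split.
#'
#' @param n_features number of features (>= 1).
#' @return an integer.
#' @export
defaultMtry <- function(n_features) {
  .assertCount(n_features, "n_features", positive = TRUE)
  max(1L, as.integer(floor(sqrt(n_features))))
}

#' Build the RF model grid for one depth level
#'
#' Seven mtry values — the default plus offsets of plus/minus one, two and
#' three — each run three times with distinct seeds (the original run plus
#' two repeats with different base trees), giving 21 configurations under
#' the defaults. Offsets are clipped to `[1, n_features]`; values that
#' collide after clipping are deduplicated with a warning.
#'
#' @param n_features number of features.
#' @param offsets integer offsets around the default mtry.
#' @param n_runs repeat runs per mtry value.
#' @param base_seed seed from which the per-run seeds are derived.
#' @return data.frame with columns `mtry`, `run`, `seed`; one row per
#'   configuration.
#' @export
buildModelGrid <- function(n_features, offsets = -3:3, n_runs = 3,
                           base_seed = 1) {
  .assertCount(n_features, "n_features", positive = TRUE)
  .assertCount(n_runs, "n_runs", positive = TRUE)
  m0 <- defaultMtry(n_features)
  mtry <- pmin(pmax(m0 + as.integer(offsets), 1L), as.integer(n_features))
  if (anyDuplicated(mtry)) {
    warning("mtry offsets collide after clipping to [1, ", n_features,
            "]; grid reduced to ", length(unique(mtry)), " mtry values",
            call. = FALSE)
    mtry <- unique(mtry)
  }
  mtry <- sort(mtry)
  grid <- expand.grid(mtry = mtry, run = seq_len(n_runs),
                      KEEP.OUT.ATTRS = FALSE)
  grid$seed <- vapply(seq_len(nrow(grid)), function(i)
    .subSeed(base_seed, 3L, grid$run[i], grid$mtry[i]), integer(1))
  grid[order(grid$mtry, grid$run), , drop = FALSE]
}

#' Train one random forest and score it out-of-bag
#'
#' Fits a classification random forest (`config$n_trees` trees, `config$mtry`
#' candidate features per split) on relative abundances and scores it on
#' out-of-bag predictions: each sample is predicted only by trees whose
#' bootstrap did not contain it, so the OOB error is a built-in
#' cross-validation estimate. Kappa is computed from the OOB confusion
#' matrix. Samples with no OOB tree (possible at very small tree counts)
#' are excluded with a warning.
#'
#' @param rel a [RelAbundanceExperiment] (features x samples).
#' @param mtry candidate features per split.
#' @param n_trees number of trees (study default 6,000).
#' @param seed seed making the fit reproducible.
#' @return list with `oob_predictions`, `oob_error`, `accuracy`, `kappa`,
#'   `n_scored`.
#' @export
trainRfOob <- function(rel, mtry, n_trees = 6000, seed = 1) {
  stopifnot(is(rel, "RelAbundanceExperiment"))
  y <- classLabels(rel)
  if (nlevels(y) < 2)
    stop("classification needs at least two classes", call. = FALSE)
  if (any(tabulate(y) < 2))
    stop("every class needs at least two samples", call. = FALSE)
  X <- t(relAbundance(rel))
  if (any(!is.finite(X))) stop("non-finite feature values", call. = FALSE)
  mtry <- min(max(1L, as.integer(mtry)), ncol(X))
  fit <- .withSeed(seed, {
    randomForest::randomForest(x = X, y = y, ntree = as.integer(n_trees),
                               mtry = mtry)
  })
  pred <- fit$predicted
  scored <- !is.na(pred)
  if (!all(scored))
    warning(sum(!scored), " sample(s) had no out-of-bag tree and were ",
            "excluded from scoring", call. = FALSE)
  oob_error <- mean(pred[scored] != y[scored])
  list(oob_predictions = pred,
       oob_error = oob_error,
       accuracy = 1 - oob_error,
       kappa = cohenKappa(y[scored], pred[scored]),
       n_scored = sum(scored))
}

#' Evaluate the full model grid at one depth level
#'
#' Transforms the level's count table to relative abundances, trains every
#' grid configuration with [trainRfOob()], and collects the per-model
#' records. The level is summarized by the median kappa and mean OOB error
#' across the grid; the best model (max kappa, ties broken by lower OOB
#' error then lower mtry) is available via [bestModel()].
#'
#' @param x the [AsvExperiment] at this depth (rarefied or full).
#' @param grid a grid from [buildModelGrid()].
#' @param n_trees trees per model.
#' @param depth depth label for the result; `NA` for the full model.
#' @return a [ModelGridResult].
#' @export
evaluateLevel <- function(x, grid, n_trees = 6000, depth = NA_real_) {
  stopifnot(is(x, "AsvExperiment"), is.data.frame(grid))
  rel <- toRelativeAbundance(x)
  rec <- lapply(seq_len(nrow(grid)), function(i) {
    r <- trainRfOob(rel, mtry = grid$mtry[i], n_trees = n_trees,
                    seed = grid$seed[i])
    data.frame(mtry = grid$mtry[i], run = grid$run[i], seed = grid$seed[i],
               oob_error = r$oob_error, accuracy = r$accuracy,
               kappa = r$kappa)
  })
  new("ModelGridResult", depth = as.numeric(depth),
      records = do.call(rbind, rec))
}

#' Extract the minimum depth meeting the full-model benchmark
#'
#' The full model's summary kappa band is the benchmark ("targeted
#' prediction performance"). Walking the ladder from deepest to
#' shallowest, the minimum depth is the smallest level such that every
#' level at or above it has a band at least as good as the benchmark
#' (contiguity: one failing level breaks the run). If even the deepest
#' level fails, the benchmark is `"not reached"`. Bands are taken from the
#' median grid kappa by default, or from the best model's kappa with
#' `gate = "best"`.
#'
#' @param full_result [ModelGridResult] of the full-depth model.
#' @param ladder_results list of [ModelGridResult], ordered by strictly
#'   decreasing depth.
#' @param gate `"median"` (default) or `"best"`: which level statistic is
#'   banded.
#' @return a [DepthDecision].
#' @export
minDepthForTarget <- function(full_result, ladder_results,
                              gate = c("median", "best")) {
  gate <- match.arg(gate)
  stopifnot(is(full_result, "ModelGridResult"))
  if (!length(ladder_results)) stop("empty ladder", call. = FALSE)
  depths <- vapply(ladder_results, function(r) r@depth, numeric(1))
  if (any(diff(depths) >= 0))
    stop("'ladder_results' must be ordered by strictly decreasing depth",
         call. = FALSE)
  stat <- function(r) {
    if (gate == "median") medianKappa(r) else bestModel(r)$kappa
  }
  bench_kappa <- stat(full_result)
  bench_band <- kappaBand(bench_kappa)
  level_kappa <- vapply(ladder_results, stat, numeric(1))
  bands <- kappaBand(level_kappa)
  pass <- bands >= bench_band
  ## longest contiguous passing run starting at the deepest level
  n_pass <- if (pass[1]) which.max(c(!pass, TRUE)) - 1L else 0L
  reached <- n_pass > 0L
  summary <- data.frame(
    depth = depths,
    median_kappa = vapply(ladder_results, medianKappa, numeric(1)),
    mean_oob_error = vapply(ladder_results, meanOobError, numeric(1)),
    best_kappa = vapply(ladder_results, function(r) bestModel(r)$kappa,
                        numeric(1)),
    band = as.character(bands),
    pass = pass)
  new("DepthDecision",
      benchmarkBand = as.character(bench_band),
      benchmarkKappa = bench_kappa,
      benchmarkAccuracy = 1 - meanOobError(full_result),
      minDepth = if (reached) depths[n_pass] else NA_real_,
      reached = reached,
      levelSummary = summary)
}

#' Run the full depth sweep on a table
#'
#' The end-to-end core procedure: evaluate the model grid on the
#' full-depth table, rarefy the table to each ladder level (one rarefied
#' table per level, shared by all grid models; set
#' `rarefy_per_model = TRUE` to re-rarefy for every model for variance
#' studies), evaluate the grid at every level, and extract the minimum
#' depth meeting the full-model benchmark.
#'
#' @param x a preprocessed [AsvExperiment].
#' @param ladder a [DepthLadder]; built with [buildLadder()] when `NULL`.
#' @param n_trees trees per model (study default 6,000; pilot analyses
#'   stabilize far below that).
#' @param offsets,n_runs grid shape, see [buildModelGrid()].
#' @param seed master seed driving rarefaction and all model fits.
#' @param gate level statistic gating the decision, see
#'   [minDepthForTarget()].
#' @param rarefy_per_model re-draw the rarefied table for every grid model
#'   (default `FALSE`: one table per level).
#' @return list with elements `decision` ([DepthDecision]), `full`
#'   ([ModelGridResult]) and `levels` (list of [ModelGridResult]).
#' @export
depthSweep <- function(x, ladder = NULL, n_trees = 6000, offsets = -3:3,
                       n_runs = 3, seed = 1, gate = c("median", "best"),
                       rarefy_per_model = FALSE) {
  gate <- match.arg(gate)
  stopifnot(is(x, "AsvExperiment"))
  if (is.null(ladder)) ladder <- buildLadder(x)
  stopifnot(is(ladder, "DepthLadder"))
  grid <- buildModelGrid(nrow(x), offsets = offsets, n_runs = n_runs,
                         base_seed = .subSeed(seed, 1L))
  full <- evaluateLevel(x, grid, n_trees = n_trees, depth = NA_real_)
  levels_res <- lapply(seq_along(ladder@levels), function(li) {
    d <- ladder@levels[li]
    if (rarefy_per_model) {
      rec <- lapply(seq_len(nrow(grid)), function(i) {
        tab <- rarefyTable(x, d, seed = .subSeed(seed, 2L, li, i))
        r <- evaluateLevel(tab, grid[i, , drop = FALSE], n_trees = n_trees,
                           depth = d)
        r@records
      })
      new("ModelGridResult", depth = as.numeric(d),
          records = do.call(rbind, rec))
    } else {
      tab <- rarefyTable(x, d, seed = .subSeed(seed, 2L, li))
      evaluateLevel(tab, grid, n_trees = n_trees, depth = d)
    }
  })
  decision <- minDepthForTarget(full, levels_res, gate = gate)
  list(decision = decision, full = full, levels = levels_res,
       ladder = ladder, grid = grid)
}
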