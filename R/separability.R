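#' Gini coefficient of the class-frequency distribution
#'
#' Measures class imbalance of a classification task:
#' `G = sum_ij |x_i - x_j| / (2 n sum(x))` over all ordered class pairs
#' (the standard mean-absolute-difference form).
#' Zero for perfectly balanced classes, approaching 1 as one class
#' dominates. Invariant under permuting the classes and under scaling all
#' counts by a constant. Not to be confused with the Gini impurity used
#' inside tree learners.
#'
#' @param class_counts positive integer sample counts, one per class
#'   (>= 2 classes).
#' @return Gini coefficient in `[0, 1)`.
#' @examples
#' classGini(c(25, 24, 27))  # 12/456
#' @export
classGini <- function(class_counts) {
  if (length(class_counts) < 2)
    stop("need at least two classes", call. = FALSE)
  if (any(class_counts <= 0))
    stop("all class counts must be positive", call. = FALSE)
  n <- length(class_counts)
  sum(abs(outer(class_counts, class_counts, "-"))) /
    (2 * n * sum(class_counts))
}

#' Per-feature coefficient of variation across class means
#'
#' For each feature, the mean relative abundance is computed within each
#' class; the CV is the sample standard deviation of those class means
#' divided by their grand mean. High-CV features are unevenly distributed
#' across classes and therefore class-discriminating; a dataset rich in
#' high-CV features can be classified from few reads. Features whose class
#' means are all zero have an undefined CV and are excluded (their number
#' is reported).
#'
#' @param rel a [RelAbundanceExperiment] with >= 2 classes.
#' @return list with `cv` (named numeric, defined features only) and
#'   `n_excluded`.
#' @export
featureCv <- function(rel) {
  stopifnot(is(rel, "RelAbundanceExperiment"))
  y <- classLabels(rel)
  if (nlevels(y) < 2) stop("need at least two classes", call. = FALSE)
  m <- relAbundance(rel)
  class_means <- vapply(levels(y), function(cl)
    rowMeans(m[, y == cl, drop = FALSE]), numeric(nrow(m)))
  grand <- rowMeans(class_means)
  defined <- grand > 0
  cv <- apply(class_means[defined, , drop = FALSE], 1L, sd) /
    grand[defined]
  list(cv = cv, n_excluded = sum(!defined))
}

#' Shared and class-exclusive feature fractions
#'
#' An ASV is "present" in a class when its pooled read count over that
#' class's samples reaches `presence_min_count`. Reported are the fraction
#' of features present in every class and, per class, the fraction present
#' exclusively in it — under two weightings: `asv` counts each ASV once,
#' `reads` weights each ASV by its total read count (the two resolve the
#' ambiguity between "fraction of ASVs" and "fraction of sequences").
#' Shared, exclusive and partially-shared fractions sum to 1.
#'
#' @param x an [AsvExperiment] with >= 2 classes.
#' @param presence_min_count pooled-count threshold for presence.
#' @param weighting `"asv"` or `"reads"`.
#' @return list with `shared_all`, `exclusive` (named per class) and
#'   `partial` (present in more than one but not all classes).
#' @export
sharedFeatureFractions <- function(x, presence_min_count = 1,
                                   weighting = c("asv", "reads")) {
  weighting <- match.arg(weighting)
  stopifnot(is(x, "AsvExperiment"))
  .assertCount(presence_min_count, "presence_min_count", positive = TRUE)
  y <- classLabels(x)
  if (nlevels(y) < 2) stop("need at least two classes", call. = FALSE)
  m <- asvCounts(x)
  pooled <- vapply(levels(y), function(cl)
    rowSums(m[, y == cl, drop = FALSE]), numeric(nrow(m)))
  present <- pooled >= presence_min_count
  n_classes_present <- rowSums(present)
  w <- if (weighting == "asv") rep(1, nrow(m)) else rowSums(m)
  w_obs <- sum(w[n_classes_present > 0])
  if (w_obs == 0) stop("no feature is present in any class", call. = FALSE)
  frac <- function(sel) sum(w[sel]) / w_obs
  exclusive <- vapply(seq_len(nlevels(y)), function(k)
    frac(n_classes_present == 1 & present[, k]), numeric(1))
  names(exclusive) <- levels(y)
  list(shared_all = frac(n_classes_present == nlevels(y)),
       exclusive = exclusive,
       partial = frac(n_classes_present > 1 &
                        n_classes_present < nlevels(y)))
}

## Confidence ellipse of one class in 2-D ordination space: normal-theory
## ellipse from the class mean and covariance with chi-square(2) radius.
## A degenerate (near-singular) covariance is inflated by a small ridge so
## collinear classes still yield a well-defined ellipse; the inflation is
## flagged on the result.
.classEllipse <- function(xy, confidence, eps = 1e-8) {
  mu <- colMeans(xy)
  S <- cov(xy)
  inflated <- FALSE
  if (!all(is.finite(S)) || det(S) < eps) {
    S <- S + diag(eps^0.5, 2)
    inflated <- TRUE
  }
  list(mu = mu, S = S, r2 = qchisq(confidence, df = 2),
       inflated = inflated)
}

## Fraction of ellipse A's area inside ellipse B, by Monte-Carlo sampling
## of points uniformly inside A (unit-disk transform through chol(S)).
.ellipseOverlapMC <- function(ea, eb, n_points, seed) {
  .withSeed(seed, {
    u <- sqrt(runif(n_points))
    th <- runif(n_points, 0, 2 * pi)
    disk <- cbind(u * cos(th), u * sin(th)) * sqrt(ea$r2)
    pts <- sweep(disk %*% chol(ea$S), 2L, ea$mu, "+")
    d <- sweep(pts, 2L, eb$mu, "-")
    maha <- rowSums((d %*% solve(eb$S)) * d)
    mean(maha <= eb$r2)
  })
}

#' NMDS ordination with per-class confidence-ellipse overlap
#'
#' Computes Bray-Curtis dissimilarities on relative abundances, a 2-D
#' non-metric MDS (multiple seeded random restarts, best-stress solution
#' kept), a normal-theory confidence ellipse per class from the 2-D class
#' mean and covariance, and the pairwise ellipse overlap fraction
#' estimated by seeded Monte-Carlo point sampling, symmetrized by
#' averaging the two directions. Low overlap means well-separated class
#' clusters — the visual signature of a task classifiable from few reads.
#'
#' @param rel a [RelAbundanceExperiment] with >= 3 samples per class.
#' @param confidence ellipse confidence level (default 0.95).
#' @param seed seed for the NMDS restarts and the Monte-Carlo overlap.
#' @param n_points Monte-Carlo points per directed pair.
#' @param trymax NMDS random restarts.
#' @return list with `ordination` (data.frame: sample, class, NMDS1,
#'   NMDS2), `stress`, `overlap` (symmetric matrix, unit diagonal) and
#'   `inflated` (classes whose ellipse needed a degeneracy ridge).
#' @export
ordinationOverlap <- function(rel, confidence = 0.95, seed = 1,
                              n_points = 2000, trymax = 20) {
  stopifnot(is(rel, "RelAbundanceExperiment"))
  y <- classLabels(rel)
  if (any(tabulate(y) < 3))
    stop("every class needs at least 3 samples for an ellipse",
         call. = FALSE)
  d <- vegan::vegdist(t(relAbundance(rel)), method = "bray")
  mds <- .withSeed(.subSeed(seed, 11L), {
    vegan::metaMDS(d, k = 2, trymax = trymax, trace = 0)
  })
  xy <- vegan::scores(mds, display = "sites")
  ords <- data.frame(sample = rownames(xy), class = as.character(y),
                     NMDS1 = xy[, 1], NMDS2 = xy[, 2],
                     row.names = NULL)
  ell <- lapply(levels(y), function(cl)
    .classEllipse(xy[y == cl, , drop = FALSE], confidence))
  names(ell) <- levels(y)
  k <- nlevels(y)
  ov <- diag(1, k)
  dimnames(ov) <- list(levels(y), levels(y))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    ab <- .ellipseOverlapMC(ell[[i]], ell[[j]], n_points,
                            .subSeed(seed, 12L, i, j))
    ba <- .ellipseOverlapMC(ell[[j]], ell[[i]], n_points,
                            .subSeed(seed, 12L, j, i))
    ov[i, j] <- ov[j, i] <- (ab + ba) / 2
  }
  list(ordination = ords, stress = mds$stress, overlap = ov,
       inflated = names(ell)[vapply(ell, `[[`, logical(1), "inflated")])
}

#' Assemble the full separability report for a table
#'
#' Bundles the class-imbalance Gini, the per-feature CV distribution, the
#' shared/exclusive feature fractions (both weightings) and the ordination
#' ellipse overlap into one [SeparabilityReport].
#'
#' @param x a preprocessed [AsvExperiment].
#' @param confidence ellipse confidence level.
#' @param seed seed for the stochastic ordination components.
#' @param presence_min_count presence threshold, see
#'   [sharedFeatureFractions()].
#' @return a [SeparabilityReport].
#' @export
separabilityReport <- function(x, confidence = 0.95, seed = 1,
                               presence_min_count = 1) {
  stopifnot(is(x, "AsvExperiment"))
  rel <- toRelativeAbundance(x)
  cvr <- featureCv(rel)
  ordr <- ordinationOverlap(rel, confidence = confidence, seed = seed)
  new("SeparabilityReport",
      gini = classGini(as.integer(tabulate(classLabels(x)))),
      cv = cvr$cv,
      nExcludedFeatures = as.integer(cvr$n_excluded),
      sharedAsv = sharedFeatureFractions(x, presence_min_count, "asv"),
      sharedReads = sharedFeatureFractions(x, presence_min_count, "reads"),
      ordination = ordr$ordination,
      stress = ordr$stress,
      ellipseOverlap = ordr$overlap,
      confidence = confidence)
}
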