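#' Specify a synthetic multi-class ASV community
#'
#' Defines the generative conditions for [generateDataset()]: a
#' Dirichlet-multinomial community with a shared log-normal expected
#' abundance profile, a configurable number of class-specific ASVs whose
#' expected relative abundance is multiplied by `effect_size` in their home
#' class, and uniform per-sample read depths. `effect_size = 1` collapses
#' the class signal entirely (the null community).
#'
#' @param n_classes number of classes (>= 2).
#' @param samples_per_class integer vector, one entry per class (each >= 3).
#' @param n_background_asvs ASVs shared by all classes.
#' @param n_specific_asvs_per_class ASVs elevated in exactly one class.
#' @param effect_size multiplicative enrichment (> 0) of a specific ASV's
#'   expected relative abundance in its home class.
#' @param base_abundance_logmean,base_abundance_logsd log-normal parameters
#'   of the expected abundance profile.
#' @param overdispersion Dirichlet concentration scaler (> 0); smaller
#'   values give noisier compositions.
#' @param depth_range length-2 integer vector `(min_depth, max_depth)` for
#'   uniform per-sample read totals.
#' @param seed master seed; the full table is reproducible from it.
#' @return a `syntheticSpec` list, validated.
#' @seealso [hardBoundarySpec()], [softBoundarySpec()]
#' @export
syntheticSpec <- function(n_classes = 3,
                          samples_per_class = c(25, 24, 27),
                          n_background_asvs = 2800,
                          n_specific_asvs_per_class = 80,
                          effect_size = 5,
                          base_abundance_logmean = 0,
                          base_abundance_logsd = 1.5,
                          overdispersion = 200,
                          depth_range = c(15000, 40000),
                          seed = 1) {
  .assertCount(n_classes, "n_classes", positive = TRUE)
  if (n_classes < 2) stop("'n_classes' must be >= 2", call. = FALSE)
  if (length(samples_per_class) != n_classes)
    stop("'samples_per_class' must have one entry per class", call. = FALSE)
  if (any(samples_per_class < 3) ||
      any(samples_per_class != floor(samples_per_class)))
    stop("'samples_per_class' entries must be integers >= 3", call. = FALSE)
  .assertCount(n_background_asvs, "n_background_asvs")
  .assertCount(n_specific_asvs_per_class, "n_specific_asvs_per_class")
  if (n_background_asvs + n_specific_asvs_per_class == 0)
    stop("community must contain at least one ASV", call. = FALSE)
  if (!is.numeric(effect_size) || effect_size <= 0)
    stop("'effect_size' must be > 0", call. = FALSE)
  if (!is.numeric(overdispersion) || overdispersion <= 0)
    stop("'overdispersion' must be > 0", call. = FALSE)
  if (length(depth_range) != 2 || any(depth_range <= 0) ||
      depth_range[1] > depth_range[2] ||
      any(depth_range != floor(depth_range)))
    stop("'depth_range' must be positive integers (min <= max)",
         call. = FALSE)
  structure(list(n_classes = as.integer(n_classes),
                 samples_per_class = as.integer(samples_per_class),
                 n_background_asvs = as.integer(n_background_asvs),
                 n_specific_asvs_per_class =
                   as.integer(n_specific_asvs_per_class),
                 effect_size = effect_size,
                 base_abundance_logmean = base_abundance_logmean,
                 base_abundance_logsd = base_abundance_logsd,
                 overdispersion = overdispersion,
                 depth_range = as.integer(depth_range),
                 seed = as.integer(seed)),
            class = "syntheticSpec")
}

#' Pilot-scale presets with hard and soft class boundaries
#'
#' Two matched small communities used throughout the package's examples and
#' validation: the hard-boundary preset has many strongly enriched
#' class-specific ASVs (well-separated classes), the soft-boundary preset
#' few, weakly enriched ones (classes blending into each other). Both share
#' sample layout (3 classes x 12 samples) and depth range (2,000-4,000
#' reads), so differences in the minimum usable depth are attributable to
#' boundary hardness alone.
#'
#' @param seed master seed.
#' @return a `syntheticSpec`.
#' @export
hardBoundarySpec <- function(seed = 1) {
  syntheticSpec(n_classes = 3, samples_per_class = c(12, 12, 12),
                n_background_asvs = 150, n_specific_asvs_per_class = 40,
                effect_size = 10, overdispersion = 200,
                depth_range = c(2000, 4000), seed = seed)
}

#' @rdname hardBoundarySpec
#' @export
softBoundarySpec <- function(seed = 1) {
  syntheticSpec(n_classes = 3, samples_per_class = c(12, 12, 12),
                n_background_asvs = 240, n_specific_asvs_per_class = 10,
                effect_size = 3, overdispersion = 200,
                depth_range = c(2000, 4000), seed = seed)
}

#' Generate a synthetic ASV count table
#'
#' Draws each sample as a Dirichlet-multinomial realization: the expected
#' relative-abundance profile (log-normal across ASVs, drawn once per spec)
#' has each class-specific ASV multiplied by `effect_size` in its home
#' class before renormalization; the renormalized profile times
#' `overdispersion` gives the Dirichlet concentration, and the sample's
#' reads are a multinomial draw at its (uniform random) depth. The random
#' stream is keyed by `(seed, sample index)`, so adding samples does not
#' perturb earlier samples.
#'
#' @param spec a [syntheticSpec()].
#' @return an [AsvExperiment] with class labels `class_1 ... class_k` and
#'   the generating spec stored in `metadata()`.
#' @examples
#' tab <- generateDataset(hardBoundarySpec(seed = 42))
#' tab
#' @export
generateDataset <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  k <- spec$n_classes
  n_bg <- spec$n_background_asvs
  n_sp <- spec$n_specific_asvs_per_class
  n_asv <- n_bg + k * n_sp
  n_samples <- sum(spec$samples_per_class)

  ## expected-abundance profile shared by all classes (stream index 0)
  base_mu <- .withSeed(.subSeed(spec$seed, 0L), {
    rlnorm(n_asv, spec$base_abundance_logmean, spec$base_abundance_logsd)
  })
  ## ASV j (specific block c) is owned by class c
  owner <- c(rep(NA_integer_, n_bg), rep(seq_len(k), each = n_sp))

  labels <- rep(seq_len(k), times = spec$samples_per_class)
  counts <- matrix(0L, nrow = n_asv, ncol = n_samples)
  for (j in seq_len(n_samples)) {
    cl <- labels[j]
    mu <- base_mu
    if (n_sp > 0)
      mu[which(owner == cl)] <- mu[which(owner == cl)] * spec$effect_size
    p <- mu / sum(mu)
    counts[, j] <- .withSeed(.subSeed(spec$seed, j), {
      depth <- if (spec$depth_range[1] == spec$depth_range[2])
        spec$depth_range[1]
      else
        sample(spec$depth_range[1]:spec$depth_range[2], 1L)
      w <- rgamma(n_asv, shape = spec$overdispersion * p, rate = 1)
      if (sum(w) <= 0) w <- p  # all-zero gamma draw: fall back to the mean
      as.integer(rmultinom(1L, depth, w / sum(w)))
    })
  }
  rownames(counts) <- sprintf("ASV_%05d", seq_len(n_asv))
  colnames(counts) <- sprintf("S%03d", seq_len(n_samples))
  x <- AsvExperiment(counts, labels = paste0("class_", labels))
  metadata(x)$synthetic_spec <- spec
  metadata(x)$asv_owner_class <- owner
  x
}
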