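# Small fixtures built in code.

# Counts given as an ASVs x samples matrix; labels one per sample.
toyTable <- function(counts, labels,
                     asv_ids = sprintf("A%02d", seq_len(nrow(counts))),
                     sample_ids = sprintf("S%02d", seq_len(ncol(counts)))) {
  counts <- as.matrix(counts)
  rownames(counts) <- asv_ids
  colnames(counts) <- sample_ids
  AsvExperiment(counts, labels = labels)
}

# A tiny but learnable community for fast RF tests.
tinySpec <- function(seed = 1, effect_size = 10, n_specific = 15,
                     overdispersion = 200) {
  syntheticSpec(n_classes = 2, samples_per_class = c(8, 8),
                n_background_asvs = 60,
                n_specific_asvs_per_class = n_specific,
                effect_size = effect_size,
                overdispersion = overdispersion,
                depth_range = c(500, 1000), seed = seed)
}

# Independent oracle for without-replacement subsampling: expand the count
# vector into individual reads, take a uniform subset, tabulate.
bruteForceRarefy <- function(counts, depth) {
  reads <- rep(seq_along(counts), counts)
  tabulate(sample(reads, depth), nbins = length(counts))
}

# Build a ModelGridResult with prescribed kappa values (one pseudo-model
# per kappa) for decision-logic tests.
fakeGrid <- function(kappas, depth = NA_real_, oob = NULL) {
  if (is.null(oob)) oob <- pmax(0, 1 - (kappas + 1) / 2)
  new("ModelGridResult", depth = as.numeric(depth),
      records = data.frame(mtry = seq_along(kappas),
                           run = 1L, seed = seq_along(kappas),
                           oob_error = oob, accuracy = 1 - oob,
                           kappa = kappas))
}
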