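# Small deterministic fixtures shared across test files. All synthetic
# datasets are generated at a coarse axis spacing so the full pipeline
# stays fast; effect sizes are the generator defaults.

toy_block <- function(n = 3, wn = c(4000, 3800, 3600, 2000, 1000, 670),
                      seed = 1, block = "MIR") {
  set.seed(seed)
  spectra_block(wn, matrix(stats::rnorm(n * length(wn)), n),
                paste0("s", seq_len(n)), block)
}

# a block with realistic structure: Gaussian band + per-sample scatter
scatter_block <- function(n = 6, seed = 1) {
  set.seed(seed)
  wn <- seq(4000, 650, by = -10)
  base <- 0.5 * exp(-(wn - 1600)^2 / (2 * 120^2)) +
    0.3 * exp(-(wn - 2900)^2 / (2 * 60^2))
  x <- t(sapply(seq_len(n), function(i)
    stats::runif(1, 0.7, 1.3) * base + stats::runif(1, -0.1, 0.1) +
      stats::rnorm(length(wn), sd = 0.002)))
  spectra_block(wn, x, block = "MIR")
}

small_paperlike <- function(seed, ...) {
  generate(difficulty_presets("paperlike", nir_spacing = 30,
                              mir_spacing = 15, seed = seed, ...))
}

# averaged, pretreated, region-filtered blocks from a generated dataset
prep_blocks <- function(ds, window = 11) {
  nir <- average_replicates(ds$nir, ds$replicate_map)
  mir <- average_replicates(ds$mir, ds$replicate_map)
  list(NIR = pretreat(nir, window = window),
       MIR = exclude_regions(pretreat(mir, window = window),
                             default_excluded_regions()))
}
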