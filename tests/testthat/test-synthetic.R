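test_that("generation is bit-identical under a fixed seed", {
  spec <- synthetic_spec(nir_spacing = 60, mir_spacing = 30, seed = 7)
  d1 <- generate(spec)
  d2 <- generate(spec)
  expect_identical(d1$nir$intensities, d2$nir$intensities)
  expect_identical(d1$mir$intensities, d2$mir$intensities)
  expect_identical(d1$truth, d2$truth)
  d3 <- generate(synthetic_spec(nir_spacing = 60, mir_spacing = 30, seed = 8))
  expect_false(identical(d1$nir$intensities, d3$nir$intensities))
})

test_that("with all variability off, spectra within a class coincide", {
  spec <- synthetic_spec(class_sizes = c(3, 3), nir_spacing = 60,
                         mir_spacing = 30, beta_scale = 0, class_effect = 0,
                         sample_effect = 0, scatter_slope = 0,
                         scatter_offset = 0, noise_sd = 0, replicates = 2)
  ds <- generate(spec)
  x <- ds$nir$intensities
  expect_equal(max(abs(sweep(x, 2, x[1, ]))), 0)
})

test_that("an isolated Gaussian band integrates to amplitude * sigma * sqrt(2*pi)", {
  pk <- data.frame(block = c("NIR", "MIR"), position = c(7000, 2000),
                   sigma = c(100, 30), amplitude = c(0.8, 0.5))
  spec <- synthetic_spec(class_sizes = 2, nir_spacing = 4, mir_spacing = 2,
                         peaks = pk, beta_scale = 0, class_effect = 0,
                         sample_effect = 0, scatter_slope = 0,
                         scatter_offset = 0, noise_sd = 0, replicates = 1,
                         baseline = c(0, 0))
  ds <- generate(spec)
  h <- 4
  area <- sum(ds$nir$intensities[1, ]) * h
  expect_equal(area, 0.8 * 100 * sqrt(2 * pi), tolerance = 0.01)
  # narrow-peak limit: the nearest axis point carries the full amplitude
  expect_equal(max(ds$mir$intensities[1, ]), 0.5, tolerance = 1e-3)
})

test_that("peak positions outside their block's axis are rejected", {
  pk <- data.frame(block = "NIR", position = 3000, sigma = 50, amplitude = 1)
  expect_error(synthetic_spec(peaks = pk), "outside")
})

test_that("MSC halves between-replicate variance under scatter", {
  spec <- synthetic_spec(class_sizes = 4, nir_spacing = 60, mir_spacing = 30,
                         seed = 3)
  ds <- generate(spec)
  reps <- ds$nir$intensities[ds$replicate_map[[1]], ]
  b <- spectra_block(ds$nir$wavenumbers, reps, block = "NIR")
  v_raw <- mean(apply(reps, 2, var))
  v_msc <- mean(apply(msc(b)$intensities, 2, var))
  expect_lt(v_msc, 0.5 * v_raw)
})

test_that("difficulty presets bracket the classification difficulty", {
  # separable: calibration is perfectly fitted
  ds <- generate(difficulty_presets("separable", nir_spacing = 60,
                                    mir_spacing = 30, seed = 2))
  b <- prep_blocks(ds)$MIR
  m <- suppressWarnings(plsda(b$intensities, ds$metadata$class, max_lv = 15))
  expect_equal(mean(predict(m)$class == ds$metadata$class), 1)

  # chance: OOB error sits at the no-signal level for 13 imbalanced classes
  dsc <- generate(difficulty_presets("chance", nir_spacing = 60,
                                     mir_spacing = 30, seed = 4))
  bc <- prep_blocks(dsc)$NIR
  f <- fit_rf(bc$intensities, dsc$metadata$class, rf_config(300, seed = 4))
  p_share <- eul_regions()$n / sum(eul_regions()$n)
  chance_err <- 1 - sum(p_share^2)             # expected no-information error
  expect_gt(f$oob_error, chance_err - 0.12)
  expect_lte(f$oob_error, 1)
  expect_error(difficulty_presets("impossible"), "arg")
})

test_that("information splitting starves the excluded block", {
  acc_of <- function(frac, block, sd = 6) {
    spec <- split_block_information(
      difficulty_presets("paperlike", nir_spacing = 30, mir_spacing = 15,
                         seed = sd), frac)
    ds <- generate(spec)
    b <- prep_blocks(ds)[[block]]
    y <- ds$metadata$class
    sp <- suppressWarnings(split_two_to_one(b$intensities, y))
    x <- apply_scale(b$intensities,
                     fit_scale(b$intensities[sp$calibration, ]))
    m <- suppressWarnings(plsda(x[sp$calibration, ], y[sp$calibration],
                                max_lv = 10))
    mean(predict(m, x[sp$validation, ])$class == y[sp$validation])
  }
  chance <- max(eul_regions()$n) / sum(eul_regions()$n)
  expect_lt(acc_of(1, "MIR"), chance + 0.15)    # starved block ~ chance
  expect_gt(acc_of(1, "NIR"), 0.6)
  expect_gt(acc_of(0.5, "NIR"), 0.5)            # balanced: both informative
  expect_gt(acc_of(0.5, "MIR"), 0.5)
})
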