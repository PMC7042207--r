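gauss_classes <- function(n_per = 20, p = 5, shift = 4, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p), n_per),
             matrix(rnorm(n_per * p, mean = shift), n_per))
  list(x = x, y = rep(c("a", "b"), each = n_per))
}

test_that("fixed seed makes forests bit-reproducible", {
  d <- gauss_classes(seed = 2)
  f1 <- fit_rf(d$x, d$y, rf_config(100, seed = 9))
  f2 <- fit_rf(d$x, d$y, rf_config(100, seed = 9))
  expect_identical(f1$votes, f2$votes)
  expect_identical(f1$oob_error, f2$oob_error)
  expect_identical(f1$importance, f2$importance)
})

test_that("vote rows are unit-sum fractions, in and out of bag", {
  d <- gauss_classes(seed = 3)
  f <- fit_rf(d$x, d$y, rf_config(150, seed = 1))
  expect_equal(unname(rowSums(f$votes)), rep(1, nrow(d$x)), tolerance = 1e-9)
  p <- predict(f, d$x + 0.1)
  expect_equal(unname(rowSums(p$membership)), rep(1, nrow(d$x)),
               tolerance = 1e-9)
  expect_error(fit_rf(d$x, rep("a", nrow(d$x)), rf_config(50)), "single-class")
})

test_that("well-separated Gaussian classes give near-zero OOB error", {
  d <- gauss_classes(n_per = 20, shift = 4, seed = 4)
  f <- fit_rf(d$x, d$y, rf_config(500, seed = 4))
  expect_lte(f$oob_error, 0.1)
})

test_that("label shuffling drives OOB error to the chance level", {
  set.seed(7)
  x <- matrix(rnorm(120 * 8), 120)
  y <- sample(rep(letters[1:4], each = 30))   # any signal destroyed
  f <- fit_rf(x, y, rf_config(300, seed = 7))
  chance <- 1 - 1 / 4
  se <- sqrt(chance * (1 - chance) / 120)
  expect_lt(abs(f$oob_error - chance), 4 * se + 0.02)
})

test_that("sequential OOB tuning finds signal and respects degenerate grids", {
  set.seed(8)
  x <- matrix(rnorm(80 * 51), 80)
  y <- rep(c("a", "b"), each = 40)
  x[y == "b", 1] <- x[y == "b", 1] + 3       # one informative variable in 51
  cfg <- tune_rf(x, y, ntree_grid = c(100, 300), mtry_grid = c(2, 7, 25),
                 seed = 8)
  expect_true(cfg$ntree %in% c(100, 300))
  tuned <- fit_rf(x, y, cfg)
  noise_cfg <- rf_config(cfg$ntree, cfg$mtry, seed = 8)
  baseline <- fit_rf(x[, 2:51], y, noise_cfg)  # signal column removed
  expect_lt(tuned$oob_error, baseline$oob_error)

  cfg1 <- tune_rf(x, y, ntree_grid = 200, mtry_grid = 5, seed = 1)
  expect_equal(cfg1$ntree, 200L)
  expect_equal(cfg1$mtry, 5L)
  expect_identical(tune_rf(x, y, ntree_grid = c(100, 200),
                           mtry_grid = c(3, 9), seed = 5)[1:3],
                   tune_rf(x, y, ntree_grid = c(100, 200),
                           mtry_grid = c(3, 9), seed = 5)[1:3])
  expect_error(tune_rf(x[1:4, ], y[1:4]), "at least 5")
})

test_that("noise variables carry no permutation importance", {
  set.seed(9)
  x <- matrix(rnorm(100 * 20), 100)
  y <- rep(c("a", "b"), each = 50)
  x[y == "b", 1] <- x[y == "b", 1] + 4
  f <- fit_rf(x, y, rf_config(400, seed = 9))
  # raw mean decrease in accuracy: ~2 binomial standard errors of zero
  se <- sqrt(0.5 * 0.5 / 100)
  expect_true(all(abs(f$importance[2:20]) < 2 * se))
  expect_gt(f$importance[1], max(abs(f$importance[2:20])))
})

test_that("variable selection keeps planted variables via the 1-SE rule", {
  hits <- sapply(1:10, function(seed) {
    set.seed(seed * 100)
    x <- matrix(rnorm(90 * 50), 90)
    y <- rep(letters[1:3], each = 30)
    for (j in 1:3) x[y == letters[j], j] <- x[y == letters[j], j] + 3
    sel <- suppressWarnings(select_variables(
      x, y, rf_config(150, seed = seed), folds = 10,
      k_grid = c(1, 2, 3, 5, 10, 25, 50)))
    all(1:3 %in% sel$selected)
  })
  expect_gte(sum(hits), 9)
})

test_that("selection degenerates sensibly without signal or choice", {
  set.seed(13)
  x <- matrix(rnorm(60 * 30), 60)
  y <- rep(c("a", "b", "c"), each = 20)
  sel <- select_variables(x, y, rf_config(100, seed = 13), folds = 5,
                          k_grid = c(2, 8, 30))
  expect_equal(sel$k, 2L)                      # no k helps: smallest wins
  sel_all <- select_variables(x, y, rf_config(100, seed = 13), folds = 5,
                              k_grid = 30)
  expect_setequal(sel_all$selected, 1:30)      # k = p: identity selection
  expect_warning(select_variables(x, y, rf_config(100, seed = 1), folds = 5,
                                  k_grid = c(10, 99)), "truncated")
})
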