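two_blocks <- function(n = 4, p1 = 5, p2 = 3, seed = 1) {
  set.seed(seed)
  ids <- paste0("s", 1:n)
  list(spectra_block(seq(9000, by = -100, length.out = p1),
                     matrix(rnorm(n * p1), n), ids, "NIR"),
       spectra_block(seq(3000, by = -100, length.out = p2),
                     matrix(rnorm(n * p2), n), ids, "MIR"))
}

test_that("low-level fusion splices scaled blocks NIR-first", {
  bl <- two_blocks()
  out <- low_level_fuse(bl)
  expect_equal(dim(out), c(4, 8))
  expect_equal(unname(attr(out, "provenance")),
               rep(c("NIR", "MIR"), c(5, 3)))
  expect_equal(unname(apply(out, 2, min)), rep(-1, 8))
  # MIR given first is still spliced NIR-first
  expect_equal(low_level_fuse(bl[2:1]), out)
  # the study's block widths reproduce the printed fused width
  wide <- list(spectra_block(seq(10000, by = -1, length.out = 3098),
                             matrix(0:1, 2, 3098), c("a", "b"), "NIR"),
               spectra_block(seq(3600, by = -1, length.out = 1047),
                             matrix(0:1, 2, 1047), c("a", "b"), "MIR"))
  expect_equal(ncol(low_level_fuse(wide)), 4145)
})

test_that("single-block low-level fusion is just the scaling", {
  bl <- two_blocks()
  out <- low_level_fuse(bl[1])
  expect_equal(out,
               apply_scale(bl[[1]]$intensities,
                           fit_scale(bl[[1]]$intensities)),
               ignore_attr = TRUE)
})

test_that("misaligned samples are rejected by name", {
  bl <- two_blocks()
  bl[[2]]$sample_ids <- rev(bl[[2]]$sample_ids)
  rownames(bl[[2]]$intensities) <- bl[[2]]$sample_ids
  expect_error(low_level_fuse(bl), "not sample-aligned")
  expect_error(mid_level_fuse(bl), "not sample-aligned")
})

test_that("mid-level eigenvalue rule retains components above 1", {
  # construct data whose sample covariance has eigenvalues 5.1, 2.3, 0.01
  set.seed(6)
  n <- 40
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  z <- scale(matrix(rnorm(n * 3), n))
  z <- qr.Q(qr(z)) * sqrt(n - 1)               # exactly orthonormal scores
  x <- z %*% diag(sqrt(c(5.1, 2.3, 0.01))) %*% t(q)
  b <- spectra_block(c(300, 200, 100), x, block = "NIR")
  out <- mid_level_fuse(list(b), prescale = FALSE)
  expect_equal(ncol(out), 2)

  bl <- two_blocks()
  expect_equal(ncol(mid_level_fuse(bl, component_rule = "fixed_k", k = 1)), 2)
  expect_error(mid_level_fuse(list(b), component_rule = "fixed_k"), "needs k")
})

test_that("duplicated blocks give equal score submatrices up to sign", {
  bl <- two_blocks()
  twin <- bl[[1]]; twin$block <- "MIR"
  out <- mid_level_fuse(list(bl[[1]], twin), component_rule = "fixed_k", k = 2)
  s1 <- out[, 1:2]; s2 <- out[, 3:4]
  for (j in 1:2)
    expect_equal(abs(cor(s1[, j], s2[, j])), 1, tolerance = 1e-10)
})

test_that("validation rows are projected with calibration loadings", {
  bl <- two_blocks(n = 10)
  out <- mid_level_fuse(bl, calibration = 1:6, component_rule = "fixed_k",
                        k = 2, prescale = FALSE)
  pc <- prcomp(bl[[1]]$intensities[1:6, ])
  ref <- sweep(bl[[1]]$intensities, 2, pc$center) %*% pc$rotation[, 1:2]
  expect_equal(unname(out[, 1:2]), unname(ref))
})

test_that("high-level fusion follows the four-operator worked example", {
  m1 <- class_membership(rbind(c(0.6, 0.3, 0.1)), paste0("c", 1:3))
  m2 <- class_membership(rbind(c(0.2, 0.5, 0.3)), paste0("c", 1:3))
  fd <- high_level_fuse(m1, m2)
  expect_false(fd$agreement)
  expect_equal(fd$min, "c2")       # (0.2, 0.3, 0.1) -> class 2
  expect_equal(fd$max, "c1")       # (0.6, 0.5, 0.3) -> class 1
  expect_equal(fd$mean, "c1")      # (0.4, 0.4, 0.2) tie -> lowest index
  expect_equal(fd$product, "c2")   # (0.12, 0.15, 0.03) -> class 2
  expect_equal(fd$final, "c1")     # 2-2 operator tie -> mean label
})

test_that("unanimous sources always carry the final label", {
  one_hot <- class_membership(rbind(c(0, 0, 1)), paste0("c", 1:3))
  fd <- high_level_fuse(one_hot, one_hot)
  expect_true(fd$agreement)
  expect_equal(fd$final, "c3")

  set.seed(14)
  for (i in 1:100) {
    a <- matrix(runif(12), 2); a <- a / rowSums(a)
    b <- matrix(runif(12), 2); b <- b / rowSums(b)
    agree <- apply(a, 1, which.max) == apply(b, 1, which.max)
    fd <- high_level_fuse(class_membership(a, paste0("c", 1:6)),
                          class_membership(b, paste0("c", 1:6)))
    lab <- paste0("c", apply(a, 1, which.max))
    expect_identical(fd$final[agree], lab[agree])
  }
})

test_that("a zero product entry annihilates that class and sets mismatch errors", {
  m1 <- class_membership(rbind(c(0.5, 0.5, 0)), paste0("c", 1:3))
  m2 <- class_membership(rbind(c(0, 0.2, 0.8)), paste0("c", 1:3))
  fd <- high_level_fuse(m1, m2)
  expect_equal(fd$product, "c2")   # only class with mass in both sources
  m3 <- class_membership(rbind(c(1, 0, 0)), paste0("k", 1:3))
  expect_error(high_level_fuse(m1, m3), "class-set mismatch")
  expect_error(class_membership(rbind(c(0.7, 0.7)), c("a", "b")), "sum to 1")
})

test_that("duplicating a block leaves downstream PLS-DA predictions unchanged", {
  set.seed(15)
  ds <- small_paperlike(15)
  b <- prep_blocks(ds)$NIR
  twin <- b; twin$block <- "MIR"
  y <- ds$metadata$class
  x1 <- low_level_fuse(list(b))
  x2 <- low_level_fuse(list(b, twin))
  m1 <- suppressWarnings(plsda(x1, y, n_lv = 8))
  m2 <- suppressWarnings(plsda(x2, y, n_lv = 8))
  expect_identical(predict(m1)$class, predict(m2)$class)
})
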