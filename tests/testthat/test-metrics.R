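test_that("one-vs-rest counts match hand tallies and invariants", {
  cm <- confusion(c("1", "1", "2"), c("1", "2", "2"))
  expect_equal(unname(cm$counts["1", ]), c(1, 0, 1, 1))  # TP FP TN FN
  expect_equal(unname(cm$counts["2", ]), c(1, 1, 1, 0))

  perfect <- confusion(rep(c("a", "b", "c"), each = 2),
                       rep(c("a", "b", "c"), each = 2))
  expect_equal(unname(perfect$counts[, "TP"]), rep(2, 3))
  expect_equal(unname(perfect$counts[, "TN"]), rep(4, 3))
  expect_error(confusion(c("a", "b"), c("a", "z")), "unknown label")

  # structural identities on random confusions
  set.seed(16)
  for (i in 1:20) {
    y <- sample(letters[1:4], 60, replace = TRUE)
    p <- sample(letters[1:4], 60, replace = TRUE)
    cm <- confusion(y, p, letters[1:4])
    expect_equal(unname(rowSums(cm$counts)), rep(60, 4))
    expect_equal(unname(cm$counts[, "TP"] + cm$counts[, "FN"]),
                 as.integer(table(factor(y, letters[1:4]))))
  }
})

test_that("efficiency is the geometric mean of sensitivity and specificity", {
  # the published table cells follow from the exact count ratios:
  # 1 of 3 correct vs perfect rejection
  y <- c(rep("g", 3), rep("o", 58))
  p <- c("g", rep("o", 60))
  m <- class_metrics(confusion(y, p))
  expect_equal(round_away(m$per_class["g", "SEN"]), 33.33)
  expect_equal(round_away(m$per_class["g", "EFF"]), 57.74)
  # 10/10 correct with 2 false positives among 51 negatives
  y <- c(rep("g", 10), rep("o", 51))
  p <- c(rep("g", 12), rep("o", 49))
  m <- class_metrics(confusion(y, p))
  expect_equal(round_away(unlist(m$per_class["g", c("SPE", "EFF")])),
               c(SPE = 96.08, EFF = 98.02))
  # 21/21 with 9 false positives among 105 negatives
  y <- c(rep("g", 21), rep("o", 105))
  p <- c(rep("g", 30), rep("o", 96))
  m <- class_metrics(confusion(y, p))
  expect_equal(round_away(unlist(m$per_class["g", c("SPE", "EFF")])),
               c(SPE = 91.43, EFF = 95.62))
  # 4 of 7, perfect rejection
  y <- c(rep("g", 7), rep("o", 54))
  p <- c(rep("g", 4), rep("o", 57))
  m <- class_metrics(confusion(y, p))
  expect_equal(round_away(m$per_class["g", "EFF"]), 75.59)
  # 3 of 4, perfect rejection
  y <- c(rep("g", 4), rep("o", 122))
  p <- c(rep("g", 3), rep("o", 123))
  m <- class_metrics(confusion(y, p))
  expect_equal(round_away(m$per_class["g", "EFF"]), 86.60)
})

test_that("macro averages exclude undefined precision entries", {
  sen <- c(100, 100, 33.33, 100, 100, 57.14, 100, 100, 0, 100, 0, 100, 66.67)
  pre <- c(100, 83.33, 100, 100, 100, 100, 71.43, 62.50, NA, 100, NA, 100, 100)
  eff <- c(100, 98.02, 57.74, 100, 100, 75.59, 98.20, 93.93, 0, 100, 0, 100,
           81.65)
  expect_equal(round_away(macro_average(sen)), 73.63)
  expect_equal(round_away(macro_average(pre)), 92.48)
  expect_equal(round_away(macro_average(eff)), 77.32)

  # a class never predicted has no precision and drops from the average
  m <- class_metrics(confusion(c("a", "a", "b"), c("a", "a", "a"),
                               c("a", "b")))
  expect_true(is.na(m$per_class["b", "PRE"]))
  expect_equal(m$macro[["PRE"]], m$per_class["a", "PRE"])
})

test_that("accuracy equals the class-size-weighted mean sensitivity", {
  set.seed(18)
  for (i in 1:20) {
    y <- sample(letters[1:5], 80, replace = TRUE)
    p <- ifelse(runif(80) < 0.6, y, sample(letters[1:5], 80, replace = TRUE))
    m <- class_metrics(confusion(y, p, letters[1:5]))
    w <- as.numeric(table(factor(y, letters[1:5]))) / 80
    expect_equal(m$accuracy, sum(w * m$per_class$SEN))
    # geometric-mean bounds
    ok <- !is.na(m$per_class$EFF)
    expect_true(all(m$per_class$EFF[ok] <=
                      pmax(m$per_class$SEN, m$per_class$SPE)[ok] + 1e-9))
    expect_true(all(m$per_class$EFF[ok] >=
                      pmin(m$per_class$SEN, m$per_class$SPE)[ok] - 1e-9))
  }
  perfect <- class_metrics(confusion(letters[1:4], letters[1:4]))
  expect_equal(unname(as.matrix(perfect$per_class)),
               matrix(100, 4, 4))
})

test_that("reported values round half away from zero", {
  # exactly representable halves, where round-half-even would differ
  expect_equal(round_away(0.125, 2), 0.13)
  expect_equal(round_away(-0.125, 2), -0.13)
  expect_equal(round_away(2.5, 0), 3)
  expect_equal(round_away(-2.5, 0), -3)
  expect_equal(round_away(sqrt(10000 / 3)), 57.74)
})
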