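#' Random-forest configuration
#'
#' @param ntree number of trees.
#' @param mtry candidate variables per split; default `floor(sqrt(p))` at
#'   fit time.
#' @param seed seed fixed before every forest grown under this
#'   configuration, so votes, importance and OOB error are bit-identical
#'   across runs.
#' @return object of class `rf_config`.
#' @export
rf_config <- function(ntree = 500, mtry = NULL, seed = 1) {
  if (ntree < 1) stop("ntree must be >= 1")
  structure(list(ntree = as.integer(ntree),
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 seed = as.integer(seed)), class = "rf_config")
}

#' @export
print.rf_config <- function(x, ...) {
  cat(sprintf("<rf_config> ntree = %d, mtry = %s, seed = %d\n", x$ntree,
              if (is.null(x$mtry)) "sqrt(p)" else x$mtry, x$seed))
  invisible(x)
}

#' Sequential out-of-bag tuning of a random forest
#'
#' The study protocol tunes the two forest parameters one after the other
#' on out-of-bag (OOB) error: first the tree count is scanned over
#' `ntree_grid` at the default `mtry` and fixed at the OOB-error minimum
#' (ties to the smallest tree count); then `mtry_grid` is scanned at that
#' tree count and fixed the same way. The ntree scan reads the cumulative
#' OOB error curve of a single forest grown to `max(ntree_grid)` trees —
#' the error a forest of each grid size would show under the same seed.
#'
#' @param x predictor matrix.
#' @param labels class label per row.
#' @param ntree_grid tree counts to scan.
#' @param mtry_grid per-split candidate counts to scan; default a
#'   log-spaced grid from 1 to `p` through `floor(sqrt(p))`.
#' @param seed seed fixed before every forest.
#' @return an [rf_config()] with the selected `ntree` and `mtry`; the OOB
#'   error curves are attached as `ntree_oob` and `mtry_oob`.
#' @export
tune_rf <- function(x, labels, ntree_grid = seq(100, 2000, by = 100),
                    mtry_grid = NULL, seed = 1) {
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nrow(x) < 5) stop("need at least 5 samples for OOB tuning")
  if (!length(ntree_grid)) stop("empty ntree grid")
  p <- ncol(x)
  if (is.null(mtry_grid))
    mtry_grid <- sort(unique(pmin(p, c(1, floor(sqrt(p)),
                                       round(2^seq(1, log2(p), length.out = 6))))))
  if (!length(mtry_grid)) stop("empty mtry grid")
  ntree_grid <- sort(as.integer(ntree_grid))
  set.seed(seed)
  rf <- randomForest::randomForest(x, labels, ntree = max(ntree_grid),
                                   mtry = max(1, floor(sqrt(p))))
  ntree_oob <- rf$err.rate[ntree_grid, "OOB"]
  best_nt <- ntree_grid[which.min(ntree_oob)]

  mtry_grid <- sort(unique(as.integer(pmin(mtry_grid, p))))
  mtry_oob <- vapply(mtry_grid, function(m) {
    set.seed(seed)
    f <- randomForest::randomForest(x, labels, ntree = best_nt, mtry = m)
    unname(f$err.rate[best_nt, "OOB"])
  }, 0)
  best_mt <- mtry_grid[which.min(mtry_oob)]
  cfg <- rf_config(best_nt, best_mt, seed)
  cfg$ntree_oob <- stats::setNames(ntree_oob, ntree_grid)
  cfg$mtry_oob <- stats::setNames(mtry_oob, mtry_grid)
  cfg
}

#' Fit a random forest and extract OOB error, votes and importance
#'
#' Wraps a bagged-tree ensemble (bootstrap sampling per tree) and exposes
#' the quantities the pipeline consumes: the OOB error, the per-sample
#' class-vote fractions (OOB votes for training samples — each row sums to
#' 1 — full-ensemble votes for new samples via [predict.rf_fit()]), and
#' raw permutation accuracy importance per variable (mean decrease in OOB
#' accuracy when the variable is permuted; set `scale_importance = TRUE`
#' for the z-scored variant).
#'
#' @param x predictor matrix.
#' @param labels class label per row (>= 2 classes).
#' @param cfg an [rf_config()].
#' @param scale_importance divide importance by its standard error.
#' @return object of class `rf_fit`: `oob_error`, `votes`, `importance`,
#'   `classes`, and the underlying `forest`.
#' @export
fit_rf <- function(x, labels, cfg = rf_config(), scale_importance = FALSE) {
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("single-class labels")
  mtry <- if (is.null(cfg$mtry)) max(1, floor(sqrt(ncol(x)))) else
    min(cfg$mtry, ncol(x))
  set.seed(cfg$seed)
  rf <- randomForest::randomForest(x, labels, ntree = cfg$ntree, mtry = mtry,
                                   importance = TRUE)
  votes <- unclass(rf$votes)
  votes <- votes / rowSums(votes)
  imp <- randomForest::importance(rf, type = 1, scale = scale_importance)[, 1]
  structure(list(oob_error = unname(rf$err.rate[cfg$ntree, "OOB"]),
                 votes = votes, importance = imp,
                 classes = levels(labels), config = cfg, forest = rf),
            class = "rf_fit")
}

#' @export
print.rf_fit <- function(x, ...) {
  cat(sprintf("<rf_fit> %d trees, mtry = %d, OOB error = %.4f\n",
              x$config$ntree, x$forest$mtry, x$oob_error))
  invisible(x)
}

#' Predict classes and vote-fraction membership from a fitted forest
#'
#' @param object an [rf_fit()].
#' @param newdata matrix of new samples; if omitted, the OOB votes and OOB
#'   predictions of the training samples are returned.
#' @param ... unused.
#' @return list with `class` and `membership` (vote fractions, rows sum
#'   to 1).
#' @export
predict.rf_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    memb <- object$votes
  } else {
    memb <- predict(object$forest, as.matrix(newdata), type = "vote")
    memb <- unclass(memb) / rowSums(memb)
  }
  cls <- object$classes[apply(memb, 1, which.max)]
  list(class = cls, membership = memb)
}

#' Select variables by permutation importance and cross-validated accuracy
#'
#' Variables are ranked by raw permutation accuracy importance from a
#' forest fitted under `cfg`; candidate top-`k` subsets over `k_grid` are
#' scored by `folds`-fold cross-validated forest accuracy, and the smallest
#' `k` whose mean accuracy is within one standard error of the best is
#' returned (one-standard-error rule).
#'
#' @param x predictor matrix.
#' @param labels class label per row.
#' @param cfg an [rf_config()].
#' @param folds cross-validation folds (study protocol: 10).
#' @param k_grid candidate subset sizes; values above `ncol(x)` are
#'   truncated with a warning. Default: powers of 2 up to `p`.
#' @return object of class `rf_selection`: `selected` (column indices,
#'   importance order), `k`, `ranking`, `cv_accuracy` (mean and se per k).
#' @export
select_variables <- function(x, labels, cfg = rf_config(), folds = 10,
                             k_grid = NULL) {
  x <- as.matrix(x)
  labels <- factor(labels)
  p <- ncol(x)
  if (is.null(k_grid)) k_grid <- unique(pmin(p, c(2^(0:20), p)))
  if (any(k_grid > p)) {
    warning("k grid truncated to the ", p, " available variables")
    k_grid <- pmin(k_grid, p)
  }
  k_grid <- sort(unique(as.integer(k_grid)))
  base <- fit_rf(x, labels, cfg)
  ranking <- order(-base$importance, seq_len(p))

  ord <- order(as.integer(labels), seq_along(labels))
  fold_of <- integer(length(labels))
  fold_of[ord] <- rep_len(seq_len(folds), length(labels))
  acc <- matrix(NA_real_, length(k_grid), folds)
  for (ki in seq_along(k_grid)) {
    cols <- ranking[seq_len(k_grid[ki])]
    for (f in seq_len(folds)) {
      tr <- fold_of != f
      set.seed(cfg$seed + f)
      m <- randomForest::randomForest(
        x[tr, cols, drop = FALSE], labels[tr], ntree = cfg$ntree,
        mtry = max(1, min(if (is.null(cfg$mtry)) floor(sqrt(length(cols)))
                          else cfg$mtry, length(cols))))
      pred <- predict(m, x[!tr, cols, drop = FALSE])
      acc[ki, f] <- mean(pred == labels[!tr])
    }
  }
  mean_acc <- rowMeans(acc)
  se_acc <- apply(acc, 1, stats::sd) / sqrt(folds)
  best <- which.max(mean_acc)
  k_sel <- k_grid[which(mean_acc >= mean_acc[best] - se_acc[best])[1]]
  structure(list(selected = ranking[seq_len(k_sel)], k = k_sel,
                 ranking = ranking,
                 cv_accuracy = data.frame(k = k_grid, mean = mean_acc,
                                          se = se_acc)),
            class = "rf_selection")
}

#' @export
print.rf_selection <- function(x, ...) {
  cat(sprintf("<rf_selection> %d variables selected (1-SE rule)\n", x$k))
  invisible(x)
}
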