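#' Partial least squares discriminant analysis
#'
#' Fits a PLS2 regression of a one-hot dummy class matrix on `x` by NIPALS,
#' extracting latent variables (LVs) sequentially from centred data. The
#' number of retained LVs is the largest run of leading components whose
#' X-eigenvalue exceeds 1, capped at `max_lv`; the eigenvalue of component
#' *a* is its explained X sum of squares expressed in average-variable
#' units, `SS_a / (SS_total / p)`, so "> 1" means the component carries
#' more X-variance than one variable's worth (the significant-component
#' convention; set `n_lv` to override). Model fit is summarised by
#' cumulative `R2X`, `R2Y`, cross-validated `Q2Y`, and per-class RMSEE /
#' RMSECV, with cross-validation by 7-fold venetian blinds over the
#' class-sorted sample order (so folds stay class-balanced).
#'
#' RMSEE uses denominator `n - n_lv - 1` per response column (estimation
#' residuals carry a fitted-parameter correction); RMSECV and RMSEP use
#' plain `n`.
#'
#' @param x numeric matrix of predictors (samples x variables).
#' @param labels class label per row (coerced to character).
#' @param max_lv maximum number of latent variables to consider.
#' @param folds number of cross-validation folds.
#' @param n_lv fixed LV count, bypassing the eigenvalue rule.
#' @param scale logical; scale columns to unit variance (default `FALSE`,
#'   centring only).
#' @return an object of class `plsda` with components `weights`,
#'   `x_loadings`, `y_loadings`, `scores`, `coefficients`, `n_lv`,
#'   `eigenvalues`, `classes`, and `stats` (class `plsda_stats`: `R2X`,
#'   `R2Y`, `Q2Y`, `RMSEE`, `RMSECV` per class and averaged).
#' @seealso [predict.plsda()], [permutation_test()]
#' @export
plsda <- function(x, labels, max_lv = 15, folds = 7, n_lv = NULL,
                  scale = FALSE) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes")
  if (nrow(x) <= folds) stop("need more samples than folds")
  y <- dummy_matrix(labels, classes)

  x_center <- colMeans(x)
  x_scale <- if (scale) apply(x, 2, stats::sd) else rep(1, ncol(x))
  if (any(x_scale == 0)) stop("constant variable with scale = TRUE")
  xc <- sweep(sweep(x, 2, x_center), 2, x_scale, "/")
  if (sum(xc^2) == 0) stop("X is constant")
  y_center <- colMeans(y)
  yc <- sweep(y, 2, y_center)

  small <- table(labels)
  if (any(small < folds))
    warning("class(es) ", paste(names(small)[small < folds], collapse = ", "),
            " have fewer members than folds; fold assignment is approximate")

  max_lv <- min(max_lv, nrow(x) - 1L, ncol(x), qr(xc)$rank)
  fit <- nipals_pls(xc, yc, max_lv)
  max_lv <- ncol(fit$W)                  # extraction may stop early
  p_vars <- ncol(x)
  eig <- fit$ssx_comp / (fit$ssx_total / p_vars)
  n_keep <- if (!is.null(n_lv)) min(n_lv, max_lv) else {
    below <- which(eig <= 1)
    by_eig <- max(1L, if (length(below)) min(below) - 1L else max_lv)
    # a G-class dummy response spans up to G-1 directions; never retain
    # fewer (capped by max_lv and rank), or class masking sets in
    min(max_lv, max(by_eig, length(classes) - 1L))
  }

  model <- structure(list(
    weights = fit$W[, seq_len(n_keep), drop = FALSE],
    x_loadings = fit$P[, seq_len(n_keep), drop = FALSE],
    y_loadings = fit$C[, seq_len(n_keep), drop = FALSE],
    scores = fit$T[, seq_len(n_keep), drop = FALSE],
    n_lv = n_keep, eigenvalues = eig,
    x_center = x_center, x_scale = x_scale, y_center = y_center,
    classes = classes, labels = labels, x = x), class = "plsda")
  model$coefficients <- pls_coef(model)

  # --- fit statistics -------------------------------------------------
  r2x <- sum(fit$ssx_comp[seq_len(n_keep)]) / fit$ssx_total
  yhat <- predict_response(model, x)
  res <- y - yhat
  ssy_tot <- colSums(yc^2)
  r2y <- 1 - sum(res^2) / sum(yc^2)
  n <- nrow(x)
  rmsee <- sqrt(colSums(res^2) / max(1, n - n_keep - 1))
  cvres <- cv_residuals(x, y, labels, classes, n_keep, folds, scale)
  q2y <- 1 - sum(cvres^2) / sum(yc^2)
  rmsecv <- sqrt(colMeans(cvres^2))
  names(rmsee) <- names(rmsecv) <- classes
  model$stats <- structure(list(
    R2X = r2x, R2Y = r2y, Q2Y = q2y,
    RMSEE = rmsee, RMSEE_avg = mean(rmsee),
    RMSECV = rmsecv, RMSECV_avg = mean(rmsecv)), class = "plsda_stats")
  model
}

dummy_matrix <- function(labels, classes) {
  y <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, classes))
  y[cbind(seq_along(labels), match(labels, classes))] <- 1
  y
}

# Sequential NIPALS PLS2 extraction on centred data.
nipals_pls <- function(xc, yc, ncomp, tol = 1e-10, maxit = 500) {
  n <- nrow(xc); p <- ncol(xc); q <- ncol(yc)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  C <- matrix(0, q, ncomp); Tm <- matrix(0, n, ncomp)
  ssx_total <- sum(xc^2)
  ssx_comp <- numeric(ncomp)
  X <- xc; Y <- yc
  for (a in seq_len(ncomp)) {
    u <- Y[, which.max(colSums(Y^2))]
    t_old <- rep(Inf, n)
    for (it in seq_len(maxit)) {
      w <- crossprod(X, u)[, 1]
      w <- w / sqrt(sum(w^2))
      t <- X %*% w
      cvec <- crossprod(Y, t)[, 1] / sum(t^2)
      u <- (Y %*% cvec) / sum(cvec^2)
      if (sum((t - t_old)^2) < tol * sum(t^2)) break
      t_old <- t
    }
    pvec <- crossprod(X, t)[, 1] / sum(t^2)
    ssx_comp[a] <- sum(t^2) * sum(pvec^2)
    W[, a] <- w; P[, a] <- pvec; C[, a] <- cvec; Tm[, a] <- t
    X <- X - t %*% t(pvec)
    Y <- Y - t %*% t(cvec)
    if (sum(X^2) < 1e-12 * ssx_total) {
      ncomp <- a
      W <- W[, 1:a, drop = FALSE]; P <- P[, 1:a, drop = FALSE]
      C <- C[, 1:a, drop = FALSE]; Tm <- Tm[, 1:a, drop = FALSE]
      ssx_comp <- ssx_comp[1:a]
      break
    }
  }
  list(W = W, P = P, C = C, T = Tm, ssx_comp = ssx_comp,
       ssx_total = ssx_total)
}

pls_coef <- function(m) {
  m$weights %*% solve(crossprod(m$x_loadings, m$weights)) %*% t(m$y_loadings)
}

predict_response <- function(m, x) {
  xc <- sweep(sweep(as.matrix(x), 2, m$x_center), 2, m$x_scale, "/")
  yhat <- xc %*% m$coefficients
  sweep(yhat, 2, m$y_center, "+")
}

cv_residuals <- function(x, y, labels, classes, n_lv, folds, scale) {
  ord <- order(labels, seq_along(labels))       # venetian blinds over classes
  fold_of <- integer(length(labels))
  fold_of[ord] <- rep_len(seq_len(folds), length(labels))
  res <- matrix(NA_real_, nrow(x), ncol(y))
  for (f in seq_len(folds)) {
    tr <- fold_of != f; te <- !tr
    xc_tr <- sweep(x[tr, , drop = FALSE], 2, colMeans(x[tr, , drop = FALSE]))
    sc <- if (scale) apply(x[tr, , drop = FALSE], 2, stats::sd) else
      rep(1, ncol(x))
    sc[sc == 0] <- 1
    xc_tr <- sweep(xc_tr, 2, sc, "/")
    yc_tr <- sweep(y[tr, , drop = FALSE], 2, colMeans(y[tr, , drop = FALSE]))
    k <- min(n_lv, sum(tr) - 1L, qr(xc_tr)$rank)
    fit <- nipals_pls(xc_tr, yc_tr, k)
    B <- fit$W %*% solve(crossprod(fit$P, fit$W)) %*% t(fit$C)
    xte <- sweep(sweep(x[te, , drop = FALSE], 2,
                       colMeans(x[tr, , drop = FALSE])), 2, sc, "/")
    yhat <- sweep(xte %*% B, 2, colMeans(y[tr, , drop = FALSE]), "+")
    res[te, ] <- y[te, , drop = FALSE] - yhat
  }
  res
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("PLS-DA model: %d classes, %d LVs (of %d variables, n = %d)\n",
              length(x$classes), x$n_lv, nrow(x$weights), nrow(x$scores)))
  cat(sprintf("  R2X = %.3f  R2Y = %.3f  Q2Y = %.3f\n",
              x$stats$R2X, x$stats$R2Y, x$stats$Q2Y))
  invisible(x)
}

#' @export
summary.plsda <- function(object, ...) {
  print(object)
  cat("\nPer-class RMSEE:\n"); print(round(object$stats$RMSEE, 4))
  cat("Per-class RMSECV:\n"); print(round(object$stats$RMSECV, 4))
  cat("Eigenvalues (average-variable units):\n")
  print(round(object$eigenvalues, 3))
  invisible(object)
}

#' @export
coef.plsda <- function(object, ...) object$coefficients

#' Plot PLS-DA scores
#'
#' Scatter of the first two latent-variable scores coloured by class.
#'
#' @param x a [plsda()] model.
#' @param lv which two LVs to plot.
#' @param ... passed to [graphics::plot()].
#' @export
plot.plsda <- function(x, lv = c(1, 2), ...) {
  s <- x$scores
  if (x$n_lv < 2) { s <- cbind(s, 0); lv <- c(1, 2) }
  cl <- factor(x$labels)
  graphics::plot(s[, lv[1]], s[, lv[2]], col = as.integer(cl),
                 pch = 19, xlab = paste0("LV", lv[1]),
                 ylab = paste0("LV", lv[2]), ...)
  graphics::legend("topright", legend = levels(cl),
                   col = seq_along(levels(cl)), pch = 19, cex = 0.7)
  invisible(x)
}

#' Predict classes and membership scores from a PLS-DA model
#'
#' The predicted dummy vector per sample is converted to a hard label by
#' argmax (ties to the lowest class index, flagged in the `ties`
#' attribute) and to a soft class-membership vector by clipping to `[0, 1]`
#' and renormalising to sum 1 — the currency of high-level fusion. A
#' predicted vector that clips to all zeros gives a uniform membership.
#'
#' @param object a [plsda()] model.
#' @param newdata matrix on the model's variable space; defaults to the
#'   training data.
#' @param ... unused.
#' @return list with `class` (character), `membership` (matrix, rows sum to
#'   1) and `response` (raw predicted dummies).
#' @export
predict.plsda <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$x
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_center))
    stop("variable count mismatch: model has ", length(object$x_center),
         ", newdata has ", ncol(newdata))
  yhat <- predict_response(object, newdata)
  memb <- membership_from_scores(yhat, object$classes)
  amax <- lapply(seq_len(nrow(yhat)),
                 function(i) which(yhat[i, ] == max(yhat[i, ])))
  ties <- vapply(amax, length, 0L) > 1L
  cls <- object$classes[vapply(amax, `[`, 0L, 1L)]
  structure(list(class = cls, membership = memb, response = yhat),
            ties = which(ties))
}

membership_from_scores <- function(scores, classes) {
  m <- pmin(pmax(scores, 0), 1)
  s <- rowSums(m)
  m[s == 0, ] <- 1 / length(classes)
  s[s == 0] <- 1
  m <- m / s
  colnames(m) <- classes
  m
}

#' Permutation test for a PLS-DA model
#'
#' The class labels are permuted uniformly at random `n_iter` times; the
#' model is refit at the original LV count and its `R2Y` / `Q2Y` recorded
#' against the correlation between the permuted and original dummy
#' matrices. Intercepts are the value at correlation 0 of the least-squares
#' line through the permuted points plus the original model at correlation
#' 1. A valid, non-overfitted model shows all permuted `R2`/`Q2` below the
#' originals and a `Q2`-intercept below 0.
#'
#' @param model a [plsda()] model (training data is stored on it).
#' @param n_iter number of permutations (the study protocol uses 20).
#' @param folds cross-validation folds for the permuted `Q2`.
#' @param seed optional seed for the permutations.
#' @return object of class `plsda_permutation`: data.frame `iterations`
#'   (`correlation`, `R2`, `Q2`), `R2_original`, `Q2_original`,
#'   `R2_intercept`, `Q2_intercept`.
#' @export
permutation_test <- function(model, n_iter = 20, folds = 7, seed = NULL) {
  stopifnot(inherits(model, "plsda"))
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  y0 <- dummy_matrix(model$labels, model$classes)
  it <- data.frame(correlation = numeric(n_iter), R2 = numeric(n_iter),
                   Q2 = numeric(n_iter))
  for (i in seq_len(n_iter)) {
    perm <- sample(model$labels)
    m <- suppressWarnings(plsda(model$x, perm, n_lv = model$n_lv,
                                folds = folds))
    it$correlation[i] <- abs(stats::cor(as.vector(dummy_matrix(perm, model$classes)),
                                        as.vector(y0)))
    it$R2[i] <- m$stats$R2Y
    it$Q2[i] <- m$stats$Q2Y
  }
  xx <- c(it$correlation, 1)
  fit_r <- stats::lm.fit(cbind(1, xx), c(it$R2, model$stats$R2Y))
  fit_q <- stats::lm.fit(cbind(1, xx), c(it$Q2, model$stats$Q2Y))
  structure(list(iterations = it,
                 R2_original = model$stats$R2Y,
                 Q2_original = model$stats$Q2Y,
                 R2_intercept = unname(fit_r$coefficients[1]),
                 Q2_intercept = unname(fit_q$coefficients[1])),
            class = "plsda_permutation")
}

#' @export
print.plsda_permutation <- function(x, ...) {
  cat(sprintf("Permutation test (%d iterations)\n", nrow(x$iterations)))
  cat(sprintf("  original R2 = %.3f  Q2 = %.3f\n", x$R2_original, x$Q2_original))
  cat(sprintf("  R2-intercept = %.3f  Q2-intercept = %.3f\n",
              x$R2_intercept, x$Q2_intercept))
  invisible(x)
}

#' Plot a PLS-DA permutation test
#'
#' Permuted and original `R2`/`Q2` against label correlation, with the
#' fitted intercept lines.
#'
#' @param x a `plsda_permutation` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.plsda_permutation <- function(x, ...) {
  it <- x$iterations
  graphics::plot(c(it$correlation, 1), c(it$R2, x$R2_original),
                 pch = 19, col = "darkgreen", ylim = range(c(it$Q2, it$R2, 1)),
                 xlab = "correlation with original labels",
                 ylab = expression(R^2 ~ "/" ~ Q^2), ...)
  graphics::points(c(it$correlation, 1), c(it$Q2, x$Q2_original),
                   pch = 17, col = "steelblue")
  graphics::abline(x$R2_intercept,
                   x$R2_original - x$R2_intercept, col = "darkgreen")
  graphics::abline(x$Q2_intercept,
                   x$Q2_original - x$Q2_intercept, col = "steelblue")
  invisible(x)
}
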