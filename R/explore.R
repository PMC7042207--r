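#' Principal-component scores with explained variance
#'
#' Scores of the centred data with per-component explained-variance
#' fractions. Component signs follow the largest-loading-positive rule, so
#' repeated runs give identical scores.
#'
#' @param x numeric matrix.
#' @param k number of components.
#' @return list with `scores` (n x k), `explained` (variance fractions),
#'   `loadings`, `center`.
#' @export
pca_scores <- function(x, k = 2) {
  x <- as.matrix(x)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  if (k > ncol(pc$rotation))
    stop("k exceeds the rank of the data (", ncol(pc$rotation), ")")
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  sc <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    flip <- sign(rot[which.max(abs(rot[, j])), j])
    if (flip < 0) { rot[, j] <- -rot[, j]; sc[, j] <- -sc[, j] }
  }
  list(scores = sc, explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
       loadings = rot, center = pc$center)
}

#' Hierarchical cluster analysis with a rescaled-height axis
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances by
#' default). Merge heights are rescaled linearly to `[0, 25]` — the
#' dendrogram convention of common statistics packages — so cluster-count
#' statements like "at distance 10 the samples fall into two groups" carry
#' over directly.
#'
#' @param x numeric matrix.
#' @param linkage linkage method for [stats::hclust()] (default
#'   `"ward.D2"`).
#' @param metric distance metric for [stats::dist()].
#' @return object of class `dendrogram_cut`: the `hclust` tree, raw
#'   and `rescaled` merge heights.
#' @export
hca <- function(x, linkage = "ward.D2", metric = "euclidean") {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 samples")
  hc <- stats::hclust(stats::dist(x, method = metric), method = linkage)
  structure(list(tree = hc, heights = hc$height,
                 rescaled = 25 * hc$height / max(hc$height)),
            class = "dendrogram_cut")
}

#' Cut a dendrogram at a rescaled height
#'
#' @param x a [hca()] result.
#' @param height cut height on the `[0, 25]` rescaled axis; merges at or
#'   below the cut are kept together.
#' @return integer cluster labels per sample.
#' @export
cut_clusters <- function(x, height) {
  stopifnot(inherits(x, "dendrogram_cut"))
  raw_h <- height / 25 * max(x$heights)
  stats::cutree(x$tree, h = raw_h)
}

#' @export
print.dendrogram_cut <- function(x, ...) {
  cat(sprintf("<dendrogram_cut> %d samples, heights rescaled to [0, 25]\n",
              length(x$tree$order)))
  invisible(x)
}

#' Plot a dendrogram on the rescaled axis
#'
#' @param x a [hca()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dendrogram_cut <- function(x, ...) {
  h <- x$tree
  h$height <- x$rescaled
  graphics::plot(h, ylab = "rescaled distance", ...)
  invisible(x)
}

#' t-distributed stochastic neighbour embedding
#'
#' Exact (dense) t-SNE to two dimensions: Gaussian input affinities with a
#' per-point bandwidth matched to `perplexity` by bisection, Student-t
#' output kernel, gradient descent with momentum and early exaggeration.
#' Deterministic under a fixed seed. Quadratic in n, intended for the
#' study-scale sample counts (a few hundred).
#'
#' @param x numeric matrix.
#' @param perplexity effective neighbour count; requires
#'   `nrow(x) > 3 * perplexity`.
#' @param seed seed for the random initialisation.
#' @param n_iter gradient-descent iterations.
#' @return n x 2 matrix of embedding coordinates.
#' @export
tsne_embed <- function(x, perplexity = 10, seed = 1, n_iter = 800) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n <= 3 * perplexity)
    stop("perplexity too large: need n > 3 * perplexity")
  d2 <- as.matrix(stats::dist(x))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- d2[i, -i]
    for (it in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 0 } else {
        p <- p / sp
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  G <- matrix(0, n, 2); gains <- matrix(1, n, 2)
  momentum <- 0.5; eta <- 100
  for (it in seq_len(n_iter)) {
    ex <- if (it <= 100) 4 else 1
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    dir_flip <- sign(grad) != sign(G)
    gains <- pmax(0.01, ifelse(dir_flip, gains + 0.2, gains * 0.8))
    G <- momentum * G - eta * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
    if (it == 100) momentum <- 0.8
    if (it == n_iter - 150) { momentum <- 0.3; eta <- eta / 10 }  # anneal
  }
  rownames(Y) <- rownames(x)
  Y
}

#' Summarise environmental covariates per cluster
#'
#' Joins cluster labels (or any grouping of samples) to a per-site
#' environmental covariate table and reports per-cluster means and ranges
#' — the reporting step behind statements like "the isolated branch is the
#' arid, high-latitude region".
#'
#' @param clusters vector of cluster labels, one per sample.
#' @param env data.frame of site covariates with a `site` column.
#' @param sites site id per sample (mapping samples onto `env`); samples
#'   whose site is missing from `env` are dropped with a warning.
#' @return data.frame with one row per cluster x covariate: mean, min,
#'   max, and the number of samples carrying a value.
#' @export
covariate_overlay <- function(clusters, env, sites) {
  stopifnot(length(clusters) == length(sites), "site" %in% names(env))
  idx <- match(sites, env$site)
  if (anyNA(idx)) {
    warning("unmapped sample site(s): ",
            paste(unique(sites[is.na(idx)]), collapse = ", "))
    keep <- !is.na(idx)
    clusters <- clusters[keep]; idx <- idx[keep]
  }
  num_cols <- names(env)[vapply(env, is.numeric, TRUE)]
  out <- do.call(rbind, lapply(split(idx, clusters), function(rows) {
    do.call(rbind, lapply(num_cols, function(v) {
      vals <- env[[v]][rows]
      data.frame(covariate = v, mean = mean(vals, na.rm = TRUE),
                 min = suppressWarnings(min(vals, na.rm = TRUE)),
                 max = suppressWarnings(max(vals, na.rm = TRUE)),
                 n = sum(!is.na(vals)))
    }))
  }))
  out$cluster <- rep(names(split(idx, clusters)),
                     each = length(num_cols))
  rownames(out) <- NULL
  out[, c("cluster", "covariate", "mean", "min", "max", "n")]
}
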