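#' Kennard-Stone sample selection
#'
#' Deterministic max-min-distance selection of `k` representative rows of
#' `x`. The first two picks are the pair at maximum Euclidean distance;
#' every subsequent pick maximises the minimum distance to the already
#' selected points. All ties break to the lowest row index, so the
#' selection is fully reproducible: identical input gives identical output,
#' with no randomness anywhere.
#'
#' @param x numeric matrix, one row per sample.
#' @param k number of rows to select, `2 <= k <= nrow(x)`.
#' @return integer vector of selected row indices, in selection order.
#' @export
kennard_stone <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("k (", k, ") exceeds number of samples (", n, ")")
  if (k < 2) stop("k must be at least 2")
  d <- as.matrix(stats::dist(x))
  # farthest pair, lexicographically smallest on ties
  best <- c(1L, 2L); bestd <- -1
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (d[i, j] > bestd) { bestd <- d[i, j]; best <- c(i, j) }
  }
  sel <- best
  mind <- pmin(d[, sel[1]], d[, sel[2]])
  while (length(sel) < k) {
    mind[sel] <- -Inf
    nxt <- unname(which.max(mind))   # which.max returns the first maximum
    sel <- c(sel, nxt)
    mind <- pmin(mind, d[, nxt])
  }
  as.integer(sel)
}

#' Split samples 2:1 into calibration and validation sets
#'
#' Kennard-Stone selection at a 2:1 calibration:validation ratio. In
#' `per_class` mode (the default) the selection runs within each class,
#' taking `round(2 * n_g / 3)` calibration samples per class of size `n_g`
#' (round half away from zero); applied to the study's 13 class sizes this
#' yields the 126 / 61 calibration / validation totals. `pooled` mode runs
#' one global selection with `k = round(2n/3)`.
#'
#' A class with a single member is forced into the calibration set with a
#' warning.
#'
#' @param x numeric matrix the Kennard-Stone distances are computed on
#'   (normally the preprocessed, scaled, low-level-fused matrix).
#' @param labels class label per row.
#' @param mode `"per_class"` or `"pooled"`.
#' @return an object of class `split_index`: integer vectors `calibration`
#'   and `validation` (disjoint, union = all rows), and a
#'   `per_class_counts` matrix with columns `n_cal`, `n_val`.
#' @export
split_two_to_one <- function(x, labels, mode = c("per_class", "pooled")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  round_away <- function(v) floor(v + 0.5)   # v > 0 here
  if (mode == "pooled") {
    k <- round_away(2 * nrow(x) / 3)
    cal <- sort(kennard_stone(x, k))
  } else {
    cal <- integer(0)
    for (g in unique(labels)) {
      idx <- which(labels == g)
      ng <- length(idx)
      if (ng == 1L) {
        warning("class '", g, "' has a single member; forced into calibration")
        cal <- c(cal, idx)
        next
      }
      kg <- max(2L, round_away(2 * ng / 3))
      if (kg >= ng) kg <- ng - 1L            # keep >= 1 validation sample
      if (ng == 2L) kg <- 1L
      cal <- c(cal, if (kg >= 2L)
        idx[kennard_stone(x[idx, , drop = FALSE], kg)] else idx[1L])
      # kg is round(2*ng/3) except at ng = 2 (split 1/1) and ng = 3 (2/1),
      # where the rounding already gives those values
    }
    cal <- sort(cal)
  }
  val <- setdiff(seq_len(nrow(x)), cal)
  cls <- unique(labels)
  counts <- t(vapply(cls, function(g)
    c(n_cal = sum(labels[cal] == g), n_val = sum(labels[val] == g)),
    integer(2)))
  structure(list(calibration = cal, validation = val,
                 per_class_counts = counts, mode = mode),
            class = "split_index")
}

#' @export
print.split_index <- function(x, ...) {
  cat(sprintf("<split_index> %d calibration / %d validation (%s mode)\n",
              length(x$calibration), length(x$validation), x$mode))
  invisible(x)
}
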