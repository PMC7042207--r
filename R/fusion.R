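#' Construct a class-membership matrix
#'
#' Per-sample, per-class soft scores in `[0, 1]` with rows summing to 1 —
#' what PLS-DA dummy predictions and random-forest vote fractions reduce
#' to, and the currency of high-level fusion.
#'
#' @param scores numeric matrix (samples x classes).
#' @param classes class names (default: column names of `scores`).
#' @param source optional tag, e.g. `"NIR/plsda"`.
#' @return object of class `class_membership` (a matrix with attributes).
#' @export
class_membership <- function(scores, classes = colnames(scores),
                             source = NULL) {
  m <- as.matrix(scores)
  if (is.null(classes)) stop("class names required")
  colnames(m) <- classes
  if (any(m < -1e-9) || any(m > 1 + 1e-9))
    stop("membership entries must lie in [0, 1]")
  if (any(abs(rowSums(m) - 1) > 1e-9))
    stop("membership rows must sum to 1")
  structure(m, class = c("class_membership", "matrix"),
            source = source)
}

#' Low-level fusion: variable concatenation
#'
#' Each preprocessed block is scaled to `[-1, 1]` per variable (parameters
#' fitted on calibration rows only) and the blocks' variables are spliced
#' sample-by-sample into one wide matrix, NIR block first. Column names
#' record provenance as `<block>_<wavenumber>`.
#'
#' @param blocks list of [spectra_block()]s with identical sample ids in
#'   identical order.
#' @param scale_params optional list of [fit_scale()] parameters, one per
#'   block; if `NULL`, fitted on the rows in `calibration`.
#' @param calibration row indices the scaling is learned on (default: all
#'   rows).
#' @return fused numeric matrix; block of origin per column in attribute
#'   `"provenance"`, the fitted scaling in `"scale_params"`.
#' @export
low_level_fuse <- function(blocks, scale_params = NULL, calibration = NULL) {
  check_alignment(blocks)
  ord <- order(match(vapply(blocks, `[[`, "", "block"), c("NIR", "MIR")))
  blocks <- blocks[ord]
  if (is.null(calibration)) calibration <- seq_len(nrow(blocks[[1]]$intensities))
  if (is.null(scale_params))
    scale_params <- lapply(blocks, function(b)
      fit_scale(b$intensities[calibration, , drop = FALSE]))
  scaled <- mapply(function(b, sp) {
    m <- apply_scale(b$intensities, sp)
    colnames(m) <- paste0(b$block, "_", format_wn(b$wavenumbers))
    m
  }, blocks, scale_params, SIMPLIFY = FALSE)
  out <- do.call(cbind, scaled)
  rownames(out) <- blocks[[1]]$sample_ids
  attr(out, "provenance") <- rep(vapply(blocks, `[[`, "", "block"),
                                 vapply(scaled, ncol, 0L))
  attr(out, "scale_params") <- scale_params
  out
}

check_alignment <- function(blocks) {
  ids <- blocks[[1]]$sample_ids
  for (b in blocks[-1]) {
    if (!identical(b$sample_ids, ids)) {
      bad <- union(setdiff(b$sample_ids, ids), setdiff(ids, b$sample_ids))
      if (!length(bad)) bad <- ids[b$sample_ids != ids]
      stop("blocks are not sample-aligned; offending ids: ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Mid-level fusion: concatenated principal-component scores
#'
#' Per block, PCA is fitted on the calibration rows (centred, covariance
#' eigenvalues) and components are retained either while their eigenvalue
#' exceeds 1 (`eigenvalue_gt_1`) or as a fixed count (`fixed_k`); all rows
#' — validation included — are projected with the calibration loadings, and
#' the per-block score matrices are concatenated NIR-first.
#'
#' @param blocks list of sample-aligned [spectra_block()]s.
#' @param calibration row indices PCA is fitted on (default: all).
#' @param component_rule `"eigenvalue_gt_1"` or `"fixed_k"`.
#' @param k components per block under `fixed_k`.
#' @param prescale apply the `[-1, 1]` fusion normalisation
#'   (calibration-fitted, see [fit_scale()]) to each block before PCA
#'   (default `TRUE`); the eigenvalue threshold is meaningful on the
#'   normalised scale. Set `FALSE` to run PCA on the raw block values.
#' @return fused score matrix; per-column block of origin in attribute
#'   `"provenance"`.
#' @export
mid_level_fuse <- function(blocks, calibration = NULL,
                           component_rule = c("eigenvalue_gt_1", "fixed_k"),
                           k = NULL, prescale = TRUE) {
  component_rule <- match.arg(component_rule)
  check_alignment(blocks)
  ord <- order(match(vapply(blocks, `[[`, "", "block"), c("NIR", "MIR")))
  blocks <- blocks[ord]
  if (is.null(calibration)) calibration <- seq_len(nrow(blocks[[1]]$intensities))
  pieces <- lapply(blocks, function(b) {
    intens <- b$intensities
    if (prescale)
      intens <- apply_scale(intens,
                            fit_scale(intens[calibration, , drop = FALSE]))
    cal <- intens[calibration, , drop = FALSE]
    pc <- stats::prcomp(cal, center = TRUE, scale. = FALSE)
    nc <- if (component_rule == "fixed_k") {
      if (is.null(k)) stop("fixed_k rule needs k")
      min(k, ncol(pc$rotation))
    } else sum(pc$sdev^2 > 1)
    if (nc == 0) stop("zero retained components for block ", b$block)
    sc <- sweep(intens, 2, pc$center) %*%
      pc$rotation[, seq_len(nc), drop = FALSE]
    colnames(sc) <- paste0(b$block, "_PC", seq_len(nc))
    sc
  })
  out <- do.call(cbind, pieces)
  rownames(out) <- blocks[[1]]$sample_ids
  attr(out, "provenance") <- rep(vapply(blocks, `[[`, "", "block"),
                                 vapply(pieces, ncol, 0L))
  out
}

#' High-level fusion: fuzzy-operator decision fusion with majority vote
#'
#' Per sample: if the two source classifiers agree (same argmax class) the
#' final label is theirs. For inconsistent samples the two membership
#' vectors are combined by four fuzzy connection operators — elementwise
#' minimum, maximum, average and product, each renormalised to sum 1 — and
#' the final label is the majority over the four operator argmax labels,
#' ties broken by the average-operator label. All argmax ties resolve to
#' the lowest class index.
#'
#' @param m1,m2 [class_membership()] matrices over the same samples and
#'   class set (e.g. NIR-model and MIR-model outputs).
#' @param weights length-2 source weights applied in the average operator
#'   (default equal).
#' @param include_sources also count the two source labels in the majority
#'   vote (default `FALSE`: the operators are invoked precisely for the
#'   inconsistent samples).
#' @return object of class `fusion_decision`: a data.frame with the two
#'   source labels, the four operator labels, the final label and an
#'   agreement flag per sample.
#' @export
high_level_fuse <- function(m1, m2, weights = c(1, 1),
                            include_sources = FALSE) {
  if (!identical(colnames(m1), colnames(m2)))
    stop("class-set mismatch between membership matrices")
  if (nrow(m1) != nrow(m2)) stop("sample-count mismatch")
  classes <- colnames(m1)
  amax <- function(v) which.max(v)   # first maximum = lowest class index
  renorm <- function(v) if (sum(v) > 0) v / sum(v) else
    rep(1 / length(v), length(v))
  lab1 <- classes[apply(m1, 1, amax)]
  lab2 <- classes[apply(m2, 1, amax)]
  n <- nrow(m1)
  op_lab <- matrix("", n, 4,
                   dimnames = list(NULL, c("min", "max", "mean", "product")))
  final <- character(n)
  agree <- lab1 == lab2
  w <- weights / sum(weights)
  for (i in seq_len(n)) {
    f <- rbind(min = renorm(pmin(m1[i, ], m2[i, ])),
               max = renorm(pmax(m1[i, ], m2[i, ])),
               mean = renorm(2 * (w[1] * m1[i, ] + w[2] * m2[i, ])),
               product = renorm(m1[i, ] * m2[i, ]))
    op_lab[i, ] <- classes[apply(f, 1, amax)]
    if (agree[i]) {
      final[i] <- lab1[i]
    } else {
      votes <- op_lab[i, ]
      if (include_sources) votes <- c(votes, lab1[i], lab2[i])
      tab <- table(votes)
      top <- names(tab)[tab == max(tab)]
      final[i] <- if (length(top) == 1) top else op_lab[i, "mean"]
    }
  }
  structure(data.frame(source1 = lab1, source2 = lab2, op_lab,
                       final = final, agreement = agree,
                       stringsAsFactors = FALSE),
            class = c("fusion_decision", "data.frame"))
}
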