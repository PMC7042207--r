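#' Multiplicative scatter correction reference
#'
#' The reference spectrum that MSC regresses each sample against. By default
#' it is the mean spectrum of the supplied block; in the modelling pipeline
#' the reference is computed on the calibration set only and then frozen for
#' validation spectra, so no validation information leaks into the
#' correction.
#'
#' @param x a [spectra_block()] (normally the calibration subset).
#' @return numeric reference spectrum over the block's axis.
#' @export
msc_reference <- function(x) colMeans(x$intensities)

#' Multiplicative scatter correction
#'
#' Each spectrum `x` is least-squares fitted to the reference,
#' `x ~ a * ref + b`, and replaced by `(x - b) / a`. This removes the
#' multiplicative (path-length / particle-size) and additive scatter
#' components that powder measurements accumulate. Slope and offset are
#' both corrected (the standard full MSC definition).
#'
#' If a fitted slope falls below `tol` in magnitude the spectrum is only
#' mean-centred and a warning names the sample.
#'
#' @param x a [spectra_block()].
#' @param ref reference spectrum (see [msc_reference()]); defaults to the
#'   mean spectrum of `x` itself.
#' @param tol minimum |slope| treated as invertible.
#' @return the corrected [spectra_block()].
#' @export
msc <- function(x, ref = NULL, tol = 1e-8) {
  if (is.null(ref)) ref <- msc_reference(x)
  if (length(ref) != ncol(x$intensities))
    stop("reference length does not match block")
  if (stats::sd(ref) == 0) stop("zero-variance MSC reference")
  rc <- ref - mean(ref)
  denom <- sum(rc^2)
  out <- x$intensities
  for (i in seq_len(nrow(out))) {
    xi <- out[i, ]
    a <- sum(rc * (xi - mean(xi))) / denom
    b <- mean(xi) - a * mean(ref)
    if (abs(a) < tol) {
      warning("MSC slope ~ 0 for sample '", x$sample_ids[i],
              "': returning mean-centred spectrum")
      out[i, ] <- xi - mean(xi)
    } else {
      out[i, ] <- (xi - b) / a
    }
  }
  spectra_block(x$wavenumbers, out, x$sample_ids, x$block)
}

#' Savitzky-Golay second derivative
#'
#' Per-spectrum second derivative with respect to the wavenumber axis,
#' computed by Savitzky-Golay polynomial filtering; removes baseline offset
#' and slope and sharpens overlapping bands. The axis must be (near)
#' uniformly spaced; edge values come from the filter's polynomial edge
#' fits. Output has the same shape as the input.
#'
#' @param x a [spectra_block()].
#' @param window odd filter window length in points (must exceed
#'   `poly_order`).
#' @param poly_order polynomial order, `>= 2`.
#' @param uniform_tol maximum allowed relative deviation of the axis spacing
#'   from uniformity.
#' @return a [spectra_block()] of second-derivative spectra
#'   (absorbance / cm^-2).
#' @export
second_derivative <- function(x, window = 11, poly_order = 2,
                              uniform_tol = 1e-6) {
  if (window %% 2 != 1 || window <= poly_order || poly_order < 2)
    stop("need odd window > poly_order >= 2")
  if (ncol(x$intensities) < window)
    stop("block has fewer variables than the filter window")
  d <- diff(x$wavenumbers)
  h <- abs(mean(d))
  if (max(abs(abs(d) - h)) > uniform_tol * h)
    stop("non-uniform wavenumber axis: interpolate to a uniform grid first")
  out <- t(apply(x$intensities, 1, signal::sgolayfilt,
                 p = poly_order, n = window, m = 2, ts = h))
  spectra_block(x$wavenumbers, out, x$sample_ids, x$block)
}

#' MSC + second-derivative pretreatment chain
#'
#' The pretreatment adopted for both blocks: multiplicative scatter
#' correction first, then the Savitzky-Golay second derivative.
#'
#' @inheritParams msc
#' @inheritParams second_derivative
#' @return the pretreated [spectra_block()].
#' @export
pretreat <- function(x, ref = NULL, window = 11, poly_order = 2) {
  second_derivative(msc(x, ref), window = window, poly_order = poly_order)
}

#' Fit per-variable [-1, 1] scaling on calibration data
#'
#' Before fusion, every variable is mapped to `[-1, 1]` by
#' `2 * (x - min) / (max - min) - 1`, with min/max learned on the
#' calibration rows only. Constant columns map to 0; validation values may
#' fall outside `[-1, 1]` (no clipping).
#'
#' @param x numeric matrix (calibration rows).
#' @return an object of class `scale_params` with per-column `min`, `max`.
#' @export
fit_scale <- function(x) {
  x <- as.matrix(x)
  structure(list(min = apply(x, 2, min), max = apply(x, 2, max)),
            class = "scale_params")
}

#' Apply fitted [-1, 1] scaling
#'
#' @param x numeric matrix on the same variables the parameters were fitted
#'   on.
#' @param params a `scale_params` object from [fit_scale()].
#' @return the scaled matrix.
#' @export
apply_scale <- function(x, params) {
  stopifnot(inherits(params, "scale_params"))
  x <- as.matrix(x)
  if (ncol(x) != length(params$min)) stop("variable count mismatch")
  rng <- params$max - params$min
  out <- sweep(x, 2, params$min)
  out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/") * 2 - 1
  out[, rng == 0] <- 0
  out
}
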