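#' Construct a spectral block
#'
#' A `spectra_block` is the unit every pipeline stage consumes and produces:
#' a wavenumber axis in cm^-1, an intensity matrix with one row per sample
#' (or replicate measurement) and one column per axis point, unique sample
#' ids, and a block tag identifying the instrument range (`"NIR"` for
#' 10,000-4,000 cm^-1 diffuse-reflectance near-infrared, `"MIR"` for
#' 4,000-650 cm^-1 ATR mid-infrared absorbance).
#'
#' The axis is stored strictly descending (instrument convention); input in
#' ascending order is reversed, columns in lockstep, so that two files
#' holding the same data in opposite axis order yield identical blocks.
#'
#' @param wavenumbers numeric vector of wavenumbers (cm^-1), strictly
#'   monotone in either direction.
#' @param intensities numeric matrix, `n_samples x length(wavenumbers)`,
#'   absorbance units. A single spectrum may be given as a vector.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to existing rownames or `"s1"`, `"s2"`, ...
#' @param block block tag, `"NIR"` or `"MIR"`.
#' @return an object of class `spectra_block` with fields `wavenumbers`,
#'   `intensities`, `sample_ids`, `block`.
#' @export
spectra_block <- function(wavenumbers, intensities, sample_ids = NULL,
                          block = c("NIR", "MIR")) {
  block <- match.arg(block)
  if (is.vector(intensities)) intensities <- matrix(intensities, nrow = 1)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) != ncol(intensities))
    stop("axis length (", length(wavenumbers),
         ") does not match intensity column count (", ncol(intensities), ")")
  d <- diff(wavenumbers)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("wavenumber axis must be strictly monotone")
  if (length(d) && all(d > 0)) {            # normalise to descending
    wavenumbers <- rev(wavenumbers)
    intensities <- intensities[, rev(seq_along(wavenumbers)), drop = FALSE]
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(intensities)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(intensities)))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(intensities))
    stop("sample_ids length does not match number of spectra")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyNA(intensities))
    stop("NA intensities are not permitted in a spectra_block")
  dimnames(intensities) <- list(sample_ids, format_wn(wavenumbers))
  structure(list(wavenumbers = wavenumbers, intensities = intensities,
                 sample_ids = sample_ids, block = block),
            class = "spectra_block")
}

format_wn <- function(wn) trimws(formatC(wn, format = "g", digits = 15))

#' @export
print.spectra_block <- function(x, ...) {
  cat(sprintf("<spectra_block:%s>  %d spectra x %d variables, %s-%s cm-1\n",
              x$block, nrow(x$intensities), length(x$wavenumbers),
              format(max(x$wavenumbers)), format(min(x$wavenumbers))))
  invisible(x)
}

#' @export
dim.spectra_block <- function(x) dim(x$intensities)

#' Plot all spectra of a block
#'
#' @param x a [spectra_block()].
#' @param col line colours, recycled over samples.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.spectra_block <- function(x, col = seq_len(nrow(x$intensities)), ...) {
  graphics::matplot(x$wavenumbers, t(x$intensities), type = "l", lty = 1,
                    col = col, xlim = rev(range(x$wavenumbers)),
                    xlab = expression(wavenumber ~ (cm^-1)),
                    ylab = "absorbance", ...)
  invisible(x)
}

#' Read a spectral matrix from delimited text
#'
#' Two dialects are supported. `wide`: the first row holds the wavenumber
#' axis (first cell is a header for the id column), each following row is a
#' sample id followed by its intensities. `long`: three columns
#' `sample_id, wavenumber, intensity`, one row per measurement point; every
#' sample must cover the same axis.
#'
#' The axis may be written ascending or descending; the returned block is
#' always descending.
#'
#' @param path file path.
#' @param dialect `"wide"` or `"long"`.
#' @param block block tag stored on the result.
#' @param sep field separator.
#' @return a [spectra_block()].
#' @export
read_spectra <- function(path, dialect = c("wide", "long"), block = "NIR",
                         sep = ",") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  cells <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(cells)
  if (length(unique(nf)) != 1L)
    stop("ragged rows in ", path, ": rows have ",
         paste(unique(nf), collapse = ", "), " fields")
  as_num <- function(x, row, col_off = 0L) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop(sprintf("non-numeric cell at row %d, column %d: '%s'",
                   row, j + col_off, x[j]))
    }
    v
  }
  if (dialect == "wide") {
    wn <- as_num(cells[[1]][-1], 1L, 1L)
    body <- cells[-1]
    ids <- vapply(body, `[[`, "", 1L)
    mat <- t(vapply(seq_along(body),
                    function(i) as_num(body[[i]][-1], i + 1L, 1L),
                    numeric(length(wn))))
    spectra_block(wn, mat, ids, block)
  } else {
    hdr <- suppressWarnings(as.numeric(cells[[1]][2]))
    body <- if (is.na(hdr)) cells[-1] else cells   # optional header line
    ids <- vapply(body, `[[`, "", 1L)
    wn <- vapply(seq_along(body), function(i) as_num(body[[i]][2], i), 0)
    val <- vapply(seq_along(body), function(i) as_num(body[[i]][3], i), 0)
    uid <- unique(ids)
    axis1 <- wn[ids == uid[1]]
    mat <- matrix(NA_real_, length(uid), length(axis1))
    for (i in seq_along(uid)) {
      sel <- ids == uid[i]
      if (sum(sel) != length(axis1) || any(wn[sel] != axis1))
        stop("long-format file: sample '", uid[i],
             "' does not cover the common wavenumber axis")
      mat[i, ] <- val[sel]
    }
    spectra_block(axis1, mat, uid, block)
  }
}

#' Write a spectral block to delimited text
#'
#' @param x a [spectra_block()].
#' @param path output file path.
#' @param dialect `"wide"` or `"long"` (see [read_spectra()]).
#' @param sep field separator.
#' @export
write_spectra <- function(x, path, dialect = c("wide", "long"), sep = ",") {
  dialect <- match.arg(dialect)
  fmt <- function(v) trimws(formatC(v, format = "g", digits = 17))
  if (dialect == "wide") {
    lines <- c(paste(c("sample_id", fmt(x$wavenumbers)), collapse = sep),
               vapply(seq_along(x$sample_ids), function(i)
                 paste(c(x$sample_ids[i], fmt(x$intensities[i, ])),
                       collapse = sep), ""))
  } else {
    lines <- c(paste("sample_id", "wavenumber", "intensity", sep = sep))
    for (i in seq_along(x$sample_ids))
      lines <- c(lines, paste(x$sample_ids[i], fmt(x$wavenumbers),
                              fmt(x$intensities[i, ]), sep = sep))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Average replicate measurements into one spectrum per sample
#'
#' Spectra are acquired in triplicate per sample; the arithmetic mean over
#' the replicate rows is taken before any further analysis.
#'
#' @param x a [spectra_block()] at replicate level.
#' @param replicate_map named list: sample id -> integer row indices of its
#'   replicate measurements in `x`.
#' @return a [spectra_block()] with one row per entry of `replicate_map`.
#' @export
average_replicates <- function(x, replicate_map) {
  stopifnot(is.list(replicate_map), !is.null(names(replicate_map)))
  n <- nrow(x$intensities)
  mat <- t(vapply(names(replicate_map), function(id) {
    idx <- replicate_map[[id]]
    if (length(idx) < 1L) stop("sample '", id, "' has no measurements")
    if (any(idx < 1L | idx > n))
      stop("measurement index out of range for sample '", id, "'")
    colMeans(x$intensities[idx, , drop = FALSE])
  }, numeric(ncol(x$intensities))))
  spectra_block(x$wavenumbers, mat, names(replicate_map), x$block)
}

#' Define wavenumber regions to exclude
#'
#' Closed intervals `[low, high]` in cm^-1, given as `c(high, low)` pairs.
#' Used to drop uninformative ranges (baseline area, diamond-crystal and
#' CO2 absorbance) before chemometric analysis.
#'
#' @param ... numeric length-2 vectors `c(high, low)` with `high >= low`.
#' @return an object of class `region_list`.
#' @export
region_list <- function(...) {
  iv <- list(...)
  for (r in iv) {
    if (length(r) != 2L || !is.numeric(r)) stop("each region must be c(high, low)")
    if (r[1] < r[2]) stop("region high (", r[1], ") < low (", r[2], ")")
  }
  structure(iv, class = "region_list")
}

#' Default excluded regions for the ATR-MIR block
#'
#' The baseline area (4,000-3,700 cm^-1), the diamond-crystal / CO2 window
#' (2,799-1,800 cm^-1) and the low-end cutoff (682-653 cm^-1).
#'
#' @return a [region_list()].
#' @export
default_excluded_regions <- function() {
  region_list(c(4000, 3700), c(2799, 1800), c(682, 653))
}

#' Drop axis points falling inside excluded regions
#'
#' A point nu is dropped when `high >= nu >= low` for any interval
#' (endpoints inclusive). Intensity columns are filtered in lockstep.
#'
#' @param x a [spectra_block()].
#' @param regions a [region_list()].
#' @return the filtered [spectra_block()].
#' @export
exclude_regions <- function(x, regions) {
  stopifnot(inherits(regions, "region_list"))
  keep <- rep(TRUE, length(x$wavenumbers))
  for (r in regions)
    keep <- keep & !(x$wavenumbers <= r[1] & x$wavenumbers >= r[2])
  if (!any(keep))
    stop("all variables excluded: empty block")
  spectra_block(x$wavenumbers[keep], x$intensities[, keep, drop = FALSE],
                x$sample_ids, x$block)
}
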