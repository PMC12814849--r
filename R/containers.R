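#' Dynamic perfusion series
#'
#' A registered time-resolved short-axis image stack: a 4-D array indexed
#' (row, col, slice, time) together with frame times in seconds and the
#' in-plane pixel spacing in mm. This is the raw material every curve and
#' map in the pipeline is derived from.
#'
#' @param data 4-D numeric array, dimensions (row, col, slice, time).
#' @param times Numeric vector of frame times in seconds, strictly
#'   increasing, length equal to `dim(data)[4]`.
#' @param pixdim In-plane pixel spacing in mm (scalar, isotropic).
#' @param domain `"signal"` or `"concentration"` — which physical quantity
#'   the voxel values carry.
#' @param meta Optional named list of provenance metadata.
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(data, times, pixdim = 1.5,
                           domain = c("concentration", "signal"),
                           meta = list()) {
  domain <- match.arg(domain)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data)[1:2], 1L, dim(data)[3])
  stopifnot(length(dim(data)) == 4L)
  if (length(times) != dim(data)[4])
    stop("length(times) must equal the number of frames")
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(data = data, times = as.numeric(times),
                 pixdim = pixdim, domain = domain, meta = meta),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dynamic_series> %dx%d px, %d slice(s), %d frames (%.1f-%.1f s), %s domain\n",
              d[1], d[2], d[3], d[4], min(x$times), max(x$times), x$domain))
  invisible(x)
}

#' Arterial input function curve
#'
#' Sampled gadolinium concentration in arterial blood, with the
#' hematocrit-corrected plasma curve alongside. Tofts-family kinetic models
#' are plasma-referenced while the Fermi model uses the blood curve, so both
#' are carried.
#'
#' @param times Frame times (s), strictly increasing.
#' @param blood Blood-pool gadolinium concentration (mM) per frame.
#' @param hematocrit Hematocrit fraction in [0, 1); plasma = blood / (1 - Hct).
#' @return An object of class `aif_curve` with elements `times`, `blood`,
#'   `plasma`, `hematocrit`.
#' @export
aif_curve <- function(times, blood, hematocrit = 0) {
  stopifnot(length(times) == length(blood))
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  if (hematocrit < 0 || hematocrit >= 1) stop("hematocrit must be in [0, 1)")
  structure(list(times = as.numeric(times), blood = as.numeric(blood),
                 plasma = as.numeric(blood) / (1 - hematocrit),
                 hematocrit = hematocrit),
            class = "aif_curve")
}

#' @export
print.aif_curve <- function(x, ...) {
  cat(sprintf("<aif_curve> %d frames, peak blood %.2f mM at t = %.1f s (Hct %.2f)\n",
              length(x$times), max(x$blood), x$times[which.max(x$blood)],
              x$hematocrit))
  invisible(x)
}

#' Parametric map
#'
#' Pixel-wise myocardial blood flow (mL/min/g) or perfusion-reserve ratio
#' defined over a myocardial mask, with a per-pixel goodness-of-fit layer.
#'
#' @param values 3-D numeric array (row, col, slice); `NA` outside the mask
#'   and at non-convergent pixels.
#' @param mask 3-D logical array of myocardial pixels.
#' @param quality Optional 3-D array of per-pixel R-squared.
#' @param pixdim In-plane pixel spacing (mm).
#' @param meta Named list (model, units, fit options, ...).
#' @return An object of class `parametric_map`.
#' @export
parametric_map <- function(values, mask, quality = NULL, pixdim = 1.5,
                           meta = list()) {
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
  stopifnot(identical(dim(values), dim(mask)))
  structure(list(values = values, mask = mask, quality = quality,
                 pixdim = pixdim, meta = meta),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<parametric_map> %d mask px, median %.2f [%.2f, %.2f], %d NA\n",
              sum(x$mask), stats::median(v, na.rm = TRUE),
              min(v, na.rm = TRUE), max(v, na.rm = TRUE), sum(is.na(v))))
  invisible(x)
}

#' Paired two-modality table
#'
#' Matched reference (PET, `x`) and test (CMR, `y`) values at a given
#' analysis level, the input to every agreement statistic.
#'
#' @param x Reference-modality values.
#' @param y Test-modality values, same length.
#' @param level Analysis level: `"participant"`, `"vessel"`, or `"segment"`.
#' @param id Optional unit identifiers.
#' @param subject Optional subject identifiers (clustering annotation only).
#' @return A data.frame of class `paired_table` with columns `id`, `level`,
#'   `x`, `y` (and `subject` when given). Non-finite pairs are dropped.
#' @export
paired_table <- function(x, y, level = "participant", id = NULL,
                         subject = NULL) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  out <- data.frame(id = (id %||% seq_along(x))[keep], level = level,
                    x = x[keep], y = y[keep])
  if (!is.null(subject)) out$subject <- subject[keep]
  class(out) <- c("paired_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce the (pairs) / (x, y) calling conventions of the stats functions.
.as_xy <- function(pairs, y = NULL) {
  if (is.data.frame(pairs)) {
    stopifnot(all(c("x", "y") %in% names(pairs)))
    list(x = pairs$x, y = pairs$y)
  } else {
    stopifnot(!is.null(y), length(pairs) == length(y))
    keep <- is.finite(pairs) & is.finite(y)
    list(x = pairs[keep], y = y[keep])
  }
}
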