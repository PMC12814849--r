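#' Saturation-recovery sequence parameters
#'
#' Parameters of the ideal saturation-recovery spoiled-gradient-echo signal
#' model used to linearise signal intensity against gadolinium
#' concentration. The dual-sequence acquisition uses a short saturation
#' delay (25 ms) for the low-resolution arterial-input stream and a longer
#' one (110 ms) for the high-resolution tissue stream.
#'
#' @param saturation_delay Effective saturation recovery time TD (s).
#' @param relaxivity_r1 Contrast-agent longitudinal relaxivity
#'   (L mmol^-1 s^-1); default 3.5, typical for Gd-DOTA at 3 T.
#' @param baseline_T1 Pre-contrast T1 (s); myocardium at 3 T is about 1.2 s.
#' @param baseline_frames Number of pre-contrast frames used for the
#'   per-pixel baseline signal.
#' @return A validated `seq_params` list.
#' @export
seq_params <- function(saturation_delay = 0.110, relaxivity_r1 = 3.5,
                       baseline_T1 = 1.2, baseline_frames = 3L) {
  if (saturation_delay <= 0) stop("saturation_delay must be > 0")
  if (relaxivity_r1 <= 0) stop("relaxivity_r1 must be > 0")
  if (baseline_T1 <= 0) stop("baseline_T1 must be > 0")
  if (baseline_frames < 1) stop("need at least 1 baseline frame")
  structure(list(saturation_delay = saturation_delay,
                 relaxivity_r1 = relaxivity_r1, baseline_T1 = baseline_T1,
                 baseline_frames = as.integer(baseline_frames)),
            class = "seq_params")
}

#' Saturation-recovery signal model
#'
#' Baseline-normalised saturation-recovery signal as a function of
#' gadolinium concentration:
#' `S(C) = (1 - exp(-TD (R10 + r1 C))) / (1 - exp(-TD R10))`
#' with `R10 = 1/T10`. `S(0) = 1` by construction, S is strictly increasing
#' in C, and saturates toward `1 / (1 - exp(-TD R10))` at high
#' concentration — the nonlinearity the conversion step corrects.
#'
#' @param conc Gadolinium concentration (mM), >= 0; vectorised.
#' @param seq A [seq_params()].
#' @return Dimensionless normalised signal.
#' @export
sr_signal <- function(conc, seq) {
  stopifnot(inherits(seq, "seq_params"))
  R10 <- 1 / seq$baseline_T1
  TD <- seq$saturation_delay
  (1 - exp(-TD * (R10 + seq$relaxivity_r1 * conc))) / (1 - exp(-TD * R10))
}

#' Invert the saturation-recovery signal model
#'
#' Closed-form logarithmic inversion of [sr_signal()]. Signals at or above
#' the saturation ceiling `1 / (1 - exp(-TD R10))` have no finite
#' pre-image and are flagged non-invertible (`NA` concentration).
#'
#' @param s Baseline-normalised signal; vectorised.
#' @param seq A [seq_params()].
#' @return List with `conc` (mM, `NA` where non-invertible) and logical
#'   `invertible`.
#' @export
sr_signal_inverse <- function(s, seq) {
  stopifnot(inherits(seq, "seq_params"))
  R10 <- 1 / seq$baseline_T1
  TD <- seq$saturation_delay
  arg <- 1 - s * (1 - exp(-TD * R10))
  ok <- is.finite(arg) & arg > 0
  conc <- rep(NA_real_, length(s))
  conc[ok] <- (-log(arg[ok]) / TD - R10) / seq$relaxivity_r1
  list(conc = conc, invertible = ok)
}

#' Convert a signal-domain series to gadolinium concentration
#'
#' Per pixel: signal intensity is normalised by the mean of the pre-contrast
#' baseline frames (which cancels coil gain and proton density), then
#' inverted through the saturation-recovery model. Pixels with
#' non-positive baseline are flagged invalid; concentrations below zero
#' (noise) are clipped to 0 and counted; samples at the saturation ceiling
#' are marked non-invertible (`NA`).
#'
#' @param series Signal-domain [dynamic_series()].
#' @param seq A [seq_params()].
#' @return Concentration-domain [dynamic_series()] whose `meta` records
#'   `n_clipped`, `n_noninvertible` and the logical `invalid_baseline` mask.
#' @export
concentration_from_signal <- function(series, seq) {
  stopifnot(inherits(series, "dynamic_series"), inherits(seq, "seq_params"))
  nb <- seq$baseline_frames
  if (dim(series$data)[4] <= nb)
    stop("series shorter than the baseline window")
  base <- apply(series$data[, , , seq_len(nb), drop = FALSE], 1:3, mean)
  invalid <- !is.finite(base) | base <= 0
  snorm <- sweep(series$data, 1:3, base, `/`)
  # time is the slowest dimension, so recycling the 3-D invalid mask along
  # the flattened 4-D array hits the same pixel in every frame
  snorm[rep(as.vector(invalid), dim(series$data)[4])] <- NA
  inv <- sr_signal_inverse(as.vector(snorm), seq)
  conc <- array(inv$conc, dim(series$data))
  n_noninv <- sum(!inv$invertible & !is.na(snorm))
  n_clip <- sum(conc < 0, na.rm = TRUE)
  conc[!is.na(conc) & conc < 0] <- 0
  dynamic_series(conc, series$times, series$pixdim,
                 domain = "concentration",
                 meta = c(series$meta,
                          list(n_clipped = n_clip,
                               n_noninvertible = n_noninv,
                               invalid_baseline = invalid)))
}

#' Proton-density normalisation
#'
#' Pixel-wise division of every frame by the proton-density map, removing
#' coil-sensitivity shading. Pixels with PD at or below `eps` are set to
#' `NA` (excluded from any downstream mask).
#'
#' @param series A [dynamic_series()].
#' @param pd_map 2-D or 3-D proton-density image on the series grid.
#' @param eps Positivity threshold.
#' @return A [dynamic_series()] in the same domain.
#' @export
pd_normalize <- function(series, pd_map, eps = 1e-6) {
  stopifnot(inherits(series, "dynamic_series"))
  if (length(dim(pd_map)) == 2L) dim(pd_map) <- c(dim(pd_map), 1L)
  if (!identical(dim(pd_map), dim(series$data)[1:3]))
    stop("pd_map grid does not match the series")
  if (all(pd_map <= eps)) stop("proton-density map is all (near) zero")
  pd <- pd_map
  pd[pd <= eps] <- NA
  out <- sweep(series$data, 1:3, pd, `/`)
  dynamic_series(out, series$times, series$pixdim, domain = series$domain,
                 meta = series$meta)
}

#' Arterial-input ROI
#'
#' A circular region of interest in the left-ventricular blood pool of the
#' low-resolution stream; 10-mm diameter by default.
#'
#' @param center ROI centre `(row, col)` in pixel coordinates.
#' @param diameter ROI diameter (mm).
#' @param slice Slice index.
#' @return A validated `aif_roi` list.
#' @export
aif_roi <- function(center, diameter = 10, slice = 1L) {
  if (diameter <= 0) stop("diameter must be > 0")
  structure(list(center = center, diameter = diameter,
                 slice = as.integer(slice)),
            class = "aif_roi")
}

#' Extract the arterial input function from a blood-pool ROI
#'
#' Per-frame mean concentration over the circular ROI — a pixel contributes
#' if its centre lies within `diameter / 2` of the ROI centre — then
#' hematocrit correction: plasma concentration = blood / (1 - Hct). Both
#' curves are returned on the [aif_curve()].
#'
#' @param series Concentration-domain [dynamic_series()] (low-resolution
#'   stream).
#' @param roi An [aif_roi()].
#' @param hematocrit Hematocrit fraction in (0, 1).
#' @return An [aif_curve()].
#' @export
extract_aif <- function(series, roi, hematocrit) {
  stopifnot(inherits(series, "dynamic_series"), inherits(roi, "aif_roi"))
  if (hematocrit <= 0 || hematocrit >= 1) stop("hematocrit must be in (0, 1)")
  d <- dim(series$data)
  cx <- roi$center[1]; cy <- roi$center[2]
  rpx <- roi$diameter / 2 / series$pixdim
  if (cx - rpx < 0.5 || cx + rpx > d[1] + 0.5 ||
      cy - rpx < 0.5 || cy + rpx > d[2] + 0.5 ||
      roi$slice < 1 || roi$slice > d[3])
    stop("AIF ROI extends outside the image")
  dist2 <- outer((seq_len(d[1]) - cx)^2, (seq_len(d[2]) - cy)^2, `+`)
  sel <- which(dist2 <= rpx^2, arr.ind = TRUE)
  if (nrow(sel) == 0L)  # degenerate ROI smaller than the pixel pitch
    sel <- which(dist2 == min(dist2), arr.ind = TRUE)[1, , drop = FALSE]
  blood <- vapply(seq_len(d[4]), function(f)
    mean(series$data[cbind(sel, roi$slice, f)]), numeric(1))
  aif_curve(series$times, blood, hematocrit)
}
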