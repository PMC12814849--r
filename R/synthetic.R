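#' Gamma-variate arterial input parameters
#'
#' Parameters of the synthetic first-pass bolus: a gamma-variate main pass
#' plus a delayed, scaled copy for recirculation. The defaults emulate a
#' compact single-bolus injection at 3 T: bolus arrival 5 s, gamma shape 3,
#' time-scale 2.5 s (peak at arrival + shape x scale = 12.5 s), peak blood
#' concentration about 5.4 mM, 15 % recirculation 20 s later.
#'
#' @param amplitude Concentration scale (mM), > 0.
#' @param t0 Bolus arrival time (s), >= 0.
#' @param alpha Gamma shape (dimensionless), > 0.
#' @param beta Gamma time-scale (s), > 0.
#' @param recirc_fraction Recirculation fraction in [0, 1).
#' @param recirc_delay Recirculation delay (s).
#' @param baseline Pre-contrast concentration (mM), normally 0.
#' @return A validated `aif_model_params` list.
#' @export
aif_model_params <- function(amplitude = 4, t0 = 5, alpha = 3, beta = 2.5,
                             recirc_fraction = 0.15, recirc_delay = 20,
                             baseline = 0) {
  if (amplitude <= 0) stop("amplitude must be > 0")
  if (alpha <= 0 || beta <= 0) stop("gamma shape and scale must be > 0")
  if (t0 < 0) stop("t0 must be >= 0")
  if (recirc_fraction < 0 || recirc_fraction >= 1)
    stop("recirc_fraction must be in [0, 1)")
  structure(list(amplitude = amplitude, t0 = t0, alpha = alpha, beta = beta,
                 recirc_fraction = recirc_fraction,
                 recirc_delay = recirc_delay, baseline = baseline),
            class = "aif_model_params")
}

#' Synthetic gamma-variate arterial input function
#'
#' First-pass bolus `amplitude * ((t - t0)/beta)^alpha * exp(-(t - t0)/beta)`
#' for `t > t0` (zero before arrival), plus `recirc_fraction` times the same
#' shape delayed by `recirc_delay`, on top of a constant baseline. The
#' gamma-variate is the field-standard smooth first-pass shape; its mode sits
#' at `t0 + alpha * beta`.
#'
#' @param params An [aif_model_params()].
#' @param times Sampling grid (s), strictly increasing, covering `t0`.
#' @param hematocrit Hematocrit fraction for the plasma curve.
#' @return An [aif_curve()].
#' @export
gamma_variate_aif <- function(params, times, hematocrit = 0) {
  stopifnot(inherits(params, "aif_model_params"))
  gv <- function(t) {
    u <- (t - params$t0) / params$beta
    ifelse(u > 0, params$amplitude * u^params$alpha * exp(-u), 0)
  }
  blood <- params$baseline + gv(times) +
    params$recirc_fraction * gv(times - params$recirc_delay)
  aif_curve(times, blood, hematocrit)
}

#' Kinetic parameters generating a given true MBF
#'
#' Maps a target myocardial blood flow to the generating parameter set of a
#' model, inverting the package's MBF read-out convention: Tofts-family
#' `K_trans = MBF * 1.05` (tissue density 1.05 g/mL), Fermi
#' `F = MBF * (1 + exp(-k MTT))` so that the initial impulse-response
#' amplitude `IRF(0)` equals the target flow. Shape parameters default to
#' physiologically typical values.
#'
#' @param model Model id.
#' @param mbf True MBF (mL/min/g).
#' @param Ve,Vp,k,MTT Shape parameters for the respective models.
#' @return Named parameter list accepted by [forward_model()].
#' @export
params_for_mbf <- function(model, mbf, Ve = 0.25, Vp = 0.05, k = 0.25,
                           MTT = 6) {
  model <- match_model(model)
  switch(model,
    tofts = list(K_trans = mbf * 1.05, Ve = Ve),
    modified_tofts = list(K_trans = mbf * 1.05, Ve = Ve, Vp = Vp),
    fermi = list(F = mbf * (1 + exp(-k * MTT)), k = k, MTT = MTT))
}

#' Simulate a tissue curve from an AIF
#'
#' Thin wrapper over [forward_model()]: the synthetic tissue response to a
#' given arterial input under a chosen kinetic model. By construction it is
#' bitwise identical to the forward model the fitter inverts.
#'
#' @inheritParams forward_model
#' @return Tissue concentration curve (mM).
#' @export
simulate_tissue_curve <- function(aif, model, params, delay = 0,
                                  aif_reference = "auto") {
  forward_model(aif, model, params, delay = delay,
                aif_reference = aif_reference)
}

#' Phantom specification
#'
#' Geometry, kinetics and noise of the synthetic multi-slice perfusion
#' phantom: an annular ("ring") myocardium around a circular blood pool in
#' each of three short-axis slices (basal, mid, apical), each AHA segment
#' carrying its own true MBF per physiological state. Frame grid defaults to
#' 60 frames at 1-s spacing — one heartbeat per frame over a 60-s
#' acquisition.
#'
#' @param dim In-plane image dimensions (pixels), length 2.
#' @param pixdim Pixel spacing (mm).
#' @param n_slices Number of short-axis slices (3 = basal, mid, apical;
#'   1 = basal only).
#' @param endo_radius,epi_radius Endocardial / epicardial radii (mm).
#' @param blood_pool_radius Blood-pool disk radius (mm).
#' @param frame_times Frame times (s), uniform spacing.
#' @param sector_truth List with elements `stress` and `rest`, each a named
#'   numeric vector of true MBF (mL/min/g) indexed by AHA segment id
#'   ("1".."16"); or a single value per state for a uniform phantom.
#' @param model Generating kinetic model id.
#' @param kin Shape parameters passed to [params_for_mbf()].
#' @param delay Bolus arrival delay of the tissue relative to the AIF (s).
#' @param aif Parameters of the arterial input ([aif_model_params()]).
#' @param hematocrit Hematocrit used for the plasma AIF.
#' @param noise_sd Concentration-domain Gaussian noise sd (mM), >= 0.
#' @param rv_insertion_angle RV insertion reference angle (degrees).
#' @param seed RNG seed.
#' @return A validated `phantom_spec` list.
#' @export
phantom_spec <- function(dim = c(48, 48), pixdim = 1.5, n_slices = 3,
                         endo_radius = 10, epi_radius = 20,
                         blood_pool_radius = 7,
                         frame_times = seq(0, 59, by = 1),
                         sector_truth = list(stress = 3.0, rest = 1.2),
                         model = "tofts",
                         kin = list(Ve = 0.25, Vp = 0.05, k = 0.25, MTT = 6),
                         delay = 2, aif = aif_model_params(),
                         hematocrit = 0.42, noise_sd = 0,
                         rv_insertion_angle = 0, seed = 1L) {
  if (epi_radius <= endo_radius || endo_radius <= 0)
    stop("need epi_radius > endo_radius > 0")
  if (any(diff(frame_times) <= 0)) stop("frame times must be strictly increasing")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  model <- match_model(model)
  seg_ids <- as.character(1:16)
  sector_truth <- lapply(sector_truth, function(v) {
    if (length(v) == 1L && is.null(names(v)))
      v <- stats::setNames(rep(v, 16), seg_ids)
    if (!all(seg_ids %in% names(v)))
      stop("sector_truth must cover AHA segments 1..16")
    v[seg_ids]
  })
  if (!all(c("stress", "rest") %in% names(sector_truth)))
    stop("sector_truth needs 'stress' and 'rest' entries")
  structure(list(dim = dim, pixdim = pixdim, n_slices = n_slices,
                 endo_radius = endo_radius, epi_radius = epi_radius,
                 blood_pool_radius = blood_pool_radius,
                 frame_times = frame_times, sector_truth = sector_truth,
                 model = model, kin = kin, delay = delay, aif = aif,
                 hematocrit = hematocrit, noise_sd = noise_sd,
                 rv_insertion_angle = rv_insertion_angle,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Annular myocardial mask and circular blood-pool mask for one slice.
annulus_masks <- function(dim, pixdim, endo, epi, pool) {
  cx <- (dim[1] + 1) / 2; cy <- (dim[2] + 1) / 2
  r <- sqrt(outer(((seq_len(dim[1]) - cx) * pixdim)^2,
                  ((seq_len(dim[2]) - cy) * pixdim)^2, `+`))
  list(myo = r > endo & r <= epi, pool = r <= pool,
       center = c(cx, cy))
}

#' Build the synthetic dynamic perfusion phantom
#'
#' Generates stress and rest concentration-domain dynamic series over an
#' annular myocardium: every myocardial pixel carries its AHA segment's
#' tissue curve (from [simulate_tissue_curve()] at the segment's true MBF),
#' blood-pool pixels carry the blood AIF, and i.i.d. Gaussian noise is added
#' in the concentration domain. Ground-truth MBF maps and the segment label
#' map come along, so the downstream fit can be scored against truth.
#'
#' @param spec A [phantom_spec()].
#' @return List with `stress`, `rest` ([dynamic_series()]), `truth` (list of
#'   stress/rest [parametric_map()]s), `labels` (3-D segment id array),
#'   `mask`, `pool_mask`, `aif` ([aif_curve()]), `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  aif <- gamma_variate_aif(spec$aif, spec$frame_times, spec$hematocrit)
  nt <- length(spec$frame_times)
  d3 <- c(spec$dim, spec$n_slices)
  levels <- c("basal", "mid", "apical")[seq_len(spec$n_slices)]

  g <- annulus_masks(spec$dim, spec$pixdim, spec$endo_radius,
                     spec$epi_radius, spec$blood_pool_radius)
  mask <- array(FALSE, d3); pool <- array(FALSE, d3)
  labels <- array(NA_integer_, d3)
  for (s in seq_len(spec$n_slices)) {
    mask[, , s] <- g$myo
    pool[, , s] <- g$pool
    labels[, , s] <- aha16_label(g$myo, spec$rv_insertion_angle, levels[s])
  }

  seg_curves <- function(truth) {
    ids <- sort(unique(labels[!is.na(labels)]))
    out <- lapply(ids, function(id)
      simulate_tissue_curve(aif, spec$model,
        do.call(params_for_mbf,
                c(list(model = spec$model, mbf = unname(truth[as.character(id)])),
                  spec$kin)),
        delay = spec$delay))
    names(out) <- as.character(ids)
    out
  }

  build_state <- function(truth, rng_stream) {
    curves <- seg_curves(truth)
    arr <- array(0, c(d3, nt))
    tru <- array(NA_real_, d3)
    for (s in seq_len(spec$n_slices)) {
      for (id in names(curves)) {
        sel <- which(!is.na(labels[, , s]) & labels[, , s] == as.integer(id),
                     arr.ind = TRUE)
        if (nrow(sel) == 0L) next
        for (r in seq_len(nrow(sel)))
          arr[sel[r, 1], sel[r, 2], s, ] <- curves[[id]]
        tru[, , s][labels[, , s] == as.integer(id) & !is.na(labels[, , s])] <-
          unname(truth[id])
      }
      psel <- which(pool[, , s], arr.ind = TRUE)
      for (r in seq_len(nrow(psel)))
        arr[psel[r, 1], psel[r, 2], s, ] <- aif$blood
    }
    if (spec$noise_sd > 0)
      arr <- arr + stats::rnorm(length(arr), 0, spec$noise_sd)
    list(series = dynamic_series(arr, spec$frame_times, spec$pixdim,
                                 domain = "concentration",
                                 meta = list(state = rng_stream,
                                             model = spec$model,
                                             seed = spec$seed)),
         truth = parametric_map(tru, mask, pixdim = spec$pixdim,
                                meta = list(units = "mL/min/g")))
  }

  set.seed(spec$seed)
  stress <- build_state(spec$sector_truth$stress, "stress")
  rest <- build_state(spec$sector_truth$rest, "rest")
  list(stress = stress$series, rest = rest$series,
       truth = list(stress = stress$truth, rest = rest$truth),
       labels = labels, mask = mask, pool_mask = pool, aif = aif,
       spec = spec)
}

#' Paired-cohort specification
#'
#' The statistical stand-in for a paired two-modality (CMR vs PET) perfusion
#' study: a latent true MBF per subject and state, observed by both arms
#' with arm-specific additive noise and a CMR-side bias. Defaults emulate a
#' 39-patient cohort with PET-like stress MBF 2.83 +/- 0.73 and rest MBF
#' 1.46 +/- 0.45 mL/min/g, a CMR bias of 0.31 mL/min/g and per-arm noise
#' 0.70/sqrt(2), giving a paired-difference sd of about 0.70.
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param stress_mean,stress_sd Latent stress MBF distribution (mL/min/g).
#' @param rest_mean,rest_sd Latent rest MBF distribution (mL/min/g).
#' @param cmr_bias Additive bias of the CMR arm (mL/min/g).
#' @param cmr_noise_sd,pet_noise_sd Arm noise sds (mL/min/g).
#' @param level Analysis level recorded on the output.
#' @param seed RNG seed.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 39, stress_mean = 2.83, stress_sd = 0.73,
                        rest_mean = 1.46, rest_sd = 0.45,
                        cmr_bias = 0.31, cmr_noise_sd = 0.70 / sqrt(2),
                        pet_noise_sd = 0.70 / sqrt(2),
                        level = "participant", seed = 1L) {
  if (n_subjects < 3) stop("n_subjects must be >= 3")
  if (any(c(stress_sd, rest_sd, cmr_noise_sd, pet_noise_sd) < 0))
    stop("sds must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects),
                 stress_mean = stress_mean, stress_sd = stress_sd,
                 rest_mean = rest_mean, rest_sd = rest_sd,
                 cmr_bias = cmr_bias, cmr_noise_sd = cmr_noise_sd,
                 pet_noise_sd = pet_noise_sd, level = level,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a paired CMR/PET cohort
#'
#' Draws the latent truth per subject from the specified normal, truncated
#' below at 0.05 mL/min/g (physiological positivity), then observes it in
#' both arms: CMR = truth + bias + noise, PET = truth + noise. MPR is the
#' stress/rest ratio within each arm.
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame (class `paired_cohort`) with one row per subject:
#'   `subject`, `level`, `stress_pet`, `stress_cmr`, `rest_pet`, `rest_cmr`,
#'   `mpr_pet`, `mpr_cmr`.
#' @export
simulate_paired_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  floor_at <- function(x) pmax(x, 0.05)
  truth_s <- floor_at(stats::rnorm(n, spec$stress_mean, spec$stress_sd))
  truth_r <- floor_at(stats::rnorm(n, spec$rest_mean, spec$rest_sd))
  obs <- function(truth, bias, sd)
    floor_at(truth + bias + stats::rnorm(n, 0, sd))
  out <- data.frame(
    subject = seq_len(n), level = spec$level,
    stress_pet = obs(truth_s, 0, spec$pet_noise_sd),
    stress_cmr = obs(truth_s, spec$cmr_bias, spec$cmr_noise_sd),
    rest_pet = obs(truth_r, 0, spec$pet_noise_sd),
    rest_cmr = obs(truth_r, spec$cmr_bias, spec$cmr_noise_sd))
  out$mpr_pet <- out$stress_pet / out$rest_pet
  out$mpr_cmr <- out$stress_cmr / out$rest_cmr
  class(out) <- c("paired_cohort", "data.frame")
  out
}

#' Extract a paired table from a simulated cohort
#'
#' @param cohort A [simulate_paired_cohort()] result.
#' @param measure `"stress"`, `"rest"`, or `"mpr"`.
#' @return A [paired_table()] with PET as `x` (reference) and CMR as `y`.
#' @export
cohort_pairs <- function(cohort, measure = c("stress", "rest", "mpr")) {
  measure <- match.arg(measure)
  paired_table(cohort[[paste0(measure, "_pet")]],
               cohort[[paste0(measure, "_cmr")]],
               level = cohort$level[1], id = cohort$subject)
}
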