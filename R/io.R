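#' Write a dynamic series as NIfTI + JSON sidecar
#'
#' The image stack goes to `<path>.nii.gz` and the acquisition metadata
#' (frame times, time unit, domain, extra metadata) to `<path>.json`.
#'
#' @param series A [dynamic_series()].
#' @param path Output path stem (no extension).
#' @return The path stem, invisibly.
#' @export
write_dynamic_series <- function(series, path) {
  stopifnot(inherits(series, "dynamic_series"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(RNifti::asNifti(series$data,
                                     pixdim = c(series$pixdim, series$pixdim, 1, 1)),
                     paste0(path, ".nii.gz"))
  meta <- series$meta
  meta$invalid_baseline <- NULL      # image-sized; not sidecar material
  jsonlite::write_json(
    list(frame_times = series$times, time_unit = "s",
         pixdim_mm = series$pixdim, domain = series$domain, meta = meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a dynamic series written by [write_dynamic_series()]
#'
#' Validates the sidecar: frame times must be present and strictly
#' increasing; a `time_unit` of `"ms"` is converted to seconds on read.
#'
#' @param path Path stem (no extension).
#' @return A [dynamic_series()].
#' @export
read_dynamic_series <- function(path) {
  json_path <- paste0(path, ".json")
  if (!file.exists(json_path))
    stop("missing JSON sidecar: ", json_path)
  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  if (is.null(side$frame_times))
    stop("sidecar is missing the 'frame_times' field")
  times <- as.numeric(side$frame_times)
  unit <- side$time_unit %||% "s"
  if (identical(unit, "ms")) times <- times / 1000
  if (any(diff(times) <= 0)) stop("sidecar frame times are not monotone")
  img <- RNifti::readNifti(paste0(path, ".nii.gz"))
  arr <- array(as.numeric(img), dim(img))
  dynamic_series(arr, times,
                 pixdim = side$pixdim_mm %||% RNifti::pixdim(img)[1],
                 domain = side$domain %||% "concentration",
                 meta = as.list(side$meta %||% list()))
}

#' Write a parametric map as NIfTI + provenance JSON
#'
#' @param map A [parametric_map()].
#' @param path Output path stem.
#' @return The path stem, invisibly.
#' @export
write_parametric_map <- function(map, path) {
  stopifnot(inherits(map, "parametric_map"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(RNifti::asNifti(map$values), paste0(path, ".nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(map$mask * 1L),
                     paste0(path, "_mask.nii.gz"))
  jsonlite::write_json(list(pixdim_mm = map$pixdim, meta = map$meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' Long-format cohort table
#'
#' Reshapes a simulated paired cohort to the interchange layout
#' `subject_id, level, territory, modality, state, value`.
#'
#' @param cohort A [simulate_paired_cohort()] result.
#' @return data.frame in long format.
#' @export
cohort_to_long <- function(cohort) {
  combos <- expand.grid(modality = c("pet", "cmr"),
                        state = c("stress", "rest", "mpr"),
                        stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    col <- paste0(combos$state[i], "_", combos$modality[i])
    data.frame(subject_id = cohort$subject, level = cohort$level,
               territory = NA_character_,
               modality = toupper(combos$modality[i]),
               state = combos$state[i], value = cohort[[col]])
  }))
}

# Validate a pipeline configuration before any computation happens.
validate_run_config <- function(config) {
  models <- config$models %||% "tofts"
  for (m in models) match_model(m)
  if (!is.null(config$hematocrit) &&
      (config$hematocrit <= 0 || config$hematocrit >= 1))
    stop("config: hematocrit must be in (0, 1)")
  if (is.null(config$phantom) && is.null(config$series))
    stop("config: provide either 'phantom' (a phantom_spec) or 'series' paths")
  invisible(config)
}

#' Run the full quantification pipeline
#'
#' Orchestrates the stages end to end: obtain the dynamic series (synthetic
#' phantom or files on disk), convert signal to concentration when needed,
#' extract or take the arterial input, fit MBF maps per model and state,
#' form MPR, label AHA segments, build the segment table and apply the
#' exclusion rules. All randomness flows from the seed embedded in the
#' phantom spec; rerunning the same configuration reproduces every output.
#'
#' @param config Named list (or path to a JSON file): `phantom` (a
#'   [phantom_spec()]) or `series` (named list of stress/rest path stems for
#'   [read_dynamic_series()]), `models` (character vector), `fit_options`,
#'   `hematocrit`, `aif_roi`, `seq` ([seq_params()], for signal-domain
#'   input), `output_dir` (optional; artifacts written when set).
#' @return List: per-model `maps` (stress, rest, mpr), `aif`, `labels`,
#'   `segment_tables`, `exclusions`, `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  validate_run_config(config)
  models <- config$models %||% "tofts"

  if (!is.null(config$phantom)) {
    ph <- make_phantom(config$phantom)
    series <- list(stress = ph$stress, rest = ph$rest)
    mask <- ph$mask
    labels <- ph$labels
    aif <- ph$aif
  } else {
    series <- lapply(config$series, read_dynamic_series)
    for (st in names(series))
      if (series[[st]]$domain == "signal")
        series[[st]] <- concentration_from_signal(series[[st]], config$seq)
    mask <- config$mask
    if (is.null(mask)) stop("config: a myocardial mask is required for file input")
    labels <- config$labels
    aif <- extract_aif(series[[1]], config$aif_roi, config$hematocrit)
  }

  results <- list()
  for (m in models) {
    stress_map <- fit_map(series$stress, aif, m, mask,
                          config$fit_options %||% list())
    rest_map <- fit_map(series$rest, aif, m, mask,
                        config$fit_options %||% list())
    mpr <- compute_mpr(stress_map, rest_map)
    tab <- if (!is.null(labels))
      segment_table(stress_map, rest_map, labels) else NULL
    exc <- if (!is.null(tab)) {
      thk <- segment_thickness(mask, labels,
                               pixdim = series$stress$pixdim)
      apply_exclusions(tab, thickness = thk[as.character(tab$segment)],
                       min_thickness = config$min_thickness %||% 5)
    } else NULL
    results[[m]] <- list(stress = stress_map, rest = rest_map, mpr = mpr,
                         segment_table = if (!is.null(exc)) exc$table else tab,
                         exclusions = if (!is.null(exc)) exc$summary else NULL)
  }

  if (!is.null(config$output_dir)) {
    out <- config$output_dir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    for (m in names(results)) {
      write_parametric_map(results[[m]]$stress, file.path(out, paste0(m, "_stress_mbf")))
      write_parametric_map(results[[m]]$rest, file.path(out, paste0(m, "_rest_mbf")))
      write_parametric_map(results[[m]]$mpr, file.path(out, paste0(m, "_mpr")))
      if (!is.null(results[[m]]$segment_table))
        utils::write.csv(results[[m]]$segment_table,
                         file.path(out, paste0(m, "_segments.csv")),
                         row.names = FALSE)
    }
    jsonlite::write_json(list(models = models,
                              seed = config$phantom$seed %||% NA,
                              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                         file.path(out, "provenance.json"),
                         auto_unbox = TRUE)
  }
  list(models = results, aif = aif, labels = labels, config = config)
}
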