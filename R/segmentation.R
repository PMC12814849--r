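#' AHA 16-segment labelling of a short-axis slice
#'
#' Partitions an annular myocardial mask into the standard American Heart
#' Association segments by equal angular sectors measured counterclockwise
#' from the RV-insertion reference ray: 6 sectors of 60 degrees on basal and
#' mid slices, 4 of 90 degrees on the apical slice. Segment ids follow the
#' AHA numbering (basal 1-6, mid 7-12, apical 13-16), ordered
#' anterior, (antero)septal, inferior(/inferoseptal), ... with increasing
#' angle from the insertion ray.
#'
#' @param mask 2-D logical myocardial mask (one slice).
#' @param rv_insertion_angle RV insertion reference angle (degrees,
#'   counterclockwise from the +row axis).
#' @param slice_level `"basal"`, `"mid"` or `"apical"`.
#' @param center Annulus centre `(row, col)`; defaults to the mask centroid.
#' @return Integer matrix of segment ids (`NA` off-mask).
#' @export
aha16_label <- function(mask, rv_insertion_angle = 0,
                        slice_level = c("basal", "mid", "apical"),
                        center = NULL) {
  slice_level <- match.arg(slice_level)
  if (!any(mask)) stop("empty myocardial mask")
  idx <- which(mask, arr.ind = TRUE)
  if (is.null(center)) center <- c(mean(idx[, 1]), mean(idx[, 2]))
  n_sec <- if (slice_level == "apical") 4L else 6L
  offset <- switch(slice_level, basal = 0L, mid = 6L, apical = 12L)
  width <- 360 / n_sec
  theta <- atan2(idx[, 2] - center[2], idx[, 1] - center[1]) * 180 / pi
  rel <- (theta - rv_insertion_angle) %% 360
  seg <- offset + pmin(floor(rel / width), n_sec - 1) + 1L
  out <- matrix(NA_integer_, nrow(mask), ncol(mask))
  out[idx] <- as.integer(seg)
  out
}

#' Coronary territory of an AHA segment
#'
#' Standard AHA territory grouping: LAD = {1,2,7,8,13,14},
#' RCA = {3,4,9,10,15}, LCX = {5,6,11,12,16}.
#'
#' @param segment Integer segment ids (1-16).
#' @return Character vector `"LAD"`, `"RCA"` or `"LCX"`.
#' @export
aha_territory <- function(segment) {
  map <- rep(NA_character_, 16)
  map[c(1, 2, 7, 8, 13, 14)] <- "LAD"
  map[c(3, 4, 9, 10, 15)] <- "RCA"
  map[c(5, 6, 11, 12, 16)] <- "LCX"
  map[segment]
}

slice_level_of <- function(segment) {
  c(rep("basal", 6), rep("mid", 6), rep("apical", 4))[segment]
}

#' Aggregate a parametric map over AHA labels
#'
#' Pixel means at the requested analysis level: per segment, per coronary
#' territory (mean over all pixels of the territory's segments), or per
#' participant (mean over all myocardial pixels). Segments present in the
#' label map but holding no finite pixel value are flagged with `NA`.
#'
#' @param map A [parametric_map()].
#' @param labels 3-D (or 2-D) integer AHA label array on the map grid.
#' @param level `"segment"`, `"vessel"` or `"participant"`.
#' @return data.frame with `unit` (segment id, territory, or "global"),
#'   `level`, `value`, `n_pixels`.
#' @export
aggregate_map <- function(map, labels,
                          level = c("segment", "vessel", "participant")) {
  level <- match.arg(level)
  stopifnot(inherits(map, "parametric_map"))
  if (length(dim(labels)) == 2L) dim(labels) <- c(dim(labels), 1L)
  stopifnot(identical(dim(labels), dim(map$values)))
  v <- map$values[map$mask]
  lab <- labels[map$mask]
  group <- switch(level,
    segment = lab,
    vessel = aha_territory(lab),
    participant = rep("global", length(lab)))
  keep <- !is.na(group)
  v <- v[keep]; group <- group[keep]
  units <- if (level == "segment") sort(unique(group)) else
    if (level == "vessel") intersect(c("LAD", "RCA", "LCX"), group) else "global"
  out <- data.frame(
    unit = as.character(units), level = level,
    value = vapply(units, function(u) {
      x <- v[group == u & !is.na(v)]
      if (length(x)) mean(x) else NA_real_
    }, numeric(1)),
    n_pixels = vapply(units, function(u) sum(group == u & !is.na(v)),
                      integer(1)),
    row.names = NULL)
  out
}

#' Per-segment stress/rest/MPR summary table
#'
#' Builds the segment-level analysis table: per AHA segment, pixel-mean
#' stress and rest MBF and the segment MPR as the ratio of segment means
#' (not the mean of pixel ratios — on heterogeneous segments the two
#' differ, and the ratio of means is the convention used here).
#'
#' @param stress,rest [parametric_map()]s on a shared grid.
#' @param labels AHA label array.
#' @param subject Subject identifier stamped on every row.
#' @return data.frame of class `segment_table`: `subject`, `segment`,
#'   `slice_level`, `territory`, `stress_mbf`, `rest_mbf`, `mpr`,
#'   `n_pixels`, `excluded`, `exclusion_reason`.
#' @export
segment_table <- function(stress, rest, labels, subject = "phantom") {
  s <- aggregate_map(stress, labels, "segment")
  r <- aggregate_map(rest, labels, "segment")
  stopifnot(identical(s$unit, r$unit))
  seg <- as.integer(s$unit)
  out <- data.frame(
    subject = subject, segment = seg,
    slice_level = slice_level_of(seg),
    territory = aha_territory(seg),
    stress_mbf = s$value, rest_mbf = r$value,
    mpr = ifelse(!is.na(r$value) & r$value > 0.1, s$value / r$value,
                 NA_real_),
    n_pixels = s$n_pixels,
    excluded = FALSE, exclusion_reason = "none")
  class(out) <- c("segment_table", "data.frame")
  out
}

# Round-half-up at d decimals (printed-style percentages, not banker's).
round_half_up <- function(x, d = 1) floor(x * 10^d + 0.5) / 10^d

#' Segment thickness from the mask
#'
#' Radial-extent thickness per segment: within each labelled sector the
#' extent of mask pixel-centre radii from the annulus centre, plus one
#' pixel width to account for pixel area. An externally measured
#' per-segment thickness table should be preferred when available.
#'
#' @param mask 3-D logical myocardial mask.
#' @param labels AHA label array on the mask grid.
#' @param pixdim Pixel spacing (mm).
#' @param center Optional `(row, col)` annulus centre per slice; defaults to
#'   each slice's mask centroid.
#' @return Named numeric vector of thickness (mm) per segment id.
#' @export
segment_thickness <- function(mask, labels, pixdim = 1.5, center = NULL) {
  if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
  if (length(dim(labels)) == 2L) dim(labels) <- c(dim(labels), 1L)
  segs <- sort(unique(labels[!is.na(labels)]))
  out <- stats::setNames(rep(NA_real_, length(segs)), segs)
  for (s in seq_len(dim(mask)[3])) {
    m <- mask[, , s]
    if (!any(m)) next
    idx <- which(m, arr.ind = TRUE)
    ctr <- if (is.null(center)) c(mean(idx[, 1]), mean(idx[, 2])) else center
    rr <- sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2) * pixdim
    lab <- labels[, , s][m]
    for (id in unique(lab[!is.na(lab)])) {
      ri <- rr[!is.na(lab) & lab == id]
      out[as.character(id)] <- diff(range(ri)) + pixdim
    }
  }
  out
}

#' Apply the segment exclusion rules
#'
#' Excludes segments with poor registration and segments thinner than the
#' minimum myocardial thickness (infarct thinning), and accounts for the
#' exclusions: counts and percentages (of all segments, rounded half-up to
#' one decimal) per reason and in total. A segment flagged for both reasons
#' is counted once, with poor registration taking precedence.
#'
#' @param table A [segment_table()] (or any data.frame with one row per
#'   segment observation).
#' @param registration_flags Logical per row: poor registration.
#' @param thickness Numeric per row: myocardial thickness (mm); `NA` means
#'   not assessed.
#' @param min_thickness Exclusion threshold (mm).
#' @return List: `table` (with `excluded` / `exclusion_reason` filled) and
#'   `summary` (counts and percentages).
#' @export
apply_exclusions <- function(table, registration_flags = NULL,
                             thickness = NULL, min_thickness = 5) {
  n <- nrow(table)
  reg <- registration_flags %||% rep(FALSE, n)
  thk <- thickness %||% rep(NA_real_, n)
  stopifnot(length(reg) == n, length(thk) == n)
  thin <- !is.na(thk) & thk < min_thickness
  reason <- ifelse(reg, "poor_registration",
                   ifelse(thin, "thin_myocardium", "none"))
  table$excluded <- reason != "none"
  table$exclusion_reason <- reason
  n_reg <- sum(reason == "poor_registration")
  n_thin <- sum(reason == "thin_myocardium")
  n_exc <- n_reg + n_thin
  summary <- list(
    n_segments = n, n_excluded = n_exc,
    n_poor_registration = n_reg, n_thin_myocardium = n_thin,
    pct_excluded = round_half_up(100 * n_exc / n, 1),
    pct_poor_registration = round_half_up(100 * n_reg / n, 1),
    pct_thin_myocardium = round_half_up(100 * n_thin / n, 1))
  list(table = table, summary = summary)
}
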