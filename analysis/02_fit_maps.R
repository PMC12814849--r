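#!/usr/bin/env Rscript
# Stage 2: pixel-wise MBF mapping of the simulated phantom.
#
# Reads the stage-1 series, extracts the arterial input from a 10-mm
# blood-pool ROI, deconvolves every myocardial pixel with the Tofts,
# modified-Tofts and Fermi models, forms MPR, aggregates to AHA segments
# and applies the thickness/registration exclusion rules. Writes maps and
# the per-model segment tables under results/maps/.

suppressPackageStartupMessages(library(qpcmr))

stopifnot(file.exists("results/phantom/geometry.rds"))
geom <- readRDS("results/phantom/geometry.rds")
stress <- read_dynamic_series("results/phantom/stress")
rest <- read_dynamic_series("results/phantom/rest")
out <- "results/maps"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# centre of the blood pool = centre of the grid, basal slice
ctr <- (dim(stress$data)[1:2] + 1) / 2
aif <- extract_aif(stress, aif_roi(ctr, diameter = 10, slice = 1),
                   hematocrit = geom$hematocrit)
cat(sprintf("AIF: peak blood %.2f mM at %.0f s (plasma %.2f mM)\n",
            max(aif$blood), aif$times[which.max(aif$blood)],
            max(aif$plasma)))

opts <- list(delay_grid = c(0, 1, 2, 3, 4))
summary_rows <- list()
for (model in c("tofts", "modified_tofts", "fermi")) {
  t0 <- proc.time()
  map_s <- fit_map(stress, aif, model, geom$mask, opts)
  map_r <- fit_map(rest, aif, model, geom$mask, opts)
  mpr <- compute_mpr(map_s, map_r)
  write_parametric_map(map_s, file.path(out, paste0(model, "_stress_mbf")))
  write_parametric_map(map_r, file.path(out, paste0(model, "_rest_mbf")))
  write_parametric_map(mpr, file.path(out, paste0(model, "_mpr")))

  tab <- segment_table(map_s, map_r, geom$labels)
  thk <- segment_thickness(geom$mask, geom$labels, pixdim = stress$pixdim)
  exc <- apply_exclusions(tab, thickness = thk[as.character(tab$segment)])
  utils::write.csv(exc$table, file.path(out, paste0(model, "_segments.csv")),
                   row.names = FALSE)

  ves <- aggregate_map(map_s, geom$labels, "vessel")
  cat(sprintf("%-15s stress MBF by vessel: %s | global %.2f | %.0f s\n",
              model,
              paste(sprintf("%s %.2f", ves$unit, ves$value), collapse = ", "),
              aggregate_map(map_s, geom$labels, "participant")$value,
              (proc.time() - t0)[3]))
  summary_rows[[model]] <- data.frame(model = model, ves)
}
utils::write.csv(do.call(rbind, summary_rows),
                 file.path(out, "vessel_summary.csv"), row.names = FALSE)
cat("note: the phantom's generating kinetics are Tofts, so the Tofts fit\n",
    "recovers truth while the other two models show model-transfer bias\n",
    "(modified-Tofts lower, Fermi higher) — a real feature of\n",
    "model-based deconvolution, not a fitting failure.\n", sep = "")
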