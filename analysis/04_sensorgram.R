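#!/usr/bin/env Rscript

# Extract sensorgrams from the selected pixels for the aptamer and control
# gratings, report percent change 10 min after analyte addition, write the
# final/initial green change-ratio image, and quantify response by
# fluorescence (height) bin.

library(braggsense)

stack <- read_stack("results/sim/stack.tif")
fluor <- read_image("results/sim/fluorescence.tif")
cfg <- read_simulation_config("results/sim/config.yaml")
bw <- baseline_frames(stack, cfg$analyte_time_min)
t_query <- cfg$analyte_time_min + 10

sel <- pixel_mask(read_image("results/select/selected_mask.tif") > 0.5,
                  provenance = "sd_band")
rois <- lapply(cfg$spots, function(s) s$region)
names(rois) <- vapply(cfg$spots, function(s) s$label, character(1))

dir.create("results/sensorgrams", recursive = TRUE, showWarnings = FALSE)
shape <- dim(fluor)

rows <- list()
sgs <- list()
for (nm in names(rois)) {
  m <- pixel_mask(sel & region_mask(rois[[nm]], shape))
  s <- extract_sensorgram(stack, m, bw, label = nm)
  sgs[[nm]] <- s
  pct <- percent_change(s, t_query)
  message(sprintf("%s: %+0.2f%% at %g min (10 min after addition), %d pixels",
                  nm, pct, t_query, sum(m)))
  rows[[nm]] <- data.frame(roi = nm, t_query_min = t_query,
                           pct_change = pct, n_pixels = sum(m))
}
message(sprintf("differential (aptamer - control): %+0.2f%%",
                compare_to_control(sgs$aptamer, sgs$control, t_query)))

utils::write.csv(do.call(rbind, lapply(sgs, as.data.frame)),
                 "results/sensorgrams/sensorgrams.csv", row.names = FALSE)
utils::write.csv(do.call(rbind, rows),
                 "results/sensorgrams/percent_changes.csv", row.names = FALSE)

ratio <- change_ratio_image(stack, n_frames(stack), 1)
write_image(ratio / max(ratio), "results/sensorgrams/change_ratio.tif")

# response vs grating height over the aptamer spot
m_apt <- pixel_mask(sel & region_mask(rois$aptamer, shape))
br <- height_binned_response(stack, fluor, m_apt, n_bins = 6,
                             t_query = t_query, baseline_window = bw)
utils::write.csv(br, "results/sensorgrams/height_binned_response.csv",
                 row.names = FALSE)
message("per-height-bin percent change written (",
        nrow(br), " bins)")
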