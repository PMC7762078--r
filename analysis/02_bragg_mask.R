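#!/usr/bin/env Rscript

# Identify Bragg-diffraction pixels in the simulated time lapse: average the
# pre-addition frames, divide the green channel by the red channel, and
# threshold the ratio (Otsu). Reports precision/recall against the simulated
# ground truth, which a real experiment does not have.

library(braggsense)

stack <- read_stack("results/sim/stack.tif")
cfg <- read_simulation_config("results/sim/config.yaml")
bw <- baseline_frames(stack, cfg$analyte_time_min)

green0 <- mean_channel(stack, bw, "green")
red0 <- mean_channel(stack, bw, "red")
ratio <- ratio_image(green0, red0)

tau <- suggest_threshold(ratio)
mask <- threshold_bragg(ratio, tau)
message(sprintf("Otsu ratio threshold tau = %.3f", tau))
message(sprintf("Bragg mask: %d of %d pixels", sum(mask), length(mask)))

truth <- round(tiff::readTIFF("results/sim/labels.tif", all = TRUE)[[2]] *
                 65535) == 1
tp <- sum(mask & truth)
message(sprintf("vs ground truth: precision %.3f, recall %.3f",
                tp / sum(mask), tp / sum(truth)))

dir.create("results/masks", recursive = TRUE, showWarnings = FALSE)
write_image(mask * 1, "results/masks/bragg_mask.tif")
write_image(unclass(ratio) / max(ratio), "results/masks/ratio.tif")
utils::write.csv(
  data.frame(tau = tau, n_total = length(mask), n_bragg = sum(mask),
             precision = tp / sum(mask), recall = tp / sum(truth)),
  "results/masks/bragg_mask_summary.csv", row.names = FALSE
)
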