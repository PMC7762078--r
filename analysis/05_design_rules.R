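#!/usr/bin/env Rscript

# Design-rule arithmetic for grating transducers: the practical height bound
# from the 1/10 height-to-line-width rule, how much thinner that is than a
# drop-cast micrometer multilayer, and the multiplexing capacity of a
# camera-addressed sensor array.

library(braggsense)

bound <- grating_height_bound(line_width_nm = 300)
ratio <- multilayer_thickness_ratio(multilayer_nm = 1000,
                                    grating_height_nm = bound)
tests <- multiplex_capacity(megapixels = 1.4, sensors_per_pixel = 1)

message(sprintf("height bound for 300 nm lines: %g nm", bound))
message(sprintf("1.0 um multilayer / grating bound: %gx thinner", ratio))
message(sprintf("1.4 MP camera, one sensor per pixel: %g tests per droplet",
                tests))

dir.create("results", showWarnings = FALSE)
utils::write.csv(
  data.frame(
    quantity = c("grating_height_bound_nm", "multilayer_thickness_ratio",
                 "tests_per_droplet"),
    value = c(bound, ratio, tests)
  ),
  "results/design_rules.csv", row.names = FALSE
)
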