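# braggsense

Image analysis for label-free optical biosensing with aptamer-functionalized
**lipid multilayer diffraction gratings**, plus a ground-truthed simulator of
the optical experiment.

Sub-100 nm-tall fluid lipid grating lines diffract obliquely incident white
light into a color camera; analyte binding (the model system is thrombin
captured by a DNA aptamer in the lipid ink) reshapes the lines and changes
the diffracted intensity. Each camera pixel is a candidate sensor — but only
some pixels actually see Bragg diffraction from well-formed gratings. The
package implements the pixel-selection and signal-extraction chain:

1. **Bragg-pixel classification** — divide the green channel by the red;
   Bragg pixels are green-dominant (ratio ≫ 1), broadband scatter is
   color-neutral (ratio ≈ 1); threshold the ratio (Otsu by default).
2. **SD-band pixel refinement** — using fluorescence *F* of the dye-doped
   lipid as the height proxy (*F = c_F·h*), bin pixels by fluorescence and
   keep those whose initial green intensity *G* lies within one sample SD
   of the bin mean, i.e. pixels consistent with the linear
   height–diffraction relation *G = c_D·min(h, w/10)* for line width *w*.
3. **Sensorgram extraction** — mean green over the selected pixels per
   frame, baseline *I₀* from the pre-addition window, percent change
   `100·(I(t) − I₀)/I₀`, final/initial change-ratio images, and response
   binned by grating height.

The simulator (`simulate_timelapse()`) renders RGB diffraction time lapses
and co-registered fluorescence images from the same physics (fluorescence ∝
height; diffraction linear in height up to *w*/10; pseudo-first-order
binding response; heterogeneous lognormal grating heights; scatter, defect
and camera noise), with full per-pixel ground truth, so every stage of the
analysis is testable without experimental data. See
`vignettes/methods.Rmd` for the model and its assumptions.

## Worked example

Simulate the packaged two-spot fixture (aptamer + non-aptamer control,
5 frames/min for 20 min, analyte added at 5 min) and run the full pipeline:

```r
library(braggsense)

cfg  <- fig6_config()
sim  <- simulate_timelapse(cfg, seed = 7)
rois <- lapply(cfg$spots, function(s) s$region)
names(rois) <- vapply(cfg$spots, function(s) s$label, "")

res <- analyze_stack(sim$stack, sim$fluorescence, cfg$analyte_time_min,
                     t_query = cfg$analyte_time_min + 10, rois = rois,
                     verbose = TRUE)
#> bragg-mask: tau = 2.3474; 6006 / 12288 pixels
#> sd-band: kept 5470 / 6006 Bragg pixels
#> height-diffraction fit: slope 0.8717, r^2 0.9807
res$percent_changes
#>       roi t_query_min  pct_change
#> 1 aptamer          15 19.24929584
#> 2 control          15  0.05367226
```

Reading: the green:red ratio threshold (chosen by Otsu) keeps 6006 of 12288
pixels as Bragg candidates; SD-band refinement keeps 5470 of those. The OLS
slope of initial green on fluorescence estimates the simulation's
diffraction/fluorescence gain ratio (0.9 here). Ten minutes after analyte
addition the aptamer grating's green intensity is up ~19% (the injected
steady-state response is 20%; the first-order kinetics have not fully
saturated and a small background dilutes the raw-intensity percent change),
while the control stays at ~0%.

The same analysis as a step-by-step workflow with files on disk lives in
`analysis/01_simulate.R` … `05_design_rules.R` (run them in order from the
repository root; outputs land under `results/`).

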