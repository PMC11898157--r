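# phantomcal

Phantom-based CT density calibration and periprosthetic bone analysis in R.

## What it does, and for whom

Quantitative CT densitometry needs a bridge from scanner intensity
(arbitrary units that drift with voltage, exposure and beam filtration) to
physical density. `phantomcal` implements that bridge around an in-house
density calibration phantom (DCP) of five polymer inserts — nylon, PEEK,
acetal, PPS, PTFE — whose certified densities (1.15–2.15 g/cc) bracket
trabecular and cortical bone. Per scan, the package segments the inserts,
fits the linear calibration

ρ(I) = a·I + b   (g/cc, ordinary least squares of density on mean insert
intensity)

and maps volumes voxel-wise to real density. On top of the calibration it
provides the analysis chain used to study bone changes during uncemented
total hip arthroplasty (THA): rigid stage registration (ICP), Gruen-zone
and bone–implant interface-shell regions of interest, bone volume fraction
(BV/TV), repeat-scan agreement statistics (bias, precision σ, limits of
agreement), and a full-factorial scan-parameter sensitivity analysis
(σ, 6σ, one-way ANOVA).

It is aimed at micro-CT / orthopaedic-biomechanics researchers who want a
tested, scriptable implementation of this workflow. Because no public scan
data accompanies the method, the package includes a synthetic micro-CT
generator (phantom, femur with cortical shell and trabecular network,
broaching/implantation stages with mass-conserving debris compaction, and
a partial-volume medical-CT analogue) with voxel-level ground truth, so the
entire pipeline is validated end-to-end in the test suite.

## Worked example

```r
library(phantomcal)

# synthetic phantom + femur with known ground truth
spec <- default_phantom_spec(radius_mm = 3, height_mm = 8, ring_radius_mm = 9)
phantom <- generate_phantom(spec, phantom_grid(spec, spacing = 0.5))
femur <- generate_femur(bone_phantom_params(outer_radius_mm = 6,
                                            length_mm = 15,
                                            cortical_thickness_mm = 1.2,
                                            seed = 7), spacing = 0.25)

# one scan: render, segment inserts, calibrate, map
p <- scan_protocol(100, 100, "0.25 mm Cu", noise_sd = 10, seed = 3)
scan <- render_scan(phantom, p)
labs <- segment_inserts(scan, spec)
ins <- mean_intensity_per_label(scan, labs)
line <- fit_calibration(ins$mean,
                        spec$densities[ins$label - tissue_labels$insert_base])
line
#> <calibration_line> density = 0.00105219 * I + -0.0495595 (R^2 = 1.000000, n = 5)

dens <- map_density(render_scan(femur, p), line)
mean(dens$voxels[femur$labels$voxels == tissue_labels$trabecular])
#> [1] 1.69968   # trabecular tissue density recovered (truth: 1.7 g/cc)
```

The fitted slope/intercept recover the scanner's (hidden) gain and offset,
and mapped insert means match the certified densities to ~4 decimals at
this noise level. A 12-protocol sensitivity run is one call:

```r
res <- run_doe(doe_grid(noise_sd = 10, seed = 50), phantom, femur, spec,
               bone_mask = "truth")
c(sigma = res$sigma, six_sigma = res$six_sigma)
#>        sigma    six_sigma
#> 0.0002995145 0.0017970870   # per-scan calibration cancels protocol effects
```

Reference insert measurements (masses, laser/CT volumes) ship with the
package: `build_insert_table()` reproduces the certified density table,
and `sensitivity_summary(reference_sensitivity_table()$mean_density)`
summarises the bundled 12-scan sensitivity study.

## Documentation

The methods vignette
(`vignettes/density-calibration-methods.Rmd`) describes the calibration
model, the synthetic scanner and femur, the segmentation and ROI
constructions, numerical choices and known limitations.
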