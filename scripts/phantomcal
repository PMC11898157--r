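#!/usr/bin/env Rscript

# Thin command-line wrapper over phantomcal's volume I/O and calibration:
#   phantomcal convert   --in A.mhd --out B.nii.gz
#   phantomcal simulate  --stage {phantom|pre|broach|implant} --out scan.mhd
#                        [--spacing 0.25] [--noise-sd 10] [--seed 1]
#   phantomcal calibrate --scan scan.mhd --out-line line.json
#   phantomcal map       --scan scan.mhd --line line.json --out density.mhd

suppressPackageStartupMessages({
  library(optparse)
  library(jsonlite)
  library(phantomcal)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L)
  stop("usage: phantomcal {convert|simulate|calibrate|map} [options]")
cmd <- args[1]
rest <- args[-1]

parse <- function(opts) parse_args(OptionParser(option_list = opts),
                                   args = rest)

default_scene <- function(spacing, seed) {
  spec <- default_phantom_spec()
  list(spec = spec,
       phantom = generate_phantom(spec, phantom_grid(spec, spacing = spacing)),
       femur = generate_femur(bone_phantom_params(seed = seed),
                              spacing = spacing),
       stage = surgical_stage_params())
}

if (cmd == "convert") {
  o <- parse(list(make_option("--in", type = "character", dest = "input"),
                  make_option("--out", type = "character")))
  write_volume(read_volume(o$input), o$out)
  cat("wrote", o$out, "\n")

} else if (cmd == "simulate") {
  o <- parse(list(
    make_option("--stage", type = "character", default = "phantom"),
    make_option("--out", type = "character"),
    make_option("--spacing", type = "double", default = 0.25),
    make_option("--noise-sd", type = "double", default = 10, dest = "noise"),
    make_option("--seed", type = "integer", default = 1L)))
  sc <- default_scene(o$spacing, o$seed)
  gt <- switch(o$stage,
               phantom = sc$phantom,
               pre = sc$femur,
               broach = apply_broaching(sc$femur, sc$stage),
               implant = insert_implant(apply_broaching(sc$femur, sc$stage),
                                        sc$stage),
               stop("unknown --stage: ", o$stage))
  scan <- render_scan(gt, scan_protocol(noise_sd = o$noise, seed = o$seed))
  write_volume(scan, o$out)
  cat("wrote", o$out, "\n")

} else if (cmd == "calibrate") {
  o <- parse(list(make_option("--scan", type = "character"),
                  make_option("--out-line", type = "character",
                              dest = "out_line")))
  spec <- default_phantom_spec()
  scan <- read_volume(o$scan)
  labs <- segment_inserts(scan, spec)
  ins <- mean_intensity_per_label(scan, labs)
  line <- fit_calibration(ins$mean,
                          spec$densities[ins$label -
                                         tissue_labels$insert_base])
  write_json(line[c("slope", "intercept", "r_squared", "n")], o$out_line,
             auto_unbox = TRUE, digits = NA)
  cat("wrote", o$out_line, "\n")

} else if (cmd == "map") {
  o <- parse(list(make_option("--scan", type = "character"),
                  make_option("--line", type = "character"),
                  make_option("--out", type = "character")))
  l <- read_json(o$line)
  line <- structure(list(slope = l$slope, intercept = l$intercept,
                         r_squared = l$r_squared, n = l$n),
                    class = "calibration_line")
  write_volume(map_density(read_volume(o$scan), line), o$out)
  cat("wrote", o$out, "\n")

} else {
  stop("unknown command: ", cmd)
}
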