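---
title: "Phantom-based CT densitometry and periprosthetic bone analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom-based CT densitometry and periprosthetic bone analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phantomcal)
```

## The problem

Quantitative CT densitometry converts scanner intensity (arbitrary units
that drift with voltage, exposure and beam filtration) into physical
density (g/cc) by scanning a density calibration phantom (DCP) alongside
the specimen. `phantomcal` implements this workflow around an in-house DCP
built from five polymer inserts — nylon, PEEK, acetal, PPS and PTFE — whose
certified densities (1.15, 1.31, 1.42, 1.62, 2.15 g/cc, the mean of
mass/laser-volume and mass/CT-volume determinations bundled in
`reference_insert_measurements()`) bracket trabecular and cortical bone.
Polymer inserts keep the phantom cheap and, because their densities extend
above cortical bone, let the mapping interpolate rather than extrapolate.

The downstream application is total hip arthroplasty (THA): broaching
compacts trabecular bone to shape the femoral cavity (osseodensification),
and the uncemented stem is press-fit into it. The package quantifies the
resulting bone changes across surgical stages — pre-surgery,
post-broaching, post-implantation — through rigid registration, Gruen-zone
summaries and the bone volume fraction (BV/TV) of a thin interface shell
around the cavity.

No scanner data ships with the package. Instead a synthetic micro-CT
generator produces phantom, femur and surgical-stage volumes with known
voxel-level ground truth, so every stage of the pipeline is testable and
its error measurable.

## The calibration model

Per scan, insert segmentation (`segment_inserts()`) yields a mean intensity
$\bar I_k$ per insert; ordinary least squares of certified density on mean
intensity (`fit_calibration()`) gives the per-scan line

$$\rho(I) = a I + b,$$

which `map_density()` applies voxel-wise, clamping negative predictions to
zero (a physical floor; intensities below the calibrated range carry no
density information). The regression direction is density on intensity
because that is the direction the mapping uses. The fit is unweighted: with
eroded insert masks of thousands of voxels each, the per-insert standard
errors are nearly equal and weighting would change nothing measurable.
Voxels mapping outside the calibrated density range are counted as
extrapolations when `range` is supplied.

Two scans of the same specimen are compared with `agreement_stats()`:
voxel-paired bias, the SD of differences ("precision half-width"),
1.96-sigma limits of agreement, Pearson correlation and the regression
slope of the second measurement on the first. Identical inputs are reported
as bias = sigma = 0, slope = R = 1 by convention. "Accuracy" against a
reference method is operationalised as bias together with limits of
agreement — the definition is stated here because half-width conventions
vary between reports.

## The synthetic scanner

`render_scan()` is affine in density with protocol-dependent gain and
offset:

$$I = g_0\,(V/100)^\alpha (E/100)^\beta f(\text{filter})\,\rho +
      b_0 f(\text{filter}) + \varepsilon,\qquad
  \varepsilon \sim N(0, \sigma_n^2).$$

The multiplicative protocol dependence is a configurable stand-in for
scanner physics (`scan_model()`, defaults $g_0 = 1000$, $\alpha = -0.4$,
$\beta = 0.15$, $b_0 = 50$, filter factors 1.00/0.95/0.90/0.82): the
calibration procedure never sees these constants and must recover each
scan's line from the phantom inserts alone. The default noise SD of 10
intensity units is roughly 1.4% of the bone–marrow contrast at the default
gain and keeps the standard error of an insert mean below 0.1% of its
value; no empirical noise magnitudes were available to emulate, so this is
a stated assumption, not a measured value. Renders are bit-reproducible
given the protocol seed. Beam hardening, scatter and metal streak artifacts
are deliberately out of scope — the synthetic scanner isolates the
intensity-to-density logic from artifact physics, so passing tests say
nothing about artifact robustness on real scans.

`simulate_medical_ct()` produces the clinical-CT analogue by block
averaging to ~0.5 mm voxels (factor `round(0.5 / spacing)` per axis) and
re-noising. Block averaging is exactly the partial-volume effect: a coarse
voxel mixes trabeculae, marrow and voids, so the mapped value approximates
*apparent* density, while micro-CT voxels inside bone tissue report *real*
density. The expected signature — trabecular apparent density drops
markedly while pure cortical voxels barely move — is asserted in the
acceptance suite.

## The synthetic femur and surgical stages

The femur (`generate_femur()`) is an idealised tapered tube: a cortical
shell of constant thickness around a medullary canal holding a trabecular
network, built by thresholding a Gaussian random field (white noise
smoothed to the correlation length) at the quantile that realises the
target BV/TV. Defaults: cortical tissue 1.9 g/cc, trabecular tissue
1.7 g/cc, marrow 1.0 g/cc (inside the 1.1–2.0 g/cc range reported for
femoral bone), BV/TV 0.30, correlation length 0.6 mm. The geometry is not
an anatomical mesh; every quantity the pipeline measures (masked means,
BV/TV, shell and zone statistics) needs distinct, known compartments, not
anatomical shape. Cortical voxels are classified by voxel centre with no
partial-volume mixing, which makes the cortical-masked mean density exactly
the cortical tissue density — a deliberate property used as an oracle.

`apply_broaching()` removes trabecular bone inside a tapered-prism cavity
and re-deposits a fraction `debris_retention` of the removed mass into the
interface shell (the distance-transform band of `shell_thickness_mm`,
default 1 mm, outside the cavity and inside the canal), converting marrow
voxels to bone closest-to-the-cavity-first until the budget is spent — a
mass-conserving model of debris compaction concentrated at the interface.
At most one voxel is partially filled, so bookkeeping closes to well within
0.1%. `retention_for_shell_bvtv_delta()` inverts the model in closed form
to hit a requested shell BV/TV increase. `insert_implant()` fills the
cavity with implant material and touches no bone voxel.

## Segmentation

Insert segmentation locates the `n_inserts + 1` dominant intensity modes
(base material plus one per insert) as peaks of a smoothed 512-bin
histogram with minimum-separation suppression. Peak detection is the right
primitive here: the base material contributes over 85% of the voxels, and
any clustering objective that competes across modes (k-means and its exact
variants included) will happily split the dominant mode and merge two
neighbouring insert modes once noise widens the base peak. Thresholds
between neighbouring modes are set by Otsu's method on the between-mode
sample, each band's largest connected component is kept,
and the mask is eroded by 2 voxels so partial-volume boundary voxels never
bias the mean intensity (on the synthetic oracle this makes the insert mean
unbiased). The band-to-insert assignment assumes positive gain (denser is
brighter) and a base material less dense than every insert.

Bone segmentation is a marker-seeded watershed on the gradient magnitude of
the (optionally Gaussian-smoothed) volume: conservative bone and background
markers from upper/lower intensity quantiles (defaults 0.99/0.50), flooding
in ascending gradient-quantile bands (discrete immersion, 24 bands), and a
nearest-marker-mean fallback for voxels never reached. On a noise-free
two-phase volume the recovery is exact; on the noisy synthetic femur the
Dice coefficient against ground truth exceeds 0.95 at 2% contrast noise.
Where two fronts meet in the same band, the bone label wins the tie — a
deterministic choice that affects only watershed-line voxels.

## Registration and regions of interest

Stages are aligned by iterative closest point (`icp_rigid_register()`):
brute-force nearest neighbours (point sets at stage-registration scale are
a few thousand points; no k-d tree needed) alternating with the SVD-based
Procrustes update, no outlier trimming — the stages image the same
specimen, so trimming would only mask errors. Labels are transferred
between grids by nearest-neighbour resampling through world coordinates
(labels must never be interpolated); the voxel-centre convention with
0-based index `k` at `origin + k * spacing` holds everywhere, and
anisotropic spacing is supported throughout because clinical grids are
anisotropic.

Gruen zones are a deterministic 3D operationalisation of the classic
radiographic zones: the implant axis is the principal axis of the implant
mask; periprosthetic bone within the implant's axial extent splits into
thirds of implant length; the sagittal plane through the implant centroid
(normal = medial–lateral axis of the femur coordinate system) separates
lateral zones 1–3 (proximal to distal) from medial zones 5–7 (distal to
proximal); zone 4 is the distal cap below the tip (default extent: a third
of implant length). Zone summaries report both bone-masked and whole-ROI
mean density, since either convention is defensible for mixed-tissue zones;
stage differences use the whole-ROI mean, which is the one debris
deposition moves.

The interface shell is `{0 < d <= t}` of the Euclidean distance transform
of the cavity/implant mask, intersected with the bone domain. The distance
transform is exact (separable, anisotropic-aware) up to a cap, but measures
voxel-centre to voxel-centre: against an analytic cylinder the shell volume
therefore converges first-order in spacing (about 5% off at 0.25 mm
voxels, under 2% at 62.5 um). Shell-based quantities compared *across
stages* share the same discretisation and are unaffected.

## Sensitivity analysis

`doe_grid()` builds the full factorial over voltage, exposure and
filtration (ordered voltage-slowest, filter-fastest); `run_doe()` executes
render → segment → calibrate → map → bone-masked mean per protocol and
summarises the per-scan means as the sample SD (n−1) and six times it
(`sensitivity_summary()`). Because calibration is per-scan, the protocol
gain/offset cancel and the simulated sensitivity collapses toward the
noise floor — the property that makes the method robust to scan settings.

One caveat the package surfaces honestly: the bundled reference study
(`reference_sensitivity_table()`) prints a sigma of 0.022 g/cc alongside a
6-sigma of 0.129 g/cc, but the sample SD of its twelve printed per-scan
means is 0.0215 g/cc (= 0.129/6), which rounds to 0.021. The two printed
summaries are mutually inconsistent at the last digit — presumably the
original sigma was computed on unrounded means — and `phantomcal` reports
the value its own computation produces.

`one_way_anova()` is the classical equal-variance F test
(`stats::oneway.test`); under a true null its rejection rate at 5% is
checked against the binomial band over a seeded replicate ladder. When
comparing scans, groups should be fixed-size seeded voxel subsamples: voxel
populations are so large that testing them wholesale makes any difference
"significant".

## Problem sizes and numerical choices

Tests and the acceptance script run on desk-scale versions of the study
geometry, chosen so that each property is resolution-checked rather than
size-dependent: phantom inserts of 3 mm radius on a 0.5 mm grid for
calibration recovery, a 0.1 mm-voxel femur (5 mm radius) for the
partial-volume comparison, a 0.2 mm-voxel femur (8 mm radius) for the
surgical stages, 1200 surface points for registration, and 1000 replicates
for the ANOVA calibration. Partial-volume voxelisation of analytic
cylinders computes the axial overlap exactly per slice and supersamples the
in-plane disc fraction 3x3 at boundary voxels (a full 3x3x3 midpoint scheme
is biased when cylinder caps align with voxel centres; the separable-exact
variant removes that failure mode while keeping the stated factor where it
matters). Mass bookkeeping counts density times voxel volume over bone
labels only.

## Limitations

* The intensity model is affine and artifact-free; nothing here validates
  behaviour under beam hardening or metal streaks.
* The femur is a tapered tube; zone geometry on anatomical femurs will
  differ in shape, though the zone construction itself is
  geometry-agnostic.
* Interface-shell volumes carry the first-order voxel-centre distance bias
  described above; compare shells across stages, not against analytic
  volumes, unless the grid is fine.
* The trabecular network is a thresholded Gaussian field: it reproduces
  BV/TV and a correlation length, not plate/rod microarchitecture.
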