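# Scan-parameter sensitivity: full-factorial design over voltage, exposure
# and beam filtration, the sigma/6-sigma sensitivity summary, one-way ANOVA
# across scans, and the surgical stage-change report.

#' Bundled reference sensitivity study
#'
#' The twelve-scan full factorial (voltage 100/110 kV, exposure 80/100 ms,
#' filtration none / 0.25 mm Cu / 0.25 mm Sn) with the measured mean
#' lamb-femur density per scan, used as the default input for
#' [sensitivity_summary()] examples.
#'
#' @return A data.frame with columns `scan`, `voltage_kv`, `exposure_ms`,
#'   `filter`, `mean_density`.
#' @export
reference_sensitivity_table <- function() {
  data.frame(
    scan = paste("Scan", 1:12),
    voltage_kv = rep(c(100, 110), each = 6),
    exposure_ms = rep(rep(c(80, 100), each = 3), times = 2),
    filter = rep(c("no", "0.25 mm Cu", "0.25 mm Sn"), times = 4),
    mean_density = c(1.528, 1.530, 1.525, 1.526, 1.567, 1.580,
                     1.570, 1.577, 1.562, 1.570, 1.560, 1.569),
    stringsAsFactors = FALSE)
}

#' Full-factorial grid of scan protocols
#'
#' Cartesian product ordered with voltage slowest and filter fastest
#' (Scan 1 = first voltage, first exposure, first filter).
#'
#' @param voltages_kv,exposures_ms Numeric level vectors.
#' @param filters Character level vector (see [scan_protocol()]).
#' @param voxel_mm,noise_sd Passed to every protocol.
#' @param seed Base seed; protocol `i` receives `seed + i`.
#' @return A list of [scan_protocol()]s labelled `"Scan 1"`, `"Scan 2"`, ...
#' @export
doe_grid <- function(voltages_kv = c(100, 110), exposures_ms = c(80, 100),
                     filters = c("no", "0.25 mm Cu", "0.25 mm Sn"),
                     voxel_mm = 0.07, noise_sd = 10, seed = 100L) {
  if (!length(voltages_kv) || !length(exposures_ms) || !length(filters))
    stop("level lists must be non-empty")
  i <- 0L
  out <- list()
  for (v in voltages_kv) for (e in exposures_ms) for (f in filters) {
    i <- i + 1L
    out[[i]] <- scan_protocol(v, e, f, voxel_mm = voxel_mm,
                              noise_sd = noise_sd, seed = as.integer(seed + i),
                              label = paste("Scan", i))
  }
  out
}

#' Sensitivity summary of mean densities across protocols
#'
#' `sigma` is the sample standard deviation (n - 1 denominator) of the
#' per-scan mean densities; `six_sigma` is six times the unrounded sigma.
#'
#' @param means Numeric vector of per-scan mean densities (g/cc), length
#'   >= 2.
#' @return A list with `sigma` and `six_sigma` (g/cc).
#' @export
sensitivity_summary <- function(means) {
  means <- as.numeric(means)
  if (length(means) < 2L) stop("need >= 2 mean densities")
  s <- stats::sd(means)
  list(sigma = s, six_sigma = 6 * s)
}

#' Run the scan-parameter DOE on synthetic ground truth
#'
#' For each protocol: render the phantom and the femur under the same
#' protocol (independent noise streams), segment the phantom inserts, fit
#' the per-scan calibration line against the certified insert densities,
#' map the femur render to density, and take the bone-masked mean. The
#' bone mask comes from the ground-truth labels (`"truth"`) or from
#' [watershed_bone_segmentation()] (`"watershed"`).
#'
#' @param grid List of [scan_protocol()]s (e.g. [doe_grid()]).
#' @param phantom_gt Phantom [ground_truth()] (fixed across protocols).
#' @param femur_gt Femur [ground_truth()] (fixed across protocols).
#' @param spec The [phantom_spec()] used to build `phantom_gt`.
#' @param bone_mask One of `"truth"`, `"watershed"`.
#' @param model A [scan_model()].
#' @return An object of class `doe_result`: `table` (one row per protocol
#'   with mean/variance of mapped bone density), `sigma`, `six_sigma`.
#' @export
run_doe <- function(grid, phantom_gt, femur_gt, spec,
                    bone_mask = c("truth", "watershed"),
                    model = scan_model()) {
  bone_mask <- match.arg(bone_mask)
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    p <- grid[[i]]
    ph_scan <- render_scan(phantom_gt, p, model)
    fe_p <- p
    fe_p$seed <- p$seed + 10000L           # independent femur noise stream
    fe_scan <- render_scan(femur_gt, fe_p, model)
    labs <- segment_inserts(ph_scan, spec)
    ins <- mean_intensity_per_label(ph_scan, labs)
    k <- ins$label - tissue_labels$insert_base
    line <- fit_calibration(ins$mean, spec$densities[k])
    dens <- map_density(fe_scan, line)
    mask <- if (bone_mask == "truth") {
      femur_gt$labels$voxels %in% bone_labels()
    } else {
      watershed_bone_segmentation(fe_scan)$voxels != 0
    }
    v <- dens$voxels[mask]
    rows[[i]] <- data.frame(scan = if (is.null(p$label)) paste("Scan", i)
                            else p$label,
                            voltage_kv = p$voltage_kv,
                            exposure_ms = p$exposure_ms,
                            filter = p$filter,
                            mean_density = mean(v),
                            variance = stats::var(v),
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  s <- sensitivity_summary(tab$mean_density)
  structure(list(table = tab, sigma = s$sigma, six_sigma = s$six_sigma),
            class = "doe_result")
}

#' @export
print.doe_result <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("sigma = %.4g g/cc, 6 sigma = %.4g g/cc\n", x$sigma,
              x$six_sigma))
  invisible(x)
}

#' One-way analysis of variance across groups
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F test) as
#' provided by [stats::oneway.test()].
#'
#' @param groups A list of numeric samples (>= 2 groups, each n >= 2).
#' @return An object of class `anova_result`: `f`, `p`, `df_between`,
#'   `df_within`, `group_means`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need >= 2 groups")
  n <- lengths(groups)
  if (any(n < 2L)) stop("every group needs n >= 2")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), times = n))
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  structure(list(f = unname(ft$statistic), p = unname(ft$p.value),
                 df_between = unname(ft$parameter[1]),
                 df_within = unname(ft$parameter[2]),
                 group_means = vapply(groups, mean, numeric(1))),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%g, %g) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f, x$p))
  invisible(x)
}

#' Stage-change report across surgical stages
#'
#' Per-zone changes (last stage minus first stage) in bone-masked and
#' whole-ROI mean density (g/cc) and in BV/TV (percentage points), plus an
#' optional interface-shell BV/TV change and min/max/mean across zones.
#' Zones empty in either stage are flagged and excluded from the summary
#' statistics.
#'
#' @param summaries Named list (>= 2) of [zone_density_summary()] tables in
#'   stage order.
#' @param shell_bvtv Optional numeric vector of interface-shell BV/TV per
#'   stage (same order/names).
#' @return An object of class `stage_change_report`: `zones` (per-zone
#'   deltas), `summary` (min/max/mean rows), `shell_delta_pp`.
#' @export
stage_change_report <- function(summaries, shell_bvtv = NULL) {
  if (!is.list(summaries) || length(summaries) < 2L)
    stop("need summaries for >= 2 stages")
  first <- summaries[[1]]
  last <- summaries[[length(summaries)]]
  zones <- merge(first, last, by = "zone", suffixes = c("_pre", "_post"))
  zones <- zones[order(zones$zone), ]
  zones$delta_density_bone <- zones$mean_density_bone_post -
    zones$mean_density_bone_pre
  zones$delta_density_roi <- zones$mean_density_roi_post -
    zones$mean_density_roi_pre
  zones$delta_bvtv_pp <- 100 * (zones$bvtv_post - zones$bvtv_pre)
  zones$excluded <- zones$empty_pre | zones$empty_post
  ok <- !zones$excluded
  smry <- data.frame(
    quantity = c("delta_density_roi", "delta_bvtv_pp"),
    min = c(min(zones$delta_density_roi[ok]), min(zones$delta_bvtv_pp[ok])),
    max = c(max(zones$delta_density_roi[ok]), max(zones$delta_bvtv_pp[ok])),
    mean = c(mean(zones$delta_density_roi[ok]), mean(zones$delta_bvtv_pp[ok])))
  shell_delta <- if (!is.null(shell_bvtv))
    100 * (shell_bvtv[length(shell_bvtv)] - shell_bvtv[1]) else NA_real_
  structure(list(zones = zones, summary = smry,
                 shell_delta_pp = shell_delta),
            class = "stage_change_report")
}

#' @export
print.stage_change_report <- function(x, ...) {
  cols <- c("zone", "delta_density_bone", "delta_density_roi",
            "delta_bvtv_pp", "excluded")
  print(x$zones[, cols], row.names = FALSE)
  if (!is.na(x$shell_delta_pp))
    cat(sprintf("interface shell BV/TV change: %+.2f pp\n", x$shell_delta_pp))
  invisible(x)
}
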