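#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: which preservation
#' groups to simulate and at what sample size, the master seed, the
#' acquisition optics, compression protocol, phase-processing
#' parameters, the response-surface resolution and the output
#' directory.
#'
#' @param groups Character vector of condition names.
#' @param n_per_group Lenses per group (recycled), >= 1; `NULL` uses
#'   each preset's study sample size.
#' @param seed Master integer seed; per-lens seeds are derived from it.
#' @param asu_um,n_x,n_frames Acquisition settings; depth range is sized
#'   per group with [optics_for_geometry()].
#' @param protocol A [compression_protocol()].
#' @param params A [processing_params()].
#' @param design_max_levels Levels kept per design factor for the
#'   inverse fit (see [coarsen_design()]); `NULL` = full grids.
#' @param design_ranges Factorial ranges passed to [build_factorial()]:
#'   `"screening"` (default; ranges adapted to the quasi-1D forward
#'   model) or `"table"` (published grids).
#' @param force_noise_sd_gf,decorrelation_sd_rad Generator noise levels.
#' @param fit Run the inverse identification per group.
#' @param out_dir Output directory for CSV/JSON artefacts (`NULL` = no
#'   files written).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(groups = c("fresh", "frozen80", "frozen20"),
                            n_per_group = 3L, seed = 1L,
                            asu_um = 9.5, n_x = 8L, n_frames = 160L,
                            protocol = compression_protocol(hold_s = 60),
                            params = processing_params(),
                            design_max_levels = c(2L, 4L, 4L, 3L),
                            design_ranges = "screening",
                            force_noise_sd_gf = 0.2,
                            decorrelation_sd_rad = 0,
                            fit = TRUE, out_dir = NULL) {
  stopifnot(length(groups) >= 1, seed == as.integer(seed))
  if (is.null(n_per_group))
    n_per_group <- vapply(groups, function(g) make_group_preset(g)$n_samples, 0L)
  structure(list(groups = groups,
                 n_per_group = rep_len(as.integer(n_per_group), length(groups)),
                 seed = as.integer(seed), asu_um = asu_um,
                 n_x = as.integer(n_x), n_frames = as.integer(n_frames),
                 protocol = protocol, params = params,
                 design_max_levels = design_max_levels,
                 design_ranges = design_ranges,
                 force_noise_sd_gf = force_noise_sd_gf,
                 decorrelation_sd_rad = decorrelation_sd_rad,
                 fit = fit, out_dir = out_dir),
            class = "pipeline_config")
}

# force at the end of the relaxation hold, read off a (noisy) trace
.min_force_from_trace <- function(trace, protocol) {
  t_end <- protocol$ramp_s + protocol$hold_s
  trace$force_gf[which.min(abs(trace$time_s - t_end))]
}

#' Run the full synthetic study
#'
#' For every configured group: draws lenses around the preset centre,
#' forward-simulates the compression test, renders speckle stacks,
#' recovers strain with the phase-sensitive estimator, summarises the
#' oscillation per lens, and (optionally) identifies the group's
#' material parameters on a response surface calibrated by the
#' group-mean relaxed force. Group statistics follow: normality-gated
#' pairwise comparisons with Bonferroni correction for every metric,
#' plus the thickness-force rank correlation. Fully reproducible from
#' the config seed.
#'
#' @param config A [pipeline_config()].
#' @param progress Print per-stage progress to stderr.
#' @return A list of class `pipeline_report`: `lens_metrics` (one row
#'   per lens), `group_summaries`, `fits` (per group, when `config$fit`),
#'   `stats` (per metric `stats_table`s), `correlations`, and `config`.
#' @export
run_pipeline <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (progress) message(sprintf(...))
  metrics <- NULL
  surfaces <- list()
  fits <- list()

  for (gi in seq_along(config$groups)) {
    gname <- config$groups[gi]
    preset <- make_group_preset(gname)
    n <- config$n_per_group[gi]
    geom0 <- lens_geometry(lt0_mm = preset$lt0_mm,
                           lt_test_mm = preset$lt_test_mm,
                           capsule_um = preset$capsule_um)
    optics <- optics_for_geometry(geom0, n_x = config$n_x,
                                  n_frames = config$n_frames,
                                  asu_um = config$asu_um)
    say("group %s: %d lenses, %d x %d px stacks", gname, n,
        optics$n_z, optics$n_x)
    for (i in seq_len(n)) {
      lens_seed <- config$seed + 7919L * gi + i
      ds <- synth_lens_dataset(preset, lens_seed, optics = optics,
                               protocol = config$protocol,
                               force_noise_sd_gf = config$force_noise_sd_gf,
                               decorrelation_sd_rad = config$decorrelation_sd_rad)
      oce <- oce_process(ds$stack, config$params,
                         drive_freq_hz = config$protocol$drive_freq_hz)
      s <- oce$summary
      metrics <- rbind(metrics, data.frame(
        group = gname, lens = i, seed = lens_seed,
        lt0_mm = ds$truth$geom$lt0_mm,
        amp_ant = s$amp_ant_permille, amp_post = s$amp_post_permille,
        amp_nuc = s$amp_nuc_permille,
        amp_cort = mean(c(s$amp_ant_permille, s$amp_post_permille)),
        strain_ratio = s$strain_ratio_cortex_nucleus,
        delay_ms = s$delay_nuc_ms,
        max_force_gf = max(ds$force$force_gf),
        min_force_gf = .min_force_from_trace(ds$force, config$protocol),
        stringsAsFactors = FALSE))
    }

    if (config$fit) {
      key <- .condition_key(gname)
      if (is.null(surfaces[[key]])) {
        design <- build_factorial(gname, ranges = config$design_ranges)
        if (!is.null(config$design_max_levels))
          design <- coarsen_design(design, config$design_max_levels)
        say("building response surface '%s' (%d rows)", key,
            nrow(design$combos))
        surfaces[[key]] <- run_design(design, config$protocol, geom0)
      }
      gm <- metrics[metrics$group == gname, ]
      obs <- observed_summary(mean(gm$amp_ant), mean(gm$amp_post),
                              mean(gm$amp_nuc),
                              mean(gm$delay_ms, na.rm = TRUE),
                              mean(gm$min_force_gf))
      scale <- c(stats::sd(gm$amp_ant), stats::sd(gm$amp_post),
                 stats::sd(gm$amp_nuc), stats::sd(gm$delay_ms, na.rm = TRUE))
      if (any(!is.finite(scale) | scale <= 0)) scale <- NULL
      fit <- optimize_fit(surfaces[[key]], obs, scale = scale)
      fit <- calibrate_scale(fit, obs$min_force_gf, geom0, config$protocol)
      fit$condition <- gname   # surfaces are shared across design keys
      fits[[gname]] <- fit
      say("fitted %s: E-ratio %.2f, tau1 %.2f s, SSE %.3g", gname,
          fit$e_ratio_nuc_cortex, fit$tau1_s, fit$sse)
    }
  }

  metric_cols <- c("amp_cort", "amp_nuc", "strain_ratio", "delay_ms",
                   "max_force_gf", "min_force_gf")
  stats_tables <- list()
  if (length(config$groups) >= 2 && all(config$n_per_group >= 3)) {
    for (mc in metric_cols) {
      byg <- split(metrics[[mc]], factor(metrics$group,
                                         levels = config$groups))
      byg <- lapply(byg, function(v) v[is.finite(v)])
      if (all(vapply(byg, length, 0L) >= 3))
        stats_tables[[mc]] <- compare_groups(byg)
    }
  }
  correlations <- list(
    thickness_vs_max_force = correlate_metrics(metrics$lt0_mm,
                                               metrics$max_force_gf),
    thickness_vs_min_force = correlate_metrics(metrics$lt0_mm,
                                               metrics$min_force_gf))

  group_summaries <- do.call(rbind, lapply(split(metrics, metrics$group),
    function(d) data.frame(
      group = d$group[1], n = nrow(d),
      amp_cort = mean(d$amp_cort), amp_nuc = mean(d$amp_nuc),
      strain_ratio = mean(d$strain_ratio),
      delay_ms = mean(d$delay_ms, na.rm = TRUE),
      max_force_gf = mean(d$max_force_gf),
      min_force_gf = mean(d$min_force_gf),
      stringsAsFactors = FALSE)))
  group_summaries <- group_summaries[match(config$groups,
                                           group_summaries$group), ]

  report <- structure(list(lens_metrics = metrics,
                           group_summaries = group_summaries,
                           fits = fits, stats = stats_tables,
                           correlations = correlations,
                           config = config),
                      class = "pipeline_report")
  if (!is.null(config$out_dir)) .write_report(report, config$out_dir)
  report
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$lens_metrics,
                   file.path(out_dir, "lens_metrics.csv"), row.names = FALSE)
  utils::write.csv(report$group_summaries,
                   file.path(out_dir, "group_summaries.csv"),
                   row.names = FALSE)
  for (mc in names(report$stats))
    utils::write.csv(report$stats[[mc]]$pairwise,
                     file.path(out_dir, paste0("pairwise_", mc, ".csv")),
                     row.names = FALSE)
  fits <- lapply(report$fits, function(f)
    unclass(f)[c("condition", "thickness_mm", "tau1_s", "form_factor_f",
                 "n_stiffness", "ratio_ant", "ratio_post",
                 "e_ratio_nuc_cortex", "sse", "c10_nuc_inf_abs_kpa",
                 "at_boundary")])
  jsonlite::write_json(list(seed = report$config$seed, fits = fits,
                            correlations = report$correlations),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Synthetic lens study:\n")
  print(x$group_summaries, row.names = FALSE)
  for (g in names(x$fits)) print(x$fits[[g]])
  invisible(x)
}
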