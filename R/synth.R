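#' B-scan stack container
#'
#' A sequence of complex-valued OCT B-scans (depth x lateral) acquired at
#' a fixed location, with the acquisition optics and provenance attached.
#'
#' @param frames Complex array `n_z x n_x x n_frames`.
#' @param optics An [optics_config()] matching the array dimensions.
#' @param provenance Free-form list (e.g. generator seed and preset).
#' @return An object of class `bscan_stack`.
#' @export
bscan_stack <- function(frames, optics, provenance = list()) {
  stopifnot(is.array(frames), length(dim(frames)) == 3, is.complex(frames))
  d <- dim(frames)
  if (d[3] != optics$n_frames || d[1] != optics$n_z || d[2] != optics$n_x)
    stop("frame array dimensions do not match the optics configuration")
  structure(list(frames = frames, optics = optics, provenance = provenance),
            class = "bscan_stack")
}

#' @export
print.bscan_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("B-scan stack: %d frames of %d x %d px at %g Hz\n",
              d[3], d[1], d[2], x$optics$frame_rate_hz))
  invisible(x)
}

#' Force trace container
#'
#' @param times_s Sample times in seconds, strictly increasing.
#' @param force_gf Force in gram-force (1 gf = 9.8 mN), compression
#'   positive.
#' @return An object of class `force_trace` (data frame `time_s`,
#'   `force_gf` with attribute `conversion_mN_per_gf = 9.8`).
#' @export
force_trace <- function(times_s, force_gf) {
  stopifnot(length(times_s) == length(force_gf),
            all(is.finite(times_s)), all(is.finite(force_gf)),
            all(diff(times_s) > 0))
  structure(data.frame(time_s = times_s, force_gf = force_gf),
            conversion_mN_per_gf = 9.8,
            class = c("force_trace", "data.frame"))
}

.preset_table <- function() {
  list(
    fresh    = list(n_samples = 12L, lt0_mm = 8.06, lt_test_mm = 5.4,
                    capsule_um = 60, c10 = 1.09, tau1 = 1.00, f = 1.00,
                    n = 0.92, design = "fresh"),
    "de-cap" = list(n_samples = 21L, lt0_mm = 6.60, lt_test_mm = 4.4,
                    capsule_um = 0, c10 = 1.72, tau1 = 0.90, f = 1.10,
                    n = 1.00, design = "de-cap"),
    fridge8  = list(n_samples = 12L, lt0_mm = 8.06, lt_test_mm = 5.4,
                    capsule_um = 60, c10 = 1.19, tau1 = 0.95, f = 1.02,
                    n = 0.95, design = "fresh"),
    MEM8     = list(n_samples = 12L, lt0_mm = 8.91, lt_test_mm = 5.4,
                    capsule_um = 60, c10 = 1.98, tau1 = 0.80, f = 1.03,
                    n = 0.95, design = "MEM8"),
    frozen20 = list(n_samples = 12L, lt0_mm = 9.33, lt_test_mm = 5.4,
                    capsule_um = 60, c10 = 2.37, tau1 = 0.30, f = 1.30,
                    n = 1.00, design = "frozen"),
    frozen80 = list(n_samples = 12L, lt0_mm = 8.75, lt_test_mm = 5.4,
                    capsule_um = 60, c10 = 2.16, tau1 = 0.32, f = 1.10,
                    n = 0.95, design = "frozen")
  )
}

#' Group preset for one preservation condition
#'
#' Returns the generator preset for one of the six experimental
#' conditions (fresh, de-cap, fridge8, MEM8, frozen20, frozen80):
#' sample size, undeformed-thickness centre, material-model centre,
#' between-sample spread and region reflectivities. Centres are chosen
#' so that the forward-simulated observables reproduce the group-level
#' directionality (frozen20 most altered, fridge8 closest to fresh).
#'
#' @param name Condition name.
#' @return An object of class `group_preset`.
#' @export
make_group_preset <- function(name) {
  tbl <- .preset_table()
  if (!name %in% names(tbl))
    stop("unknown condition '", name, "'; valid names: ",
         paste(names(tbl), collapse = ", "))
  p <- tbl[[name]]
  structure(list(
    name = name,
    n_samples = p$n_samples,
    lt0_mm = p$lt0_mm,
    lt_test_mm = p$lt_test_mm,
    capsule_um = p$capsule_um,
    material_center = material_model(c10_nuc_inf_kpa = p$c10,
                                     tau1_s = p$tau1,
                                     form_factor_f = p$f,
                                     n_stiffness = p$n),
    between_sample_cv = 0.04,
    intensity_profile = c(cortex = 1.0, nucleus = 0.60, background = 0.02),
    design_condition = p$design
  ), class = "group_preset")
}

#' @export
print.group_preset <- function(x, ...) {
  cat(sprintf(
    "Preset '%s': n = %d, LT0 %.2f mm -> LT_test %.2f mm, capsule %g um\n",
    x$name, x$n_samples, x$lt0_mm, x$lt_test_mm, x$capsule_um))
  print(x$material_center)
  invisible(x)
}

#' Draw one lens from a group preset
#'
#' Samples per-lens geometry and material parameters around the preset
#' centre: the undeformed thickness is normal with relative spread
#' `between_sample_cv`; moduli, relaxation time and the stiffness-shape
#' factors are log-normal with the same log-scale spread, guaranteeing
#' positivity. Deterministic for a fixed seed.
#'
#' @param preset A [make_group_preset()] result.
#' @param seed Integer RNG seed.
#' @param nucleus_fraction Axial nucleus fraction passed to the geometry.
#' @return A list with `geom` ([lens_geometry()]) and `mat`
#'   ([material_model()]).
#' @export
sample_lens <- function(preset, seed, nucleus_fraction = 0.55) {
  stopifnot(inherits(preset, "group_preset"), preset$between_sample_cv >= 0)
  set.seed(as.integer(seed))
  cv <- preset$between_sample_cv
  mc <- preset$material_center
  lt0 <- preset$lt0_mm * (1 + cv * stats::rnorm(1))
  draw <- function(center) center * exp(cv * stats::rnorm(1))
  mat <- material_model(
    c10_nuc_inf_kpa = draw(mc$c10_nuc_inf_kpa),
    g1 = mc$g1,
    tau1_s = draw(mc$tau1_s),
    form_factor_f = draw(mc$form_factor_f),
    n_stiffness = draw(mc$n_stiffness),
    c10_capsule_mpa = mc$c10_capsule_mpa,
    eq4_variant = mc$eq4_variant)
  geom <- lens_geometry(lt0_mm = lt0, lt_test_mm = preset$lt_test_mm,
                        capsule_um = preset$capsule_um,
                        nucleus_fraction = nucleus_fraction)
  list(geom = geom, mat = mat)
}

#' Render a speckle B-scan stack from prescribed displacements
#'
#' Simulates fully developed speckle (complex circular Gaussian field per
#' pixel, variance set by the per-depth mean reflectivity) and encodes a
#' prescribed axial displacement history into the interframe phase:
#' `phi = 4 pi n(z) ddz / wavelength`. The expected interframe
#' correlation angle at every pixel then equals `phi`, inverting the
#' phase-sensitive estimator exactly in expectation.
#'
#' @param displacement_series Interframe axial displacements in nm:
#'   array `n_z x n_x x (n_frames - 1)` or matrix `n_z x (n_frames - 1)`
#'   (replicated laterally). With `cumulative = TRUE`, `n_frames` time
#'   slices of cumulative displacement are expected instead and are
#'   differenced.
#' @param reflectivity Mean intensity per depth pixel (length `n_z`).
#' @param optics An [optics_config()].
#' @param seed Integer seed fixing the speckle realisation.
#' @param cumulative Whether `displacement_series` is cumulative.
#' @param speckle If `FALSE`, replace the random speckle field with a
#'   deterministic unit-phase field of amplitude `sqrt(reflectivity)`:
#'   an estimator oracle that isolates the phase processing from
#'   speckle statistics. Default `TRUE`.
#' @param decorrelation_sd_rad Optional multiplicative phase-noise SD in
#'   radians per pixel and frame (default 0), to stress-test the
#'   estimator.
#' @param check_wrap If `TRUE` (default), reject displacement histories
#'   whose interframe phase reaches pi anywhere: beyond that bound the
#'   displacement map (not the strain map) is ambiguous. Strain
#'   estimation only requires the axial phase *gradient* to stay below
#'   pi per pixel, which is always verified.
#' @param provenance Optional provenance list merged with the seed.
#' @return A [bscan_stack()].
#' @export
render_bscan_stack <- function(displacement_series, reflectivity, optics,
                               seed, cumulative = FALSE,
                               decorrelation_sd_rad = 0, check_wrap = TRUE,
                               speckle = TRUE, provenance = list()) {
  nz <- optics$n_z; nx <- optics$n_x; nf <- optics$n_frames
  ds <- displacement_series
  if (is.matrix(ds)) ds <- array(rep(ds, each = 1),
                                 dim = c(nrow(ds), 1L, ncol(ds)))
  if (dim(ds)[2] == 1L && nx > 1L)
    ds <- array(apply(ds, 3, function(m) matrix(m, nz, nx)),
                dim = c(nz, nx, dim(ds)[3]))
  if (cumulative) {
    stopifnot(dim(ds)[3] == nf)
    ds <- array(ds[, , -1, drop = FALSE] - ds[, , -nf, drop = FALSE],
                dim = c(nz, nx, nf - 1L))
  }
  stopifnot(dim(ds)[1] == nz, dim(ds)[2] == nx, dim(ds)[3] == nf - 1L)
  refl <- rep_len(as.numeric(reflectivity), nz)
  stopifnot(all(refl >= 0))

  phase <- 4 * pi * optics$n_of_z * ds / optics$wavelength_nm  # recycles n(z) over z
  if (check_wrap) {
    worst <- which.max(abs(phase))
    if (abs(phase[worst]) >= pi) {
      idx <- arrayInd(worst, dim(phase))
      stop(sprintf(
        "interframe phase exceeds the wrap limit at pixel (z=%d, x=%d, pair=%d): |%.3f| rad >= pi",
        idx[1], idx[2], idx[3], phase[worst]))
    }
  }
  grad <- abs(phase[-1, , , drop = FALSE] - phase[-nz, , , drop = FALSE])
  if (max(grad) >= pi)
    stop(sprintf(
      "axial phase gradient reaches %.3f rad/px (>= pi): strain exceeds the estimator validity bound",
      max(grad)))

  set.seed(as.integer(seed))
  base <- if (speckle) {
    matrix(complex(real = stats::rnorm(nz * nx),
                   imaginary = stats::rnorm(nz * nx)),
           nz, nx) * sqrt(refl / 2)
  } else {
    matrix(complex(real = sqrt(refl), imaginary = 0), nz, nx)
  }
  frames <- array(complex(real = 0), dim = c(nz, nx, nf))
  frames[, , 1] <- base
  cum_phase <- matrix(0, nz, nx)
  for (s in 2:nf) {
    cum_phase <- cum_phase + phase[, , s - 1L]
    fr <- base * exp(-1i * cum_phase)
    if (decorrelation_sd_rad > 0)
      fr <- fr * exp(1i * stats::rnorm(nz * nx, sd = decorrelation_sd_rad))
    frames[, , s] <- fr
  }
  bscan_stack(frames, optics,
              provenance = c(provenance, list(seed = seed,
                                              decorrelation_sd_rad = decorrelation_sd_rad)))
}

#' Noisy synthetic force trace
#'
#' Adds i.i.d. Gaussian noise to a model force series, in gram-force.
#'
#' @param force_series A [force_trace()] or data frame with `time_s` and
#'   `force_gf`.
#' @param noise_sd_gf Noise standard deviation in gf, >= 0.
#' @param seed Integer RNG seed.
#' @return A [force_trace()].
#' @export
synth_force_trace <- function(force_series, noise_sd_gf, seed) {
  stopifnot(noise_sd_gf >= 0)
  set.seed(as.integer(seed))
  f <- force_series$force_gf
  if (noise_sd_gf > 0) f <- f + stats::rnorm(length(f), sd = noise_sd_gf)
  force_trace(force_series$time_s, f)
}

#' Optics configuration sized to a lens geometry
#'
#' Convenience constructor: picks `n_z` so the compressed lens fits the
#' depth range with a top margin, keeping all other parameters.
#'
#' @param geom A [lens_geometry()] (or anything with `lt_test_mm`).
#' @param n_x,n_frames,asu_um,... Passed to [optics_config()].
#' @return An [optics_config()].
#' @export
optics_for_geometry <- function(geom, n_x = 8L, n_frames = 160L,
                                asu_um = 9.5, ...) {
  opt <- optics_config(n_x = n_x, n_frames = n_frames, asu_um = asu_um, ...)
  px_mm <- opt$asu_um * 1e-3 / mean(opt$n_of_z)
  n_z <- ceiling(geom$lt_test_mm / px_mm / 0.86)
  optics_config(n_x = n_x, n_frames = n_frames, asu_um = asu_um,
                n_z = n_z, ...)
}

# Per-pixel cumulative displacement (nm) over the oscillation frames,
# interpolated from the simulated layer-interface motion. Pixels above
# the lens are static; pixels below move with the bottom lamella.
.displacement_from_sim <- function(sim, optics, z_top_px) {
  n_if <- ncol(sim$interfaces_mm)
  ref <- sim$interfaces_ref_mm
  nz <- optics$n_z
  px_mm <- optics$asu_um * 1e-3 / optics$n_of_z  # physical pixel depth
  depth_mm <- cumsum(c(0, px_mm[-nz])) - sum(px_mm[seq_len(z_top_px - 1)])
  nf <- nrow(sim$interfaces_mm)
  u <- matrix(0, nz, nf)
  inside <- depth_mm >= 0 & depth_mm <= ref[n_if]
  below <- depth_mm > ref[n_if]
  for (s in seq_len(nf)) {
    du_if <- sim$interfaces_mm[s, ] - ref
    u[inside, s] <- stats::approx(ref, du_if, xout = depth_mm[inside])$y * 1e6
    u[below, s] <- du_if[n_if] * 1e6
  }
  u
}

#' Generate one complete synthetic lens acquisition
#'
#' Draws a lens from a preset, runs the forward compression model, and
#' renders the oscillation phase of the experiment into a speckle B-scan
#' stack plus a noisy force-relaxation trace. The protocol's solver step
#' and oscillation duration are locked to the stack's frame grid.
#'
#' @param preset A [make_group_preset()] result.
#' @param seed Integer seed (drives lens sampling, speckle and force
#'   noise through derived sub-seeds).
#' @param optics An [optics_config()]; its depth range must cover the
#'   compressed lens plus margins.
#' @param protocol A [compression_protocol()]; `dt_s` and `osc_s` are
#'   overridden to match the frame grid.
#' @param force_noise_sd_gf Force-trace noise SD in gf.
#' @param decorrelation_sd_rad Optional speckle phase noise (radians).
#' @param nucleus_fraction Nucleus fraction for the sampled geometry.
#' @return A list with `stack` ([bscan_stack()]), `force`
#'   ([force_trace()]) and `truth` (sampled `geom`, `mat`, the full
#'   `sim` output, the painted `mask_px` region boundaries and
#'   `nucleus_fraction_painted`).
#' @export
synth_lens_dataset <- function(preset, seed, optics = optics_config(),
                               protocol = compression_protocol(),
                               force_noise_sd_gf = 0.2,
                               decorrelation_sd_rad = 0,
                               nucleus_fraction = 0.55) {
  lens <- sample_lens(preset, seed, nucleus_fraction = nucleus_fraction)
  protocol$dt_s <- 1 / optics$frame_rate_hz
  protocol$osc_s <- optics$n_frames / optics$frame_rate_hz
  sim <- simulate_test(lens$geom, lens$mat, protocol, summary_fit = FALSE)

  # depth layout: lens top at a fixed margin below the image top
  n_mean <- mean(optics$n_of_z)
  lens_px <- lens$geom$lt_test_mm / (optics$asu_um * 1e-3 / n_mean)
  z_top_px <- max(2L, round(0.08 * optics$n_z))
  if (z_top_px + lens_px > 0.98 * optics$n_z)
    stop(sprintf(
      "depth range too small: compressed lens needs %.0f px of %d available",
      lens_px, optics$n_z))

  u <- .displacement_from_sim(sim, optics, z_top_px)

  # reflectivity: three plateaus following the compressed-configuration
  # region boundaries
  ref <- sim$interfaces_ref_mm
  reg <- sim$layers$region
  nuc_i <- which(reg == "nuc")
  nuc_top_mm <- ref[nuc_i]          # interface above nucleus
  nuc_bot_mm <- ref[nuc_i + 1L]
  lens_bot_mm <- ref[length(ref)]
  px_mm <- optics$asu_um * 1e-3 / n_mean
  depth_mm <- (seq_len(optics$n_z) - z_top_px) * px_mm
  ip <- preset$intensity_profile
  refl <- rep(ip[["background"]], optics$n_z)
  in_lens <- depth_mm >= 0 & depth_mm <= lens_bot_mm
  refl[in_lens] <- ip[["cortex"]]
  in_nuc <- depth_mm >= nuc_top_mm & depth_mm < nuc_bot_mm
  refl[in_nuc] <- ip[["nucleus"]]

  # absolute interframe phase wraps for realistic lamella strokes; the
  # strain estimate depends only on the axial phase gradient, which the
  # renderer still validates
  stack <- render_bscan_stack(
    array(u[, -1, drop = FALSE] - u[, -ncol(u), drop = FALSE],
          dim = c(optics$n_z, 1L, ncol(u) - 1L)),
    refl, optics, seed = seed + 1000003L,
    decorrelation_sd_rad = decorrelation_sd_rad, check_wrap = FALSE,
    provenance = list(preset = preset$name, lens_seed = seed))
  force <- synth_force_trace(sim$force_trace, force_noise_sd_gf,
                             seed = seed + 2000003L)

  mask_px <- c(lens_top = z_top_px,
               boundary_ant_nuc = z_top_px + round(nuc_top_mm / px_mm),
               boundary_nuc_post = z_top_px + round(nuc_bot_mm / px_mm),
               lens_bottom = z_top_px + round(lens_bot_mm / px_mm))
  list(stack = stack, force = force,
       truth = list(geom = lens$geom, mat = lens$mat, sim = sim,
                    mask_px = mask_px,
                    nucleus_fraction_painted =
                      (nuc_bot_mm - nuc_top_mm) / lens_bot_mm))
}
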