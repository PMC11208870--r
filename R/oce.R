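#' Phase-processing parameters
#'
#' Window sizes for the two complex cross-correlation passes and the
#' lateral averaging zone. Window arguments are half-sizes in pixels; a
#' half-size `w` spans `2 w + 1` pixels. Windows are truncated at image
#' borders (no padding).
#'
#' @param w_z,w_x Displacement (first-pass) window half-sizes in depth
#'   and lateral direction (10, 1).
#' @param v_z,v_x Strain (second-pass) window half-sizes (15, 1).
#' @param lateral_zone_mm Width of the lateral averaging zone, centred on
#'   the lens apex column (2.3 mm).
#' @return An object of class `processing_params`.
#' @export
processing_params <- function(w_z = 10, w_x = 1, v_z = 15, v_x = 1,
                              lateral_zone_mm = 2.3) {
  stopifnot(w_z >= 1, w_x >= 0, v_z >= 1, v_x >= 0, lateral_zone_mm > 0)
  structure(list(w_z = as.integer(w_z), w_x = as.integer(w_x),
                 v_z = as.integer(v_z), v_x = as.integer(v_x),
                 lateral_zone_mm = lateral_zone_mm),
            class = "processing_params")
}

# Boxcar (moving window) sum over a matrix with edge truncation.
# Half-sizes wz (rows) and wx (cols); works for complex input.
.boxcar_sum <- function(m, wz, wx) {
  nz <- nrow(m); nx <- ncol(m)
  if (wz > 0) {
    cs <- rbind(0, apply(m, 2, cumsum))
    hi <- pmin(nz, seq_len(nz) + wz) + 1L
    lo <- pmax(1L, seq_len(nz) - wz)
    m <- cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
  }
  if (wx > 0 && nx > 1) {
    cs <- cbind(0, t(apply(m, 1, cumsum)))
    hi <- pmin(nx, seq_len(nx) + wx) + 1L
    lo <- pmax(1L, seq_len(nx) - wx)
    m <- cs[, hi, drop = FALSE] - cs[, lo, drop = FALSE]
  }
  m
}

#' Interframe complex cross-correlation
#'
#' For each pair of consecutive B-scans computes the windowed complex
#' cross-correlation `R_s = sum_w B_s conj(B_{s+1})` over a
#' `(2 w_z + 1) x (2 w_x + 1)` window (truncated at borders). The angle
#' of `R_s` encodes the interframe axial displacement.
#'
#' @param stack A [bscan_stack()].
#' @param params A [processing_params()].
#' @return A complex array `n_z x n_x x (n_frames - 1)` of class
#'   `correlation_fields`, carrying the stack's optics as an attribute.
#' @export
interframe_xcorr <- function(stack, params = processing_params()) {
  stopifnot(inherits(stack, "bscan_stack"), inherits(params, "processing_params"))
  fr <- stack$frames
  d <- dim(fr)
  if (d[3] < 2) stop("need at least 2 frames")
  out <- array(complex(real = 0), dim = c(d[1], d[2], d[3] - 1L))
  for (s in seq_len(d[3] - 1L)) {
    out[, , s] <- .boxcar_sum(fr[, , s] * Conj(fr[, , s + 1L]),
                              params$w_z, params$w_x)
  }
  structure(out, optics = stack$optics, params = params,
            class = "correlation_fields")
}

#' Axial displacement from correlation phase
#'
#' Converts the cross-correlation angle into interframe axial
#' displacement, `dz = wavelength * angle(R) / (4 pi n(z))`, in
#' nanometres. Displacement depends on the refractive-index profile;
#' strain (see [strain_from_xcorr()]) does not.
#'
#' @param corr A `correlation_fields` array (or a single complex matrix).
#' @param optics An [optics_config()]; defaults to the optics attached to
#'   `corr`.
#' @return Numeric array of interframe displacements in nm, same
#'   dimensions as `corr`.
#' @export
displacement_from_phase <- function(corr, optics = attr(corr, "optics")) {
  if (is.null(optics)) stop("optics required")
  n_z <- if (is.matrix(corr)) nrow(corr) else dim(corr)[1]
  stopifnot(length(optics$n_of_z) >= n_z)
  optics$wavelength_nm * Arg(corr) / (4 * pi * optics$n_of_z[seq_len(n_z)])
}

#' Axial strain from a second cross-correlation
#'
#' Approximates the axial strain as the depth gradient of the interframe
#' phase: a second windowed complex cross-correlation between each
#' correlation field and its copy shifted by one pixel axially,
#' `eps_z = wavelength * angle(sum_v R(z+1) conj(R(z))) / (4 pi asu)`.
#' The refractive index cancels: the phase-per-pixel gradient scales with
#' n(z) while the physical pixel size scales with 1/n(z), so the output
#' depends only on the axial sampling unit in air. A positive phase
#' gradient with depth yields positive strain; compression is negative.
#'
#' @param corrs A `correlation_fields` array from [interframe_xcorr()].
#' @param params A [processing_params()].
#' @param optics An [optics_config()]; defaults to the attached optics.
#' @return Numeric array `(n_z - 1) x n_x x (n_frames - 1)` of class
#'   `strain_fields`, dimensionless strain per frame pair; row `z` is the
#'   gradient between depth pixels `z` and `z + 1`.
#' @export
strain_from_xcorr <- function(corrs, params = attr(corrs, "params"),
                              optics = attr(corrs, "optics")) {
  if (is.null(params)) params <- processing_params()
  if (is.null(optics)) stop("optics required")
  d <- dim(corrs)
  if (d[1] < 2 * params$v_z + 2)
    stop("depth extent smaller than the strain processing window")
  out <- array(NA_real_, dim = c(d[1] - 1L, d[2], d[3]))
  cplx <- array(complex(real = 0), dim = dim(out))
  scale <- optics$wavelength_nm / (4 * pi * optics$asu_um * 1e3)
  for (s in seq_len(d[3])) {
    p <- corrs[2:d[1], , s, drop = FALSE] *
      Conj(corrs[1:(d[1] - 1L), , s, drop = FALSE])
    p <- .boxcar_sum(array(p, dim = c(d[1] - 1L, d[2])),
                     params$v_z, params$v_x)
    cplx[, , s] <- p
    out[, , s] <- scale * Arg(p)
  }
  structure(out, optics = optics, params = params, complex = cplx,
            class = "strain_fields")
}

#' Segment cortical and nuclear regions from a reflectivity profile
#'
#' Identifies the lens span in a mean depth-intensity profile and splits
#' its interior into anterior cortex, nucleus and posterior cortex by an
#' exhaustive three-plateau (piecewise-constant) least-squares fit, the
#' nucleus being the middle plateau. Deterministic for a fixed profile.
#'
#' @param structural_intensity Numeric vector: mean intensity per depth
#'   pixel (averaged over frames and the lateral zone).
#' @param optics An [optics_config()] (supplies lateral geometry for the
#'   averaging zone).
#' @param params A [processing_params()].
#' @return An object of class `region_mask`: list with `lens_top`,
#'   `boundary_ant_nuc`, `boundary_nuc_post`, `lens_bottom` (depth-pixel
#'   indices, strictly increasing) and `lateral_zone` (column indices).
#' @export
segment_regions <- function(structural_intensity, optics,
                            params = processing_params()) {
  prof_raw <- as.numeric(structural_intensity)
  nz <- length(prof_raw)
  rng <- range(prof_raw)
  if (!all(is.finite(rng)) || diff(rng) <= 1e-9 * max(abs(rng), 1e-300))
    stop("no detectable lens: flat intensity profile")
  # speckle intensity is exponential-distributed per pixel: smooth before
  # detecting the lens span and plateaus
  k <- min(7L, max(1L, 2L * (nz %/% 30L) + 1L))
  prof <- as.numeric(stats::filter(prof_raw, rep(1 / k, k), sides = 2))
  na <- is.na(prof)
  prof[na] <- prof_raw[na]
  q <- stats::quantile(prof, c(0.1, 0.95), names = FALSE)
  th <- q[1] + 0.25 * (q[2] - q[1])
  above <- prof > th
  # close short speckle-induced gaps inside the lens span
  gap <- max(5L, nz %/% 40L)
  r0 <- rle(above)
  fill <- !r0$values & r0$lengths <= gap
  if (any(fill)) {
    r0$values[fill] <- TRUE
    above <- inverse.rle(r0)
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (length(runs) == 0) stop("no detectable lens: no pixels above threshold")
  main <- runs[which.max(r$lengths[runs])]
  a <- starts[main]; b <- ends[main]
  m <- b - a + 1L
  if (m < 12L) stop("no detectable lens: span too short (", m, " px)")

  # exhaustive 3-plateau fit inside [a, b]; trim the smoothing ramps at
  # the span edges so they cannot masquerade as plateau steps
  trim <- min(k, (m - 12L) %/% 2)
  a_fit <- a + trim; b_fit <- b - trim
  x <- prof[a_fit:b_fit]
  m <- length(x)
  minlen <- max(3L, round(0.08 * m))
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  seg_sse <- function(i, j) {  # sse of x[i..j], vectorised over j
    n <- j - i + 1
    s <- cs[j] - c(0, cs)[i]
    s2 <- cs2[j] - c(0, cs2)[i]
    s2 - s^2 / n
  }
  best <- c(Inf, NA, NA)
  for (i in seq(minlen, m - 2L * minlen)) {     # last index of segment 1
    j <- seq(i + minlen, m - minlen)            # last index of segment 2
    sse <- seg_sse(1L, i) + seg_sse(i + 1L, j) + seg_sse(j + 1L, m)
    k <- which.min(sse)
    if (sse[k] < best[1]) best <- c(sse[k], i, j[k])
  }
  i <- best[2]; j <- best[3]
  m1 <- mean(x[1:i]); m2 <- mean(x[(i + 1):j]); m3 <- mean(x[(j + 1):m])
  level <- mean(x)
  if (abs(m2 - (m1 + m3) / 2) < 0.02 * level)
    stop("no detectable contrast between nucleus and cortex")

  zone_px <- max(1L, round(params$lateral_zone_mm * 1000 /
                             optics$lateral_sampling_um))
  mid <- ceiling(optics$n_x / 2)
  half <- (zone_px - 1) %/% 2
  zone <- max(1L, mid - half):min(optics$n_x, mid + half)

  structure(list(lens_top = a,
                 boundary_ant_nuc = a_fit + i,   # first pixel of nucleus
                 boundary_nuc_post = a_fit + j,  # first pixel of posterior cortex
                 lens_bottom = b,
                 lateral_zone = zone),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf(
    "Region mask: lens %d-%d px, nucleus %d-%d px, lateral zone %d columns\n",
    x$lens_top, x$lens_bottom, x$boundary_ant_nuc, x$boundary_nuc_post - 1L,
    length(x$lateral_zone)))
  invisible(x)
}

#' Per-region strain time series
#'
#' Averages each frame-pair strain field over the lateral zone and over
#' the depth extent of the anterior cortex, nucleus and posterior cortex.
#'
#' @param strains A `strain_fields` array from [strain_from_xcorr()].
#' @param mask A `region_mask` from [segment_regions()].
#' @param params A [processing_params()].
#' @param erode_px Pixels trimmed from each region boundary before
#'   averaging, to exclude depths where the two correlation windows mix
#'   adjacent regions. Defaults to `w_z + v_z`; regions are never eroded
#'   below 3 pixels.
#' @return A data frame of class `region_strain_series` with columns
#'   `time_s`, `eps_ant`, `eps_nuc`, `eps_post` (incremental strain per
#'   frame pair, in permille).
#' @export
region_series <- function(strains, mask, params = attr(strains, "params"),
                          erode_px = NULL) {
  optics <- attr(strains, "optics")
  if (is.null(params)) params <- processing_params()
  if (is.null(erode_px)) erode_px <- params$w_z + params$v_z
  d <- dim(strains)
  if (!(mask$lens_top < mask$boundary_ant_nuc &&
        mask$boundary_ant_nuc < mask$boundary_nuc_post &&
        mask$boundary_nuc_post < mask$lens_bottom))
    stop("empty region: mask boundaries must be strictly increasing")
  rows <- list(ant = mask$lens_top:(mask$boundary_ant_nuc - 1L),
               nuc = mask$boundary_ant_nuc:(mask$boundary_nuc_post - 1L),
               post = mask$boundary_nuc_post:min(mask$lens_bottom, d[1]))
  cols <- mask$lateral_zone[mask$lateral_zone <= d[2]]
  for (r in names(rows)) {
    rr <- rows[[r]]
    e <- min(erode_px, max(0L, (length(rr) - 3L) %/% 2L))
    if (e > 0) rr <- rr[(e + 1L):(length(rr) - e)]
    rr <- rr[rr >= 1 & rr <= d[1]]
    if (length(rr) == 0) stop("empty region: ", r)
    rows[[r]] <- rr
  }
  if (length(cols) == 0) stop("empty lateral zone")
  # with the complex second-correlation field available, use the
  # magnitude-weighted circular mean over the region: low-SNR speckle
  # pixels (|S| ~ 0) then barely contribute, instead of injecting
  # uniformly distributed phase noise into the plain average
  cplx <- attr(strains, "complex")
  optics_scale <- if (!is.null(optics))
    optics$wavelength_nm / (4 * pi * optics$asu_um * 1e3) else NA_real_
  mean_rs <- function(rr) {
    if (!is.null(cplx) && is.finite(optics_scale)) {
      1000 * optics_scale * vapply(seq_len(d[3]), function(s)
        Arg(sum(cplx[rr, cols, s])), 0)
    } else {
      1000 * vapply(seq_len(d[3]), function(s)
        mean(strains[rr, cols, s]), 0)
    }
  }
  fps <- if (!is.null(optics)) optics$frame_rate_hz else 1
  out <- data.frame(time_s = seq_len(d[3]) / fps,
                    eps_ant = mean_rs(rows$ant),
                    eps_nuc = mean_rs(rows$nuc),
                    eps_post = mean_rs(rows$post))
  class(out) <- c("region_strain_series", "data.frame")
  out
}

# Least-squares sinusoid fit at a known frequency; returns amplitude and
# phase of y ~ A cos(w t - phi) after removing intercept and linear drift.
.sinfit <- function(t, y, freq) {
  w <- 2 * pi * freq
  X <- cbind(1, t, cos(w * t), sin(w * t))
  cf <- stats::lm.fit(X, y)$coefficients
  a <- cf[3]; b <- cf[4]
  list(amp = sqrt(a^2 + b^2), phase = atan2(b, a))
}

.wrap_pi <- function(x) atan2(sin(x), cos(x))

#' Oscillation amplitudes and nucleus delay
#'
#' Fits a sinusoid at the known drive frequency to each region's strain
#' series (least squares, with intercept and linear-drift terms) and
#' summarises the oscillation: amplitudes in permille, the nucleus phase
#' delay relative to the cortex in milliseconds, and the cortical:nuclear
#' amplitude ratio. Incremental (per-frame-pair) series are integrated by
#' cumulative summation before fitting so amplitudes refer to the
#' physical strain oscillation. The cortex phase is the circular mean of
#' the anterior and posterior phases; a negative delay means the nucleus
#' lags the cortex.
#'
#' @param series A `region_strain_series` data frame.
#' @param drive_freq_hz Drive frequency in Hz.
#' @param frame_rate_hz Sampling rate; only used when `series` lacks a
#'   `time_s` column.
#' @param cumulative If `FALSE` (default, the OCE case) the series are
#'   incremental and are cumulated before fitting; `TRUE` for series
#'   already referenced to a fixed configuration (forward-model output).
#' @return An object of class `oscillation_summary`: list with
#'   `amp_ant_permille`, `amp_post_permille`, `amp_nuc_permille`,
#'   `delay_nuc_ms` (NA when undefined), `delay_defined`,
#'   `strain_ratio_cortex_nucleus` and `drive_freq_hz`.
#' @export
amplitude_and_delay <- function(series, drive_freq_hz,
                                frame_rate_hz = NULL, cumulative = FALSE) {
  t <- if (!is.null(series$time_s)) series$time_s
       else seq_len(nrow(series)) / frame_rate_hz
  if (diff(range(t)) < 2 / drive_freq_hz)
    stop("series shorter than 2 periods of the drive frequency")
  prep <- function(y) if (cumulative) y else cumsum(y)
  fits <- lapply(list(ant = series$eps_ant, nuc = series$eps_nuc,
                      post = series$eps_post),
                 function(y) .sinfit(t, prep(y), drive_freq_hz))
  amps <- vapply(fits, `[[`, 0, "amp")
  amp_tol <- 1e-9 * max(amps, 1e-12)
  delay_defined <- all(amps > amp_tol) && max(amps) > 0
  if (delay_defined) {
    ph_cort <- atan2(mean(sin(c(fits$ant$phase, fits$post$phase))),
                     mean(cos(c(fits$ant$phase, fits$post$phase))))
    dphi <- .wrap_pi(fits$nuc$phase - ph_cort)
    # phase convention y = A cos(w t - phi): a lagging nucleus has a
    # larger phi; report lag as negative delay
    delay_ms <- unname(-1000 * dphi / (2 * pi * drive_freq_hz))
  } else delay_ms <- NA_real_
  structure(list(
    amp_ant_permille = unname(amps["ant"]),
    amp_post_permille = unname(amps["post"]),
    amp_nuc_permille = unname(amps["nuc"]),
    delay_nuc_ms = delay_ms,
    delay_defined = delay_defined,
    strain_ratio_cortex_nucleus =
      mean(amps[c("ant", "post")]) / amps[["nuc"]],
    drive_freq_hz = drive_freq_hz
  ), class = "oscillation_summary")
}

#' @export
print.oscillation_summary <- function(x, ...) {
  cat(sprintf(
    "Oscillation: amp ant %.3g / nuc %.3g / post %.3g permille, ratio %.3g, delay %s\n",
    x$amp_ant_permille, x$amp_nuc_permille, x$amp_post_permille,
    x$strain_ratio_cortex_nucleus,
    if (isTRUE(x$delay_defined)) sprintf("%.1f ms", x$delay_nuc_ms)
    else "undefined"))
  invisible(x)
}

#' Macroscopic compression consistency check
#'
#' Compares the OCE-measured compression, averaged across the full lens
#' thickness, against the macroscopic compression imposed by the
#' actuator: half the peak-to-peak excursion of the (detrended,
#' cumulated) full-lens mean strain versus `(stroke/2) / LT_test`.
#'
#' @param strains A `strain_fields` array.
#' @param mask A full-lens `region_mask`.
#' @param stroke_um Peak-to-peak lamella stroke in micrometres.
#' @param lt_test_mm Compressed lens thickness in mm (a homogeneous
#'   refractive index of 1.49 is assumed upstream when converting optical
#'   to geometric thickness).
#' @param drive_freq_hz Optional drive frequency; when given, the
#'   measured amplitude comes from a least-squares sinusoid fit (robust
#'   to drift), otherwise from half the raw peak-to-peak excursion.
#' @return Relative deviation `|measured - expected| / expected`
#'   (dimensionless); values above 0.10 indicate a failed consistency
#'   check and are reported, not suppressed.
#' @export
macroscopic_check <- function(strains, mask, stroke_um, lt_test_mm,
                              drive_freq_hz = NULL) {
  if (stroke_um <= 0) stop("zero stroke: macroscopic check undefined")
  d <- dim(strains)
  rows <- mask$lens_top:min(mask$lens_bottom, d[1])
  cols <- mask$lateral_zone[mask$lateral_zone <= d[2]]
  cplx <- attr(strains, "complex")
  optics <- attr(strains, "optics")
  mean_s <- if (!is.null(cplx) && !is.null(optics)) {
    sc <- optics$wavelength_nm / (4 * pi * optics$asu_um * 1e3)
    vapply(seq_len(d[3]), function(s) sc * Arg(sum(cplx[rows, cols, s])), 0)
  } else {
    vapply(seq_len(d[3]), function(s) mean(strains[rows, cols, s]), 0)
  }
  y <- cumsum(mean_s)
  measured <- if (!is.null(drive_freq_hz)) {
    fps <- if (!is.null(optics)) optics$frame_rate_hz else 1
    .sinfit(seq_along(y) / fps, y, drive_freq_hz)$amp
  } else {
    (max(y) - min(y)) / 2
  }
  expected <- (stroke_um / 2) / (lt_test_mm * 1e3)
  abs(measured - expected) / expected
}

#' One-call OCE processing of a B-scan stack
#'
#' Convenience wrapper: interframe cross-correlation, strain estimation,
#' reflectivity-based segmentation, per-region series and oscillation
#' summary.
#'
#' @param stack A [bscan_stack()].
#' @param params A [processing_params()].
#' @param drive_freq_hz Drive frequency for the oscillation fit.
#' @return A list with `corr`, `strains`, `mask`, `series`, `summary`
#'   and the mean structural `profile`.
#' @export
oce_process <- function(stack, params = processing_params(),
                        drive_freq_hz = 1.0) {
  corr <- interframe_xcorr(stack, params)
  strains <- strain_from_xcorr(corr, params, stack$optics)
  profile <- apply(Mod(stack$frames)^2, 1, mean)
  mask <- segment_regions(profile, stack$optics, params)
  series <- region_series(strains, mask, params)
  summary <- amplitude_and_delay(series, drive_freq_hz,
                                 stack$optics$frame_rate_hz)
  list(corr = corr, strains = strains, profile = profile, mask = mask,
       series = series, summary = summary)
}
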