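#' Layer stack of the quasi-1D lens model
#'
#' Assembles the axial layer stack, ordered from the top (anterior)
#' lamella downwards: anterior capsule, anterior cortical layers
#' (outermost first, layer 1 adjacent to the nucleus), nucleus, posterior
#' cortical layers (layer 1 first), posterior capsule. Reference
#' thicknesses sum to `lt0_mm`; cortical layers share one thickness so
#' the anterior:posterior cortical thickness ratio equals the 9:6 layer
#' count ratio.
#'
#' @param geom A [lens_geometry()].
#' @param mat A [material_model()].
#' @return A data frame with columns `h_mm`, `c10_kpa`, `region`
#'   (capsule/ant/nuc/post) and `layer_n` (cortical layer index, NA
#'   elsewhere).
#' @export
lens_layers <- function(geom, mat) {
  caps_mm <- geom$capsule_um * 1e-3
  interior <- geom$lt0_mm - 2 * caps_mm
  h_nuc <- interior * geom$nucleus_fraction
  n_cort <- geom$n_ant_layers + geom$n_post_layers
  h_layer <- interior * (1 - geom$nucleus_fraction) / n_cort
  mod <- cortical_layer_moduli(mat, geom)
  c10_caps <- mat$c10_capsule_mpa * 1e3  # MPa -> kPa
  c10_nuc_inst <- mat$c10_nuc_inf_kpa / (1 - mat$g1)
  ant_order <- rev(seq_len(geom$n_ant_layers))   # outermost (n = 9) on top
  post_order <- seq_len(geom$n_post_layers)      # innermost (n = 1) first
  df <- data.frame(
    h_mm = c(if (caps_mm > 0) caps_mm,
             rep(h_layer, geom$n_ant_layers),
             h_nuc,
             rep(h_layer, geom$n_post_layers),
             if (caps_mm > 0) caps_mm),
    c10_kpa = c(if (caps_mm > 0) c10_caps,
                mod$c10_ant[ant_order],
                c10_nuc_inst,
                mod$c10_post[post_order],
                if (caps_mm > 0) c10_caps),
    region = c(if (caps_mm > 0) "capsule",
               rep("ant", geom$n_ant_layers),
               "nuc",
               rep("post", geom$n_post_layers),
               if (caps_mm > 0) "capsule"),
    layer_n = c(if (caps_mm > 0) NA_integer_,
                ant_order, NA_integer_, post_order,
                if (caps_mm > 0) NA_integer_),
    stringsAsFactors = FALSE
  )
  stopifnot(abs(sum(df$h_mm) - geom$lt0_mm) < 1e-12 * geom$lt0_mm)
  df
}

# Vectorised inversion of sigma = 2 c10 (lambda^2 - 1/lambda) for lambda > 0.
# Newton with halving safeguard; the function is strictly increasing on
# (0, Inf) so the positive root is unique.
.invert_nh <- function(c10, sigma, lambda0) {
  lam <- lambda0
  for (it in 1:100) {
    f <- 2 * c10 * (lam^2 - 1 / lam) - sigma
    fp <- 2 * c10 * (2 * lam + 1 / lam^2)
    step <- f / fp
    lam_new <- lam - step
    bad <- lam_new <= 0
    if (any(bad)) lam_new[bad] <- lam[bad] / 2
    done <- abs(lam_new - lam) < 1e-14 * pmax(lam_new, 1)
    lam <- lam_new
    if (all(done)) break
  }
  lam
}

# One equilibrium step of the series composite: find the common axial
# Cauchy stress sigma such that sum(h_i lambda_i) = L_target, where each
# layer's stress is A_i * sigma_e(lambda_i) + B_i (A = 1, B = 0 for
# elastic layers; the nucleus QLV recurrence contributes A < 1 and an
# offset B). Returns sigma, lambda and the per-layer instantaneous
# elastic stress.
.solve_thickness <- function(h, c10, A, B, L_target, sigma0, lambda0) {
  sigma <- sigma0
  lam <- lambda0
  glen <- function(sig) {
    target_e <- (sig - B) / A
    lam <<- .invert_nh(c10, target_e, lam)
    sum(h * lam) - L_target
  }
  g <- glen(sigma)
  # bracket the root (g is strictly increasing in sigma)
  lo <- sigma; hi <- sigma; glo <- g; ghi <- g
  span <- max(abs(sigma), 1)
  while (glo > 0) { lo <- lo - span; glo <- glen(lo); span <- span * 2 }
  span <- max(abs(sigma), 1)
  while (ghi < 0) { hi <- hi + span; ghi <- glen(hi); span <- span * 2 }
  for (it in 1:200) {
    dlam_dsig <- 1 / (A * 2 * c10 * (2 * lam + 1 / lam^2))
    dg <- sum(h * dlam_dsig)
    sig_new <- sigma - g / dg
    if (!is.finite(sig_new) || sig_new <= lo || sig_new >= hi)
      sig_new <- (lo + hi) / 2
    g_new <- glen(sig_new)
    if (g_new < 0) { lo <- sig_new } else { hi <- sig_new }
    conv <- abs(g_new) < 1e-10 * L_target
    sigma <- sig_new; g <- g_new
    if (conv) break
    if (it == 200) stop("thickness solve did not converge at L = ", L_target)
  }
  sigma_e <- (sigma - B) / A
  list(sigma = sigma, lambda = lam, sigma_e = sigma_e)
}

# Imposed lamella-gap history: ramp, hold, sinusoidal micro-compression.
.thickness_history <- function(geom, protocol) {
  p <- protocol
  t_ramp <- seq(0, p$ramp_s, length.out = max(30L, ceiling(p$ramp_s / p$dt_s)) + 1L)
  # hold grid: fine early (relative to tau-scale transients), geometric later
  if (p$hold_s > 0) {
    fine <- seq(p$dt_s, min(2, p$hold_s), by = 2 * p$dt_s)
    coarse <- exp(seq(log(max(2 * p$dt_s, 0.2)), log(p$hold_s), length.out = 70))
    t_hold <- p$ramp_s + sort(unique(c(fine, coarse, p$hold_s)))
    t_hold <- t_hold[t_hold > p$ramp_s & t_hold <= p$ramp_s + p$hold_s]
  } else t_hold <- numeric(0)
  t0 <- p$ramp_s + p$hold_s
  t_osc <- t0 + seq(p$dt_s, p$osc_s, by = p$dt_s)
  times <- c(t_ramp, t_hold, t_osc)
  lt <- numeric(length(times))
  ramp_idx <- times <= p$ramp_s
  lt[ramp_idx] <- geom$lt0_mm +
    (geom$lt_test_mm - geom$lt0_mm) * times[ramp_idx] / p$ramp_s
  hold_idx <- times > p$ramp_s & times <= t0
  lt[hold_idx] <- geom$lt_test_mm
  osc_idx <- times > t0
  extra_um <- p$stroke_offset_um +
    (p$stroke_um / 2) * sin(2 * pi * p$drive_freq_hz * (times[osc_idx] - t0))
  lt[osc_idx] <- geom$lt_test_mm - extra_um * 1e-3
  phase <- c(rep("ramp", sum(ramp_idx)), rep("hold", sum(hold_idx)),
             rep("osc", sum(osc_idx)))
  list(times = times, lt_mm = lt, phase = phase, t_osc0 = t0)
}

#' Simulate a lens compression test
#'
#' Runs the quasi-1D series-composite forward model through the full
#' protocol: pre-compression ramp, stress-relaxation hold, sinusoidal
#' micro-compression. At every time step all layers carry the same axial
#' Cauchy stress and the layer stretches satisfy
#' `sum(h_i lambda_i) = LT(t)`. Elastic layers follow
#' [nh_uniaxial_stress()]; the nucleus follows quasi-linear
#' viscoelasticity, applying the reduced relaxation
#' `g(t) = 1 - g1 (1 - exp(-t/tau1))` to the instantaneous Neo-Hookean
#' stress through a recursive exponential (internal-variable) update.
#' Region strains during the oscillation are engineering strains relative
#' to the configuration at the end of the hold, reported in permille.
#'
#' @param geom A [lens_geometry()].
#' @param mat A [material_model()].
#' @param protocol A [compression_protocol()].
#' @param summary_fit If `TRUE` (default), fit oscillation amplitudes and
#'   the nucleus delay with [amplitude_and_delay()] and attach them as
#'   `$summary`.
#' @return An object of class `sim_output`: a list with
#'   `region_strain_series` (data frame `time_s`, `eps_ant`, `eps_nuc`,
#'   `eps_post` in permille, reference = end of hold),
#'   `force_trace` (full [force_trace()]), `min_force_gf` (end of hold),
#'   `max_force_gf` (end of ramp), `summary` (oscillation amplitudes and
#'   delay), `interfaces_mm` (layer interface depths from the top lamella
#'   at each oscillation sample, first column 0), `interfaces_ref_mm`,
#'   `layers`, and solver diagnostics (`thickness_residual`,
#'   `stress_imbalance`).
#' @export
simulate_test <- function(geom, mat, protocol, summary_fit = TRUE) {
  stopifnot(inherits(geom, "lens_geometry"), inherits(mat, "material_model"),
            inherits(protocol, "compression_protocol"))
  if (geom$lt_test_mm - (protocol$stroke_offset_um + protocol$stroke_um / 2) * 1e-3 <= 0)
    stop("oscillation stroke would close the lamella gap")
  layers <- lens_layers(geom, mat)
  nl <- nrow(layers)
  h <- layers$h_mm
  c10 <- layers$c10_kpa
  is_nuc <- layers$region == "nuc"
  hist <- .thickness_history(geom, protocol)
  nt <- length(hist$times)

  g1 <- mat$g1; tau1 <- mat$tau1_s
  lam <- rep(1, nl)
  sigma <- 0
  sig_e_nuc_prev <- 0
  q_prev <- 0  # exponential hereditary state of the nucleus
  lambda_hist <- matrix(NA_real_, nt, nl)
  sigma_hist <- numeric(nt)
  max_thick_resid <- 0
  max_stress_imb <- 0
  prev_t <- 0

  for (k in seq_len(nt)) {
    dt <- hist$times[k] - prev_t
    A <- rep(1, nl); B <- rep(0, nl)
    if (g1 > 0) {
      e <- exp(-dt / tau1)
      cc <- if (dt > 0) (1 - e) * tau1 / dt else 1
      A[is_nuc] <- (1 - g1) + g1 * cc
      B[is_nuc] <- g1 * (e * q_prev - cc * sig_e_nuc_prev)
    }
    sol <- .solve_thickness(h, c10, A, B, hist$lt_mm[k], sigma, lam)
    sigma <- sol$sigma; lam <- sol$lambda
    if (g1 > 0) {
      e <- exp(-dt / tau1)
      cc <- if (dt > 0) (1 - e) * tau1 / dt else 1
      sig_e_nuc <- sol$sigma_e[is_nuc][1]
      q_prev <- e * q_prev + cc * (sig_e_nuc - sig_e_nuc_prev)
      sig_e_nuc_prev <- sig_e_nuc
    }
    lambda_hist[k, ] <- lam
    sigma_hist[k] <- sigma
    max_thick_resid <- max(max_thick_resid, abs(sum(h * lam) - hist$lt_mm[k]))
    lay_sig <- A * nh_uniaxial_stress(c10, lam) + B
    max_stress_imb <- max(max_stress_imb,
                          diff(range(lay_sig)) / max(abs(mean(lay_sig)), 1e-12))
    prev_t <- hist$times[k]
  }

  # force: compression positive, gram-force; kPa * mm^2 = mN
  force_gf <- -sigma_hist * geom$contact_area_mm2 / 9.8
  hold_end <- max(which(hist$phase != "osc"))
  osc_idx <- which(hist$phase == "osc")
  ref_lam <- lambda_hist[hold_end, ]

  reg_len <- function(lamv, region) sum(h[layers$region == region] *
                                          lamv[layers$region == region])
  regs <- c("ant", "nuc", "post")
  ref_len <- vapply(regs, function(r) reg_len(ref_lam, r), 0)
  series <- vapply(regs, function(r) {
    lens_r <- apply(lambda_hist[osc_idx, , drop = FALSE], 1, reg_len, region = r)
    1000 * (lens_r - ref_len[[r]]) / ref_len[[r]]
  }, numeric(length(osc_idx)))

  t_osc <- hist$times[osc_idx] - hist$t_osc0
  region_series <- data.frame(time_s = t_osc,
                              eps_ant = series[, "ant"],
                              eps_nuc = series[, "nuc"],
                              eps_post = series[, "post"])
  class(region_series) <- c("region_strain_series", "data.frame")

  interfaces <- cbind(0, t(apply(lambda_hist[osc_idx, , drop = FALSE], 1,
                                 function(l) cumsum(h * l))))
  trace <- force_trace(hist$times, force_gf)
  out <- list(
    region_strain_series = region_series,
    force_trace = trace,
    min_force_gf = force_gf[hold_end],
    max_force_gf = force_gf[which(hist$phase == "ramp")[sum(hist$phase == "ramp")]],
    interfaces_mm = interfaces,
    interfaces_ref_mm = cumsum(c(0, h * ref_lam)),
    layers = layers,
    times = hist$times, phase = hist$phase,
    sigma_kpa = sigma_hist,
    lambda = lambda_hist,
    lateral_stretch = lambda_hist^(-0.5),
    thickness_residual = max_thick_resid,
    stress_imbalance = max_stress_imb
  )
  if (summary_fit) {
    out$summary <- amplitude_and_delay(region_series,
                                       drive_freq_hz = protocol$drive_freq_hz,
                                       frame_rate_hz = 1 / protocol$dt_s,
                                       cumulative = TRUE)
  }
  structure(out, class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf(
    "Lens compression simulation: %d steps, min force %.3g gf, max force %.3g gf\n",
    length(x$times), x$min_force_gf, x$max_force_gf))
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}
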