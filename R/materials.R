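#' Lens geometry for the compression model
#'
#' The lens is represented as a one-dimensional axial stack of layers
#' between two flat glass lamellae: an anterior capsule, nine anterior
#' cortical layers, the nucleus, six posterior cortical layers and a
#' posterior capsule. Layer reference thicknesses sum to the undeformed
#' thickness `lt0_mm`.
#'
#' @param lt0_mm Undeformed lens thickness (mm).
#' @param lt_test_mm Compressed thickness during the test (mm); 5.4 for
#'   encapsulated lenses, 4.4 after decapsulation (33% pre-strain).
#' @param capsule_um Capsule thickness per face in micrometres (60;
#'   use 0 for decapsulated lenses).
#' @param n_ant_layers,n_post_layers Number of cortical layers on the
#'   anterior (9) and posterior (6) side.
#' @param nucleus_fraction Axial fraction of the capsule-free lens
#'   occupied by the nucleus (default 0.55).
#' @param contact_area_mm2 Effective lamella contact area used to convert
#'   axial stress to force; a pure force-scale calibration constant.
#' @return An object of class `lens_geometry`.
#' @export
lens_geometry <- function(lt0_mm = 8.06, lt_test_mm = 5.4, capsule_um = 60,
                          n_ant_layers = 9L, n_post_layers = 6L,
                          nucleus_fraction = 0.55,
                          contact_area_mm2 = pi * 2.5^2) {
  stopifnot(lt0_mm > 0, lt_test_mm > 0, lt_test_mm < lt0_mm,
            capsule_um >= 0, n_ant_layers >= 1, n_post_layers >= 1,
            nucleus_fraction > 0, nucleus_fraction < 1,
            contact_area_mm2 > 0)
  if (2 * capsule_um * 1e-3 >= lt0_mm)
    stop("capsule thicker than the lens")
  structure(list(
    lt0_mm = lt0_mm, lt_test_mm = lt_test_mm, capsule_um = capsule_um,
    n_ant_layers = as.integer(n_ant_layers),
    n_post_layers = as.integer(n_post_layers),
    nucleus_fraction = nucleus_fraction,
    contact_area_mm2 = contact_area_mm2
  ), class = "lens_geometry")
}

#' Visco-hyperelastic material parameters of the lens
#'
#' The nucleus is an incompressible Neo-Hookean solid whose coefficient
#' relaxes with a one-term Prony series,
#' `C10(t) = C10_0 (1 - g1 (1 - exp(-t/tau1)))`, so the long-term modulus
#' is `C10_inf = C10_0 (1 - g1)`. Cortical layers are purely elastic
#' Neo-Hookean; their stiffness profile is controlled by the form factor
#' `F` and the nucleus factor `N_stiffness` (see
#' [cortical_layer_moduli()]). The capsule is elastic Neo-Hookean with
#' coefficient 0.166 MPa (Young's modulus about 1 MPa).
#'
#' @param c10_nuc_inf_kpa Long-term nucleus Neo-Hookean coefficient in kPa.
#' @param g1 Prony pre-exponential factor (dimensionless, `0 <= g1 < 1`);
#'   fixed at 0.25 across conditions to avoid overfitting.
#' @param tau1_s Relaxation time in seconds.
#' @param form_factor_f Form factor F grading the cortical layer stiffness.
#' @param n_stiffness Nucleus-to-cortex stiffness factor N.
#' @param c10_capsule_mpa Capsule Neo-Hookean coefficient in MPa.
#' @param eq4_variant Either `"corrected"` (layer C10 =
#'   C10_inf / (N F^n), the default: nucleus stiffer than cortex for
#'   F > 1, N near 1) or `"printed"` (layer C10 = N F^n C10_inf),
#'   retained for auditability.
#' @return An object of class `material_model`.
#' @export
material_model <- function(c10_nuc_inf_kpa = 2, g1 = 0.25, tau1_s = 1,
                           form_factor_f = 1.4, n_stiffness = 1,
                           c10_capsule_mpa = 0.166,
                           eq4_variant = c("corrected", "printed")) {
  eq4_variant <- match.arg(eq4_variant)
  stopifnot(c10_nuc_inf_kpa > 0, g1 >= 0, g1 < 1, tau1_s > 0,
            form_factor_f > 0, n_stiffness > 0, c10_capsule_mpa > 0)
  structure(list(
    c10_nuc_inf_kpa = c10_nuc_inf_kpa, g1 = g1, tau1_s = tau1_s,
    form_factor_f = form_factor_f, n_stiffness = n_stiffness,
    c10_capsule_mpa = c10_capsule_mpa, eq4_variant = eq4_variant
  ), class = "material_model")
}

#' @export
print.material_model <- function(x, ...) {
  cat(sprintf(
    "Lens material: C10_nuc_inf %.3g kPa, g1 %.2f, tau1 %.3g s, F %.3g, N %.3g (%s Eq-4 rule)\n",
    x$c10_nuc_inf_kpa, x$g1, x$tau1_s, x$form_factor_f, x$n_stiffness,
    x$eq4_variant))
  invisible(x)
}

#' Compression protocol
#'
#' Thickness history imposed by the lamellae: a linear ramp to the
#' pre-strained thickness, a relaxation hold, then a sinusoidal
#' micro-compression. The oscillation spans `stroke_um` peak-to-peak,
#' offset by `stroke_offset_um` towards compression, reproducing a
#' -32 to +36 um lamella excursion with the defaults.
#'
#' @param prestrain Engineering pre-strain target (0.33); informational
#'   when geometry fixes `lt_test_mm` explicitly.
#' @param ramp_s Pre-compression ramp duration in seconds.
#' @param hold_s Relaxation duration in seconds (120 short, 1800 long).
#' @param stroke_um Peak-to-peak oscillation stroke in micrometres (68).
#' @param stroke_offset_um Mean additional compression during the
#'   oscillation in micrometres (2).
#' @param drive_freq_hz Oscillation frequency in Hz (default 1.0).
#' @param dt_s Solver step during ramp and oscillation, seconds.
#' @param osc_s Duration of the oscillation phase in seconds; defaults to
#'   256 frames at 33 Hz.
#' @return An object of class `compression_protocol`.
#' @export
compression_protocol <- function(prestrain = 0.33, ramp_s = 1, hold_s = 120,
                                 stroke_um = 68, stroke_offset_um = 2,
                                 drive_freq_hz = 1.0, dt_s = 1 / 33,
                                 osc_s = 256 / 33) {
  stopifnot(prestrain > 0, prestrain < 1, ramp_s > 0, hold_s >= 0,
            stroke_um >= 0, drive_freq_hz > 0, dt_s > 0, osc_s > 0)
  if (dt_s > 1 / (20 * drive_freq_hz))
    stop("dt_s must be at most 1/(20 * drive_freq_hz) to resolve the oscillation")
  structure(list(
    prestrain = prestrain, ramp_s = ramp_s, hold_s = hold_s,
    stroke_um = stroke_um, stroke_offset_um = stroke_offset_um,
    drive_freq_hz = drive_freq_hz, dt_s = dt_s, osc_s = osc_s
  ), class = "compression_protocol")
}

#' Cortical layer stiffness profile
#'
#' Computes the Neo-Hookean coefficient of every cortical layer from the
#' long-term nucleus modulus, the form factor F and the nucleus factor N.
#' Layer n = 1 is adjacent to the nucleus on either side. Under the
#' default (corrected) rule, layer n has
#' `C10_n = C10_nuc_inf / (N F^n)`, so F > 1 grades the cortex softer
#' towards the surface and N scales the overall nucleus:cortex stiffness
#' ratio. The per-side averages `C10bar_ant` and `C10bar_post` are
#' arithmetic means over the 9 anterior and 6 posterior layers.
#'
#' @param mat A [material_model()].
#' @param geom A [lens_geometry()].
#' @return A list with `c10_ant` (length 9, ordered layer 1 = innermost),
#'   `c10_post` (length 6), `c10bar_ant`, `c10bar_post`, `c10bar_pooled`
#'   (mean over all 15 cortical layers), and the stiffness ratios
#'   `ratio_ant = C10_nuc_inf / C10bar_ant`, `ratio_post`, `ratio_pooled`.
#' @export
cortical_layer_moduli <- function(mat, geom) {
  stopifnot(inherits(mat, "material_model"), inherits(geom, "lens_geometry"))
  layer <- function(n) {
    if (mat$eq4_variant == "corrected")
      mat$c10_nuc_inf_kpa / (mat$n_stiffness * mat$form_factor_f^n)
    else
      mat$n_stiffness * mat$form_factor_f^n * mat$c10_nuc_inf_kpa
  }
  c10_ant <- layer(seq_len(geom$n_ant_layers))
  c10_post <- layer(seq_len(geom$n_post_layers))
  if (any(c(c10_ant, c10_post) <= 0) || any(!is.finite(c(c10_ant, c10_post))))
    stop("nonpositive or non-finite cortical layer modulus")
  c10bar_ant <- mean(c10_ant)
  c10bar_post <- mean(c10_post)
  c10bar_pooled <- mean(c(c10_ant, c10_post))
  list(c10_ant = c10_ant, c10_post = c10_post,
       c10bar_ant = c10bar_ant, c10bar_post = c10bar_post,
       c10bar_pooled = c10bar_pooled,
       ratio_ant = mat$c10_nuc_inf_kpa / c10bar_ant,
       ratio_post = mat$c10_nuc_inf_kpa / c10bar_post,
       ratio_pooled = mat$c10_nuc_inf_kpa / c10bar_pooled)
}

#' Incompressible Neo-Hookean uniaxial Cauchy stress
#'
#' For an incompressible Neo-Hookean solid under uniaxial stretch
#' `lambda` (lateral stretch `lambda^(-1/2)`), the axial Cauchy stress is
#' `sigma = 2 C10 (lambda^2 - 1/lambda)`. Its tangent at `lambda = 1` is
#' `6 C10`, consistent with the small-strain Young's modulus
#' [to_linear_modulus()].
#'
#' @param c10 Neo-Hookean coefficient (any stress unit).
#' @param stretch Axial stretch, > 0 (vectorised).
#' @return Axial Cauchy stress in the unit of `c10`.
#' @export
nh_uniaxial_stress <- function(c10, stretch) {
  stopifnot(all(stretch > 0))
  2 * c10 * (stretch^2 - 1 / stretch)
}

#' Prony-series relaxation of the Neo-Hookean coefficient
#'
#' `C10(t) = C10_0 (1 - g1 (1 - exp(-t / tau1)))`, monotone
#' non-increasing from `C10_0` at t = 0 towards the long-term modulus
#' `C10_inf = C10_0 (1 - g1)`.
#'
#' @param t Time(s) in seconds, >= 0 (vectorised).
#' @param c10_0 Instantaneous coefficient.
#' @param g1 Prony pre-exponential factor.
#' @param tau1 Relaxation time in seconds.
#' @return Relaxed coefficient at `t`, same unit as `c10_0`.
#' @export
relaxation_modulus <- function(t, c10_0, g1, tau1) {
  stopifnot(all(t >= 0), tau1 > 0, g1 >= 0, g1 < 1)
  c10_0 * (1 - g1 * (1 - exp(-t / tau1)))
}

#' Small-strain Young's modulus of a Neo-Hookean solid
#'
#' Uses the incompressible identities `mu = 2 C10` and `E = 3 mu`, i.e.
#' `E = 6 C10`, in the unit of `c10`.
#'
#' @param c10 Neo-Hookean coefficient, >= 0.
#' @return Young's modulus `E = 6 c10`.
#' @export
to_linear_modulus <- function(c10) {
  stopifnot(all(c10 >= 0))
  6 * c10
}
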