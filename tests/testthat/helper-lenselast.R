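# Shared fixtures, built lazily and cached for the whole test run.

.lenselast_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.lenselast_cache[[key]]))
    assign(key, force(expr), envir = .lenselast_cache)
  .lenselast_cache[[key]]
}

# protocol locked to a frame grid, short hold: fast but fully featured
quick_protocol <- function(hold_s = 40, n_frames = 128, frame_rate_hz = 33,
                           ...) {
  compression_protocol(hold_s = hold_s, dt_s = 1 / frame_rate_hz,
                       osc_s = n_frames / frame_rate_hz, ...)
}

# coarse fresh-design response surface shared by the inverse-fit tests
fresh_surface <- function() {
  cached("fresh_surface", {
    design <- coarsen_design(build_factorial("fresh"), c(2L, 4L, 4L, 3L))
    run_design(design, quick_protocol(), lens_geometry())
  })
}

# one fully rendered fresh lens acquisition at true axial sampling
fresh_dataset <- function() {
  cached("fresh_dataset", {
    preset <- make_group_preset("fresh")
    geom <- lens_geometry(lt0_mm = preset$lt0_mm,
                          lt_test_mm = preset$lt_test_mm)
    optics <- optics_for_geometry(geom, n_x = 8L, n_frames = 160L)
    synth_lens_dataset(preset, seed = 42L, optics = optics,
                       protocol = quick_protocol(hold_s = 60,
                                                 n_frames = 160L))
  })
}

# uniform-strain oscillation phantom: cumulative displacement field for a
# prescribed strain amplitude (permille) at a drive frequency
uniform_strain_displacement <- function(optics, amp_permille, freq_hz = 1,
                                        mean_permille = 0) {
  n_mean <- mean(optics$n_of_z)
  px_nm <- optics$asu_um * 1e3 / n_mean
  t <- seq_len(optics$n_frames) / optics$frame_rate_hz
  eps <- (mean_permille + amp_permille * sin(2 * pi * freq_hz * t)) * 1e-3
  outer((seq_len(optics$n_z) - 1) * px_nm, eps)
}
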