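test_that("layer stack partitions the undeformed thickness", {
  geom <- lens_geometry(lt0_mm = 8.06, capsule_um = 60,
                        nucleus_fraction = 0.55)
  lay <- lens_layers(geom, material_model())
  expect_equal(sum(lay$h_mm), 8.06)
  expect_equal(sum(lay$region == "ant"), 9)
  expect_equal(sum(lay$region == "post"), 6)
  expect_equal(sum(lay$region == "capsule"), 2)
  interior <- 8.06 - 2 * 0.06
  expect_equal(lay$h_mm[lay$region == "nuc"], interior * 0.55)
  # layer 1 sits adjacent to the nucleus on both sides
  nuc_i <- which(lay$region == "nuc")
  expect_equal(lay$layer_n[nuc_i - 1], 1L)
  expect_equal(lay$layer_n[nuc_i + 1], 1L)
  # decapsulated: no capsule rows
  lay0 <- lens_layers(lens_geometry(lt0_mm = 6.6, lt_test_mm = 4.4,
                                    capsule_um = 0), material_model())
  expect_false(any(lay0$region == "capsule"))
  expect_equal(sum(lay0$h_mm), 6.6)
})

test_that("solver conserves thickness and balances stress to tight tolerances", {
  sim <- simulate_test(lens_geometry(), material_model(), quick_protocol())
  expect_lt(sim$thickness_residual, 1e-9 * 8.06)
  expect_lt(sim$stress_imbalance, 1e-6)
  # lateral stretch of an incompressible uniaxial layer is lambda^(-1/2)
  expect_identical(sim$lateral_stretch, sim$lambda^(-0.5))
})

test_that("pure elastic lens shows no relaxation and no nucleus delay", {
  sim <- simulate_test(lens_geometry(),
                       material_model(g1 = 0, tau1_s = 1),
                       quick_protocol())
  expect_equal(sim$min_force_gf, sim$max_force_gf, tolerance = 1e-9)
  # force constant during the hold
  hold <- sim$phase == "hold"
  f <- sim$force_trace$force_gf[hold]
  expect_lt(diff(range(f)), 1e-9 * max(f))
  expect_equal(sim$summary$delay_nuc_ms, 0, tolerance = 5e-2)
})

test_that("homogeneous lens deforms uniformly: identical region series", {
  geom <- lens_geometry(capsule_um = 0)
  sim <- simulate_test(geom,
                       material_model(form_factor_f = 1, n_stiffness = 1,
                                      g1 = 0),
                       quick_protocol())
  s <- sim$region_strain_series
  expect_equal(s$eps_ant, s$eps_nuc, tolerance = 1e-9)
  expect_equal(s$eps_post, s$eps_nuc, tolerance = 1e-9)
  expect_equal(sim$summary$strain_ratio_cortex_nucleus, 1, tolerance = 1e-7)
})

test_that("force relaxes monotonically during the hold and the nucleus lags", {
  sim <- simulate_test(lens_geometry(),
                       material_model(g1 = 0.25, tau1_s = 1),
                       quick_protocol(hold_s = 30))
  hold <- sim$phase == "hold"
  expect_true(all(diff(sim$force_trace$force_gf[hold]) <= 1e-12))
  expect_true(sim$summary$delay_defined)
  expect_lt(sim$summary$delay_nuc_ms, 0)
  # delay vanishes as g1 -> 0
  d <- vapply(c(0.25, 0.1, 0.02), function(g) {
    simulate_test(lens_geometry(), material_model(g1 = g, tau1_s = 1),
                  quick_protocol(hold_s = 10))$summary$delay_nuc_ms
  }, 0)
  expect_true(all(diff(abs(d)) < 0))
})

test_that("small-strain force relaxation matches the analytic SLS series solution", {
  # 1% pre-strain, near-instant ramp, no oscillation: the composite reduces
  # to elastic springs in series with one standard-linear-solid element
  lt0 <- 8
  prestrain <- 0.01
  geom <- lens_geometry(lt0_mm = lt0, lt_test_mm = lt0 * (1 - prestrain))
  mat <- material_model(c10_nuc_inf_kpa = 2, g1 = 0.25, tau1_s = 2,
                        form_factor_f = 1.3, n_stiffness = 0.9)
  prot <- compression_protocol(ramp_s = 0.004, hold_s = 20, stroke_um = 0,
                               stroke_offset_um = 0, dt_s = 1 / 33,
                               osc_s = 0.25)
  sim <- simulate_test(geom, mat, prot, summary_fit = FALSE)

  # independent linear oracle: springs E_i = 6 C10_i in series with an SLS
  # nucleus (E_inf parallel to a Maxwell arm E_1 - eta, eta = E_1 tau)
  lay <- lens_layers(geom, mat)
  is_nuc <- lay$region == "nuc"
  e_inf <- 6 * mat$c10_nuc_inf_kpa
  e0 <- e_inf / (1 - mat$g1)
  e1 <- e0 * mat$g1
  h_n <- lay$h_mm[is_nuc]
  c_e <- sum(lay$h_mm[!is_nuc] / (6 * lay$c10_kpa[!is_nuc]))
  u <- lt0 * prestrain
  sig0 <- u / (c_e + h_n / e0)
  sig_inf <- u / (c_e + h_n / e_inf)
  d_fac <- 1 + e0 * c_e / h_n
  k <- (1 / mat$tau1_s) * (1 - c_e * e1 / (h_n * d_fac))
  hold <- sim$phase == "hold"
  t <- sim$times[hold] - prot$ramp_s
  oracle_gf <- (sig_inf + (sig0 - sig_inf) * exp(-k * t)) *
    geom$contact_area_mm2 / 9.8
  expect_equal(sim$force_trace$force_gf[hold], oracle_gf, tolerance = 0.01)
})

test_that("halving the time step changes oscillation amplitudes by < 0.5%", {
  geom <- lens_geometry()
  mat <- material_model(tau1_s = 0.5)
  s1 <- simulate_test(geom, mat, quick_protocol(hold_s = 20,
                                                frame_rate_hz = 33))
  s2 <- simulate_test(geom, mat, quick_protocol(hold_s = 20,
                                                frame_rate_hz = 66,
                                                n_frames = 256))
  for (fld in c("amp_ant_permille", "amp_nuc_permille", "amp_post_permille")) {
    expect_equal(s1$summary[[fld]], s2$summary[[fld]], tolerance = 5e-3)
  }
})

test_that("a stiffer nucleus strains less than the cortex", {
  sim <- simulate_test(lens_geometry(),
                       material_model(form_factor_f = 1.3, n_stiffness = 1),
                       quick_protocol())
  expect_lt(sim$summary$amp_nuc_permille,
            mean(c(sim$summary$amp_ant_permille,
                   sim$summary$amp_post_permille)))
})
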