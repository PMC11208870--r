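test_that("factorial designs reproduce the published level lists", {
  d <- build_factorial("fresh")
  expect_equal(d$levels$thickness, c(7.1, 7.4, 7.55, 7.8))
  expect_equal(d$levels$tau1, c(0.25, 0.5, 1, 1.5, 3, 5, 7.5))
  expect_equal(d$levels$f, seq(1, 3, by = 0.25))
  expect_length(d$levels$n, 9)
  expect_equal(nrow(d$combos), 4 * 7 * 9 * 9)   # 2268
  # frozen: 17 F levels; fridge8 maps onto the fresh design
  expect_length(build_factorial("frozen20")$levels$f, 17)
  expect_equal(build_factorial("fridge8")$levels,
               build_factorial("fresh")$levels)
  # de-cap F grid generated start-by-increment stops at 3.8, not 4.0
  expect_equal(max(build_factorial("de-cap")$levels$f), 3.8)
  expect_equal(build_factorial("de-cap")$levels$n,
               seq(0.85, 1.03, by = 0.03))
  expect_error(build_factorial("thawed"), "unknown")
  # every level appears in at least one combination
  for (nm in c("thickness_mm", "tau1_s", "form_factor_f", "n_stiffness")) {
    lv <- list(thickness_mm = d$levels$thickness, tau1_s = d$levels$tau1,
               form_factor_f = d$levels$f, n_stiffness = d$levels$n)[[nm]]
    expect_setequal(unique(d$combos[[nm]]), lv)
  }
  # screening ranges only re-span the frozen F/N rows
  scr <- build_factorial("frozen20", ranges = "screening")
  expect_equal(range(scr$levels$f), c(1, 2))
  expect_equal(build_factorial("fresh", ranges = "screening")$levels,
               build_factorial("fresh")$levels)
})

test_that("the SSE objective is a standardized sum of squares", {
  obs <- observed_summary(1, 1, 1, 0)
  expect_equal(fit_sse(obs, c(1, 1, 1, 0)), 0)
  expect_equal(fit_sse(obs, c(0, 0, 0, 0)), 3)
  # symmetric under swapping anterior/posterior mismatches
  o2 <- observed_summary(2, 1, 1, 0)
  expect_equal(fit_sse(o2, c(1, 2, 1, 0)), fit_sse(observed_summary(1, 2, 1, 0),
                                                   c(2, 1, 1, 0)))
  # standardization divides each component by its scale
  expect_equal(fit_sse(obs, c(0, 0, 0, 10), scale = c(1, 1, 1, 5)),
               3 + 4)
  # missing observed delay drops that component
  expect_equal(fit_sse(observed_summary(1, 1, 1, NA), c(0, 0, 0, 99)), 3)
})

test_that("a single-combination design reproduces the direct simulation", {
  d <- build_factorial("fresh")
  near <- function(x, v) abs(x - v) < 1e-9
  d$combos <- d$combos[near(d$combos$thickness_mm, 7.4) &
                         near(d$combos$tau1_s, 1) &
                         near(d$combos$form_factor_f, 1.5) &
                         near(d$combos$n_stiffness, 0.85), ]
  d$levels <- list(thickness = 7.4, tau1 = 1, f = 1.5, n = 0.85)
  prot <- quick_protocol()
  surf <- run_design(d, prot, lens_geometry())
  expect_equal(nrow(surf$rows), 1)
  s <- simulate_test(lens_geometry(lt0_mm = 7.4),
                     material_model(c10_nuc_inf_kpa = 1, tau1_s = 1,
                                    form_factor_f = 1.5,
                                    n_stiffness = 0.85), prot)$summary
  expect_equal(surf$rows$amp_ant, s$amp_ant_permille)
  expect_equal(surf$rows$amp_nuc, s$amp_nuc_permille)
  expect_equal(surf$rows$delay_ms, s$delay_nuc_ms)
})

test_that("strain outputs are invariant under a global modulus scaling", {
  prot <- quick_protocol(hold_s = 20)
  geom <- lens_geometry(lt0_mm = 7.4)
  s1 <- simulate_test(geom, material_model(c10_nuc_inf_kpa = 1), prot)
  s2 <- simulate_test(geom, material_model(c10_nuc_inf_kpa = 2,
                                           c10_capsule_mpa = 0.332), prot)
  expect_equal(s1$summary$amp_ant_permille, s2$summary$amp_ant_permille,
               tolerance = 1e-8)
  expect_equal(s1$summary$amp_nuc_permille, s2$summary$amp_nuc_permille,
               tolerance = 1e-8)
  expect_equal(s1$summary$delay_nuc_ms, s2$summary$delay_nuc_ms,
               tolerance = 1e-6)
  # forces scale linearly with the moduli
  expect_equal(s2$min_force_gf / s1$min_force_gf, 2, tolerance = 1e-8)
})

test_that("surrogate predictions agree with the simulated design rows", {
  surf <- fresh_surface()
  rows <- surf$rows[surf$rows$ok, ]
  pred <- t(vapply(seq_len(nrow(rows)), function(i)
    lenselast:::.predict_surface(surf, as.numeric(
      rows[i, c("thickness_mm", "tau1_s", "form_factor_f", "n_stiffness")])),
    numeric(4)))
  rel_amp_ok <- abs(pred[, 1:3] / as.matrix(rows[, c("amp_ant", "amp_post",
                                                     "amp_nuc")]) - 1) < 0.10
  expect_gte(mean(rel_amp_ok), 0.90)
  expect_gte(min(surf$surrogate_r2[c("amp_ant", "amp_post", "amp_nuc")]),
             0.95)
})

test_that("noise-free observables from an exact design combination are recovered", {
  surf <- fresh_surface()
  prot <- quick_protocol()
  # truth at a node of the surface grid (away from the F/N hull corners)
  lv <- surf$design$levels
  truth <- c(thickness = lv$thickness[1], tau = lv$tau1[2], f = lv$f[2],
             n = lv$n[2])
  s <- simulate_test(lens_geometry(lt0_mm = truth[["thickness"]]),
                     material_model(tau1_s = truth[["tau"]],
                                    form_factor_f = truth[["f"]],
                                    n_stiffness = truth[["n"]]),
                     prot)$summary
  fit <- optimize_fit(surf, as_observed(s), polish = FALSE)
  step <- function(v) if (length(v) > 1) max(diff(sort(v))) else Inf
  lv <- surf$design$levels
  expect_lte(abs(fit$thickness_mm - truth[["thickness"]]),
             step(lv$thickness) + 1e-9)
  expect_lte(abs(fit$tau1_s - truth[["tau"]]), step(lv$tau1) + 1e-9)
  expect_lte(abs(fit$form_factor_f - truth[["f"]]), step(lv$f) + 1e-9)
  expect_lte(abs(fit$n_stiffness - truth[["n"]]), step(lv$n) + 1e-9)
  expect_lt(fit$sse, 1e-6)
})

test_that("observations outside the response range clip to the design boundary and are flagged", {
  surf <- fresh_surface()
  far <- observed_summary(80, 80, 0.01, -400)
  fit <- optimize_fit(surf, far, refine = FALSE, polish = FALSE)
  expect_true(fit$at_boundary ||
                max(abs(fit$predicted[1:3] - c(80, 80, 0.01))) > 1)
  lv <- surf$design$levels
  expect_gte(fit$form_factor_f, min(lv$f))
  expect_lte(fit$form_factor_f, max(lv$f))
})

test_that("force calibration is a pure linear scale on the moduli", {
  surf <- fresh_surface()
  prot <- surf$protocol
  geom <- lens_geometry()
  s <- simulate_test(lens_geometry(lt0_mm = 7.4),
                     material_model(tau1_s = 1), prot)
  fit <- optimize_fit(surf, as_observed(s$summary), polish = FALSE)
  # observed equals simulated at c10_ref: scale factor 1
  g <- geom; g$lt0_mm <- fit$thickness_mm
  f_at_ref <- simulate_test(g, material_model(
    c10_nuc_inf_kpa = fit$c10_ref_kpa, tau1_s = fit$tau1_s,
    form_factor_f = fit$form_factor_f, n_stiffness = fit$n_stiffness),
    prot, summary_fit = FALSE)$min_force_gf
  cal0 <- calibrate_scale(fit, f_at_ref, geom, prot)
  expect_equal(cal0$force_scale_factor, 1, tolerance = 1e-9)
  # doubling the observed force doubles the recovered modulus
  cal1 <- calibrate_scale(fit, 3, geom, prot)
  cal2 <- calibrate_scale(fit, 6, geom, prot)
  expect_equal(cal2$c10_nuc_inf_abs_kpa / cal1$c10_nuc_inf_abs_kpa, 2,
               tolerance = 1e-12)
  expect_error(calibrate_scale(fit, -1, geom, prot), "positive")
})

test_that("dropping the delay from the objective degrades tau recovery", {
  surf <- fresh_surface()
  prot <- surf$protocol
  set.seed(11)
  err_with <- err_without <- numeric(5)
  lv <- surf$design$levels
  for (i in 1:5) {
    tr_tau <- exp(runif(1, log(0.3), log(5)))
    s <- simulate_test(lens_geometry(lt0_mm = 7.4),
                       material_model(tau1_s = tr_tau), prot)$summary
    obs_full <- as_observed(s)
    obs_nodelay <- obs_full; obs_nodelay$delay_ms <- NA
    f1 <- optimize_fit(surf, obs_full, polish = FALSE)
    f2 <- optimize_fit(surf, obs_nodelay, polish = FALSE)
    err_with[i] <- abs(log(f1$tau1_s / tr_tau))
    err_without[i] <- abs(log(f2$tau1_s / tr_tau))
  }
  expect_lt(mean(err_with), mean(err_without))
})

test_that("goodness of fit is 100% for identity and 0% for the mean predictor", {
  t <- seq_len(99) / 33
  mk <- function(a) data.frame(time_s = t, eps_ant = a * sin(2 * pi * t),
                               eps_nuc = a * 0.5 * sin(2 * pi * t),
                               eps_post = a * sin(2 * pi * t))
  obs <- mk(2)
  expect_equal(goodness_r2(obs, obs, observed_incremental = FALSE), 100)
  flat <- obs
  flat[c("eps_ant", "eps_nuc", "eps_post")] <-
    lapply(obs[c("eps_ant", "eps_nuc", "eps_post")], function(y) y * 0)
  expect_equal(goodness_r2(obs, flat, observed_incremental = FALSE), 0,
               tolerance = 1e-9)
  zero <- flat
  expect_warning(r <- goodness_r2(zero, obs, observed_incremental = FALSE),
                 "zero variance")
  expect_true(is.na(r))
})
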