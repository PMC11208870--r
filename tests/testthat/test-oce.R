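make_stack <- function(frames_list, optics = NULL) {
  nz <- nrow(frames_list[[1]]); nx <- ncol(frames_list[[1]])
  if (is.null(optics))
    optics <- optics_config(n_z = nz, n_x = nx,
                            n_frames = length(frames_list),
                            refractive_index_profile = 1.49)
  arr <- array(complex(real = 0), dim = c(nz, nx, length(frames_list)))
  for (s in seq_along(frames_list)) arr[, , s] <- frames_list[[s]]
  bscan_stack(arr, optics)
}

speckle_frame <- function(nz, nx, seed) {
  set.seed(seed)
  matrix(complex(real = rnorm(nz * nx), imaginary = rnorm(nz * nx)), nz, nx)
}

test_that("interframe correlation angle encodes the declared conjugation convention", {
  b <- speckle_frame(40, 6, 1)
  # identical frames: zero phase
  co <- interframe_xcorr(make_stack(list(b, b)), processing_params(w_z = 3))
  expect_equal(max(abs(Arg(co[, , 1]))), 0, tolerance = 1e-12)
  # global phase shift: B(s) conj(B(s+1)) gives minus the shift
  co2 <- interframe_xcorr(make_stack(list(b, b * exp(0.3i))),
                          processing_params(w_z = 3))
  expect_true(all(abs(Arg(co2[, , 1]) + 0.3) < 1e-10))
  # independent white-noise frames decorrelate: |R| << windowed power
  b2 <- speckle_frame(40, 6, 2)
  co3 <- interframe_xcorr(make_stack(list(b, b2)), processing_params(w_z = 10))
  pow <- lenselast:::.boxcar_sum(Mod(b)^2, 10, 1)
  expect_lt(mean(Mod(co3[, , 1]) / pow), 0.5)
})

test_that("displacement conversion follows dz = lambda angle / (4 pi n)", {
  opt <- optics_config(n_z = 4, n_x = 2, n_frames = 2,
                       refractive_index_profile = 1.49)
  co <- array(exp(1i * pi), dim = c(4, 2, 1))
  expect_equal(displacement_from_phase(co, opt)[1, 1, 1],
               1200 / (4 * 1.49), tolerance = 1e-9)   # 201.34 nm
  opt1 <- optics_config(n_z = 4, n_x = 2, n_frames = 2,
                        refractive_index_profile = 1.0)
  co2 <- array(exp(1i * pi / 2), dim = c(4, 2, 1))
  expect_equal(displacement_from_phase(co2, opt1)[1, 1, 1], 150,
               tolerance = 1e-9)
  expect_equal(displacement_from_phase(array(1 + 0i, dim = c(4, 2, 1)), opt),
               array(0, dim = c(4, 2, 1)))
})

test_that("strain estimation recovers a linear phase ramp and ignores n(z)", {
  nz <- 80; nx <- 4
  ramp <- 0.1  # rad per depth pixel
  co <- array(exp(1i * ramp * (seq_len(nz) - 1)), dim = c(nz, nx, 1))
  opt <- optics_config(n_z = nz, n_x = nx, n_frames = 2)
  eps <- strain_from_xcorr(co, processing_params(v_z = 5), opt)
  expect_equal(eps[40, 2, 1], 1200e-9 * 0.1 / (4 * pi * 9.5e-6),
               tolerance = 1e-9)                       # 1.005e-3
  # rigid translation: uniform phase, zero strain
  co0 <- array(exp(1i * 0.7), dim = c(nz, nx, 1))
  eps0 <- strain_from_xcorr(co0, processing_params(v_z = 5), opt)
  expect_equal(max(abs(eps0)), 0, tolerance = 1e-12)
  # independence from the refractive-index profile, bitwise
  opt149 <- optics_config(n_z = nz, n_x = nx, n_frames = 2,
                          refractive_index_profile = 1.49)
  eps149 <- strain_from_xcorr(co, processing_params(v_z = 5), opt149)
  expect_identical(as.numeric(eps), as.numeric(eps149))
  # depth extent must exceed the strain window
  expect_error(strain_from_xcorr(co[1:8, , , drop = FALSE],
                                 processing_params(v_z = 15), opt),
               "window")
})

test_that("doubling the lateral window leaves the phase of a laterally homogeneous field unchanged", {
  nz <- 60; nx <- 9
  b1 <- speckle_frame(nz, 1, 3)[, rep(1, nx)]  # identical columns
  b2 <- b1 * exp(1i * outer(0.05 * seq_len(nz), rep(1, nx)))
  st <- make_stack(list(b1, b2))
  a1 <- Arg(interframe_xcorr(st, processing_params(w_z = 4, w_x = 1))[, 5, 1])
  a2 <- Arg(interframe_xcorr(st, processing_params(w_z = 4, w_x = 2))[, 5, 1])
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("segmentation finds three-plateau boundaries and rejects degenerate profiles", {
  nz <- 300
  prof <- c(rep(0.02, 40), rep(1.0, 70), rep(0.55, 120), rep(1.0, 50),
            rep(0.02, 20))
  opt <- optics_config(n_z = nz, n_x = 8, n_frames = 2)
  m <- segment_regions(prof, opt)
  expect_equal(m$lens_top, 41, tolerance = 3)
  expect_equal(m$boundary_ant_nuc, 111, tolerance = 3)
  expect_equal(m$boundary_nuc_post, 231, tolerance = 3)
  expect_equal(m$lens_bottom, 280, tolerance = 3)
  expect_true(m$lens_top < m$boundary_ant_nuc &&
              m$boundary_ant_nuc < m$boundary_nuc_post &&
              m$boundary_nuc_post < m$lens_bottom)
  expect_error(segment_regions(rep(1, nz), opt), "flat")
  flatlens <- c(rep(0.02, 40), rep(1, 240), rep(0.02, 20))
  expect_error(segment_regions(flatlens, opt), "contrast")
})

test_that("region averaging is exact on piecewise-constant strain fields", {
  nz <- 120; nx <- 6
  eps <- array(0, dim = c(nz, nx, 3))
  eps[20:49, , ] <- 2e-3; eps[50:89, , ] <- 1e-3; eps[90:110, , ] <- 2e-3
  mask <- structure(list(lens_top = 20L, boundary_ant_nuc = 50L,
                         boundary_nuc_post = 90L, lens_bottom = 110L,
                         lateral_zone = 1:6),
                    class = "region_mask")
  rs <- region_series(eps, mask, processing_params(), erode_px = 0)
  expect_equal(unique(rs$eps_ant), 2)   # permille
  expect_equal(unique(rs$eps_nuc), 1)
  expect_equal(unique(rs$eps_post), 2)
  # spatially uniform field: all three series constant and equal
  epsu <- array(5e-4, dim = c(nz, nx, 3))
  rsu <- region_series(epsu, mask, processing_params())
  expect_true(all(abs(unlist(rsu[c("eps_ant", "eps_nuc", "eps_post")]) - 0.5)
                  < 1e-12))
  # empty region errors
  bad <- mask; bad$boundary_ant_nuc <- bad$lens_top
  expect_error(region_series(eps, bad, processing_params()), "empty")
})

test_that("oscillation fit recovers amplitudes, delay sign and the cortical:nuclear ratio", {
  t <- seq_len(160) / 33
  mk <- function(amp, lag_s) amp * sin(2 * pi * (t - lag_s))
  series <- data.frame(time_s = t,
                       eps_ant = mk(2.46, 0), eps_nuc = mk(2.0, 5 / 33),
                       eps_post = mk(2.46, 0))
  s <- amplitude_and_delay(series, drive_freq_hz = 1, cumulative = TRUE)
  expect_equal(s$amp_ant_permille, 2.46, tolerance = 1e-6)
  expect_equal(s$amp_nuc_permille, 2.0, tolerance = 1e-6)
  expect_equal(s$strain_ratio_cortex_nucleus, 1.23, tolerance = 1e-6)
  # nucleus lagging 5 frames at 33 Hz: -151.5 ms
  expect_equal(s$delay_nuc_ms, -1000 * 5 / 33, tolerance = 1e-6)
  # identical series: zero delay
  same <- data.frame(time_s = t, eps_ant = mk(1, 0), eps_nuc = mk(1, 0),
                     eps_post = mk(1, 0))
  expect_equal(amplitude_and_delay(same, 1, cumulative = TRUE)$delay_nuc_ms,
               0, tolerance = 1e-9)
  # flat nucleus: delay undefined, flagged, not fabricated
  flat <- data.frame(time_s = t, eps_ant = mk(1, 0),
                     eps_nuc = rep(0, length(t)), eps_post = mk(1, 0))
  sf <- amplitude_and_delay(flat, 1, cumulative = TRUE)
  expect_false(sf$delay_defined)
  expect_true(is.na(sf$delay_nuc_ms))
  # too short for 2 periods
  expect_error(amplitude_and_delay(series[1:40, ], 1, cumulative = TRUE),
               "periods")
})

test_that("macroscopic check compares lens-average strain to the imposed stroke", {
  nz <- 100; nx <- 4; nf <- 99
  mask <- structure(list(lens_top = 1L, boundary_ant_nuc = 40L,
                         boundary_nuc_post = 70L, lens_bottom = 99L,
                         lateral_zone = 1:4),
                    class = "region_mask")
  # all-zero strain with nonzero stroke: deviation exactly 1
  zeros <- array(0, dim = c(nz - 1, nx, nf))
  expect_equal(macroscopic_check(zeros, mask, 68, 5.4), 1)
  expect_error(macroscopic_check(zeros, mask, 0, 5.4), "stroke")
  # uniform sinusoidal compression at the exact theoretical amplitude
  t <- seq_len(nf) / 33
  amp <- (34 / 5400)  # (stroke/2) / LT_test
  inc <- diff(c(0, amp * sin(2 * pi * t)))
  eps <- array(rep(inc, each = (nz - 1) * nx), dim = c(nz - 1, nx, nf))
  attr(eps, "optics") <- optics_config(n_z = nz, n_x = nx, n_frames = nf + 1)
  expect_lt(macroscopic_check(eps, mask, 68, 5.4, drive_freq_hz = 1), 0.02)
})
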