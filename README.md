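# lenselast

Quantitative compression optical coherence elastography (OCE) and inverse
mechanical characterisation of the *ex vivo* crystalline lens, in R.

Storage of donor lenses — refrigeration, culture medium, freezing — changes
their mechanics, and because the lens is mechanically graded (a stiff
nucleus inside a softer cortex) the change is region-specific: macroscopic
stiffness tests can miss it entirely. This package implements the full
analysis chain used to resolve such changes with depth-resolved strain
imaging, for researchers in ocular biomechanics and for anyone who needs a
tested, seeded reference implementation of phase-sensitive compression OCE
with inverse parameter identification:

* **Synthetic data generation** (`make_group_preset`, `sample_lens`,
  `render_bscan_stack`, `synth_force_trace`, `synth_lens_dataset`) —
  complex-valued 256-frame B-scan stacks at 33 Hz with fully developed
  speckle, displacement-encoded interframe phase from a sinusoidal
  micro-compression on a 33% pre-strain, and noisy force-relaxation traces
  in gram-force. Six presets emulate the preservation conditions of a
  porcine-lens storage study (fresh, de-cap, fridge8, MEM8, frozen20,
  frozen80).
* **Phase-sensitive strain estimation** (`interframe_xcorr`,
  `displacement_from_phase`, `strain_from_xcorr`, `segment_regions`,
  `region_series`, `amplitude_and_delay`, `macroscopic_check`) — the
  complex cross-correlation vector method: displacement
  `dz = lambda * angle(R) / (4 pi n(z))` and strain as the windowed phase
  gradient `eps_z = lambda * angle(sum R(z+1) R*(z)) / (4 pi asu)`, which
  is independent of the refractive index; reflectivity-based segmentation
  into anterior cortex, nucleus and posterior cortex; per-region
  oscillation amplitudes (permille) and the nucleus phase delay (ms).
* **Forward mechanics** (`lens_layers`, `nh_uniaxial_stress`,
  `relaxation_modulus`, `to_linear_modulus`, `simulate_test`) — a quasi-1D
  series composite of incompressible Neo-Hookean layers
  (`sigma = 2 C10 (lambda^2 - 1/lambda)`, `E = 6 C10`) with a
  quasi-linear-viscoelastic nucleus
  (`C10(t) = C10_0 (1 - g1 (1 - exp(-t/tau1)))`, `g1 = 0.25`), a graded
  cortical stiffness profile `C10_n = C10_inf / (N F^n)`, and the full
  ramp-hold-oscillation protocol with force output in gf.
* **Inverse identification** (`build_factorial`, `run_design`, `fit_sse`,
  `optimize_fit`, `calibrate_scale`, `goodness_r2`) — full-factorial
  response surfaces over thickness, tau1, F and N; a standardized SSE over
  the measured amplitudes and delay; surrogate-seeded, simulator-verified
  optimisation; absolute modulus scale from the post-relaxation force.
* **Study orchestration and statistics** (`pipeline_config`,
  `run_pipeline`, `compare_groups`, `correlate_metrics`) — seeded
  end-to-end group studies with normality-gated (Shapiro-Wilk) parametric
  or non-parametric comparisons, Bonferroni correction, and Spearman
  correlations.

See the methods vignette (`vignettes/lens-oce-methods.Rmd`) for the models,
their assumptions, numerical policies and declared limitations.

## Worked example

Generate one fresh-preset lens, process its B-scan stack, and compare the
estimated oscillation against the generating model:

```r
library(lenselast)

preset <- make_group_preset("fresh")
geom   <- lens_geometry(lt0_mm = preset$lt0_mm, lt_test_mm = preset$lt_test_mm)
optics <- optics_for_geometry(geom, n_x = 8, n_frames = 160)   # 9.5 um sampling
prot   <- compression_protocol(hold_s = 60, dt_s = 1/33, osc_s = 160/33)
ds  <- synth_lens_dataset(preset, seed = 42, optics = optics, protocol = prot)
oce <- oce_process(ds$stack, drive_freq_hz = 1.0)
oce$summary
#> Oscillation: amp ant 7.51 / nuc 5.41 / post 7.2 permille, ratio 1.36, delay -6.1 ms
amplitude_and_delay(ds$truth$sim$region_strain_series, 1, 33, cumulative = TRUE)
#> Oscillation: amp ant 7.73 / nuc 5.5 / post 7.45 permille, ratio 1.38, delay -6.1 ms
```

The estimator reads back the generating model: cortical strain amplitudes
of about 7.4 permille against 7.7 in the model (the small deficit is the
documented speckle-estimator bias), the nuclear amplitude of 5.4 permille
within 2%, the cortex:nucleus strain ratio near 1.36, and a nucleus that
lags the cortex by about 6 ms — the viscoelastic signature of the nucleus.

Inverse identification on a coarse response surface then recovers the
material parameters from such summaries and calibrates their absolute
scale against the relaxed force (5.01 gf at the end of this lens's hold):

```r
surf <- run_design(coarsen_design(build_factorial("fresh"), c(2, 4, 4, 3)),
                   prot, geom)
fit  <- optimize_fit(surf, as_observed(oce$summary), n_starts = 3)
calibrate_scale(fit, observed_min_force_gf = 5.01, geom, prot)
#> Fit 'fresh': thickness 7.78 mm, tau1 1.01 s, F 1.04, N 0.878 | nucleus:cortex E-ratio 1.04, SSE 0.004306
#>   absolute C10_nuc_inf = 1.31 kPa
```

This lens was drawn with tau1 = 1.015 s and C10 = 1.066 kPa: the
relaxation time comes back within 1%, and the absolute modulus within
about 25% — limited here by the sampled thickness (7.94 mm) sitting just
outside the design's thickness grid (7.1-7.8 mm), a clipping the fit
reports rather than hides.

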