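---
title: "Methods: compression OCE and inverse identification of lens mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compression OCE and inverse identification of lens mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lenselast` implements a complete, testable analysis chain for quantitative
compression optical coherence elastography (OCE) of the *ex vivo* crystalline
lens: a seeded generator of synthetic complex-valued B-scan stacks and force
traces, phase-sensitive strain estimation, a visco-hyperelastic forward model
of the compression test, and inverse parameter identification through a
full-factorial response surface. This vignette is the package's own account of
the science: the models, their assumptions, the tunable parameters, and the
limits of what the synthetic closed loop can and cannot demonstrate.

## The experiment being modelled

A lens is compressed between two glass lamellae to a fixed test thickness
(5.4 mm with capsule, 4.4 mm after decapsulation; about 33% engineering
pre-strain), held there while the reaction force relaxes, and then subjected
to a sinusoidal micro-compression (68 µm peak-to-peak, offset 2 µm towards
compression, spanning −32 to +36 µm of lamella excursion) while 256 B-scans
are recorded at 33 Hz. The oscillation frequency of the drive is a free
configuration parameter; the default is 1.0 Hz, chosen so that the 33 Hz
frame rate samples each cycle 33 times and an acquisition covers several
cycles. Forces are recorded in gram-force (1 gf = 9.8 mN).

Six preservation conditions are represented as generator presets (`fresh`,
`de-cap`, `fridge8`, `MEM8`, `frozen20`, `frozen80`), with sample sizes,
undeformed thicknesses, and material centres chosen so that the simulated
observables reproduce the documented group-level pattern: freezing at −20 °C
alters the strain distribution the most (higher cortical, lower nuclear
amplitude, larger nucleus delay), −80 °C the same direction but milder, and
refrigeration the least.

## Phase-sensitive strain estimation

The displacement that occurs between two consecutive B-scans is encoded in
the phase of the windowed complex cross-correlation

$$R_s(z, x) = \sum_{j=-w_z}^{w_z} \sum_{k=-w_x}^{w_x}
  B_s(z+j, x+k)\, B_{s+1}^{*}(z+j, x+k),$$

with window half-sizes $w_z = 10$, $w_x = 1$ pixels. The axial displacement
follows as $\Delta z = \lambda \angle R / (4\pi n(z))$ with
$\lambda = 1200$ nm; it is valid while the interframe phase stays below
$\pi$, i.e. $|\Delta z| < \lambda/(4n) \approx 201$ nm per frame pair.

Axial strain is the depth gradient of that phase, computed as a second
windowed cross-correlation between the first correlation field and its copy
shifted by one depth pixel ($v_z = 15$, $v_x = 1$):

$$\varepsilon_z = \frac{\lambda\,\angle \sum_v R_s(z+1)\,R_s^{*}(z)}
  {4\pi\,\mathrm{asu}},$$

with asu = 9.5 µm the axial pixel pitch in air. Two conventions had to be
fixed where the algebra admits either sign, and both are enforced by test:
the first correlation is $B_s B_{s+1}^{*}$ (a pure global phase advance
$\varphi_0$ between frames yields $\angle R = -\varphi_0$), and the second
correlation conjugates the *unshifted* field, so that phase increasing with
depth yields positive strain and compression (thickness decreasing) yields
negative strain.

Two properties are worth emphasising:

* **Refractive-index independence.** The phase-per-pixel gradient scales
  with $n(z)$ while the physical pixel size scales with $1/n(z)$; the two
  cancel, so the strain map depends only on the axial sampling unit in air.
  The package tests this bitwise: changing $n(z)$ leaves the strain output
  identical.
* **Wrapping.** The *absolute* interframe phase wraps for realistic lamella
  strokes (a 1 Hz, 68 µm stroke moves the deep lens by several wavelengths
  per frame); this is harmless for strain, which only requires the axial
  phase *gradient* to stay below $\pi$ per pixel (about 3.2% strain at
  9.5 µm sampling). The renderer enforces the gradient bound always and the
  absolute bound only when displacement maps are requested.

Strain fields are averaged over a 2.3 mm lateral zone centred on the apex
column. Region averages use the magnitude-weighted circular mean of the
complex second-correlation field rather than the arithmetic mean of
per-pixel angles: dark speckle pixels carry uniformly distributed phase
noise, and with a handful of lateral columns a single such pixel can
otherwise dominate a region series. Regions are eroded by $w_z + v_z$
pixels at their boundaries before averaging so that windows do not mix
adjacent regions.

Anterior cortex, nucleus and posterior cortex are segmented from the mean
depth-reflectivity profile: the lens span is the longest run above an
adaptive threshold (after boxcar smoothing and closing of short
speckle-induced gaps), and the two interior boundaries minimise the
residual of an exhaustive three-plateau piecewise-constant fit. A profile
without detectable lens or without cortex/nucleus contrast is rejected, not
guessed.

Per-region oscillation summaries come from a least-squares sinusoid fit at
the known drive frequency (with intercept and linear-drift terms).
Incremental per-frame-pair series are cumulated before fitting, so
amplitudes are physical strain amplitudes in permille. The nucleus delay is
the wrapped phase difference between nucleus and cortex (circular mean of
anterior and posterior phases) divided by the angular drive frequency;
negative values mean the nucleus lags. When a region's amplitude is
numerically zero the delay is flagged undefined rather than fabricated.

### Estimator fidelity

The estimator is speckle-limited. With fully developed speckle the
windowed phase-gradient estimate carries a small multiplicative bias
(about −1.5% at 9.5 µm sampling and permille-scale strains, growing with
the phase gradient) and per-pixel noise that averages out over the lateral
zone. The test suite therefore checks two levels of the oracle: exact
per-pixel recovery on a deterministic-amplitude phantom
(`render_bscan_stack(speckle = FALSE)`), which isolates the algorithm, and
recovery within 2% of the zone-averaged strain on speckle phantoms, which
is what the real processing chain achieves.

## Forward model: a quasi-1D visco-hyperelastic series composite

The published analysis of this experiment used a 2D axisymmetric finite
element model with hard frictionless contact. This package deliberately
replaces it with a quasi-1D axial series composite: the lens is a stack of
layers between flat plates — capsule (60 µm per face, elastic Neo-Hookean,
$C_{10} = 0.166$ MPa $\approx$ 1 MPa Young's modulus), nine anterior and
six posterior cortical layers (elastic), and an incompressible
visco-hyperelastic nucleus. At every time step all layers carry the same
axial Cauchy stress and the layer stretches partition the imposed lamella
gap: $\sum_i h_i \lambda_i = LT(t)$. The rationale: the measured observable
is depth-resolved *axial* strain along the compression axis, and the
quantities entering the inverse fit — relative region amplitudes, their
ratios, and the viscoelastic delay — are captured by the axial force
balance, while barreling and radial bulge are declared out of scope.

Each elastic layer follows the incompressible Neo-Hookean uniaxial stress
$\sigma = 2C_{10}(\lambda^2 - 1/\lambda)$ (lateral stretch
$\lambda^{-1/2}$), whose small-strain tangent is the Young's modulus
$E = 6C_{10}$ (via $\mu = 2C_{10}$, $E = 3\mu$).

The cortical stiffness profile is parameterised by a form factor $F$ and a
nucleus factor $N$: layer $n$ (counting from the nucleus outwards, 9
anterior, 6 posterior) has

$$C_{10,n} = \frac{C_{10\text{-}N\infty}}{N\,F^{\,n}}.$$

With $F > 1$ the cortex grades softer towards the surface and the
nucleus-to-mean-cortex stiffness ratio increases monotonically in both $F$
and $N$. The printed form of this rule in the source literature
($C_{10,n} = N F^n C_{10\text{-}N\infty}$) would make the outer cortex
orders of magnitude stiffer than the nucleus, contradicting the same
study's reported nucleus:cortex ratios above one; the reciprocal rule is
therefore the default, and the printed variant is retained as
`eq4_variant = "printed"` for auditability.

The nucleus relaxes with a one-term Prony series,
$C_{10}(t) = C_{10}^{0}\,(1 - g_1(1 - e^{-t/\tau_1}))$, with $g_1 = 0.25$
fixed across conditions (to curb overfitting) and $\tau_1$ free. Stress
follows quasi-linear viscoelasticity: the reduced relaxation applies to the
full instantaneous Neo-Hookean stress via a hereditary integral, which the
solver realises as a recursive exponential internal-variable update that is
exact for piecewise-linear stress histories. The imposed thickness history
is a 1 s linear ramp (the ramp rate is not documented; a 1 s default is
used), a hold of 120 s (short protocol) or 1800 s (long), then the
sinusoidal micro-compression. Region strains are engineering strains
relative to the configuration at the end of the hold, in permille, so the
oscillating component is directly comparable with the OCE output. Force is
the common axial stress times a nominal contact area
($\pi (2.5\,\mathrm{mm})^2$ by default — a pure force-scale calibration
constant, since the contact patch is not documented), converted to
gram-force.

Numerical policy: the scalar stress at each step is found by a
Newton-with-bracketing iteration whose inner per-layer stretch inversion is
a safeguarded vectorised Newton on the monotone cubic
$2C_{10}\lambda^3 - \sigma\lambda - 2C_{10} = 0$; thickness is conserved to
$10^{-9}\,LT_0$ and stress balance holds to $10^{-6}$ by construction at
every accepted step. The hold uses a geometric time grid (the QLV update is
exact for constant stretch), the ramp and oscillation a uniform grid tied
to the frame rate; halving the step changes oscillation amplitudes by less
than 0.5%.

## Synthetic data generation

Each lens is drawn around its preset centre: thickness normal, moduli and
shape factors log-normal, with a 4% between-sample coefficient of
variation — comparable to the relative group spreads of the study the
presets emulate. All randomness flows from one integer seed per dataset;
identical seeds give bit-identical stacks and traces.

The forward simulation's layer-interface motion is interpolated onto the
pixel grid, differenced between frames, and encoded as interframe phase on
a fully developed speckle field (complex circular Gaussian per pixel,
variance set by a three-plateau reflectivity profile that follows the
compressed-configuration region boundaries; background 0.02, cortex 1.0,
nucleus 0.6). An optional multiplicative phase noise stresses the
estimator; force traces get additive Gaussian noise in gf.

**Preset calibration.** Preset centres were fixed once against the printed
group-level observables of the emulated study — the quantities the inverse
fit actually consumes: cortical:nuclear strain-amplitude ratios near
1.23 (fresh), 1.70 (frozen80) and 2.59 (frozen20), nuclear and cortical
amplitude shifts in the reported directions, group maximum forces
(5.35-11.0 gf), and thickness shifts (+1.27 mm frozen20, −1.46 mm
decapsulated). Frozen presets use a relaxation time near
$1/(2\pi f_\text{drive})$ so their nucleus delay is maximally expressed at
the default drive frequency. Two scale differences against the emulated
study are declared rather than hidden:

* In a series composite the strain-amplitude ratio and the stiffness ratio
  are tied (strain follows tangent compliance), so matching the strain
  ratios forces simulated nucleus:cortex E-ratios of roughly 0.9/1.4/2.7
  (fresh/frozen80/frozen20) instead of the published 3.3/4.06/7.06; a 2D
  model decouples the two through lateral bulging. The *ordering* across
  conditions is preserved and is what the directionality suite asserts.
* A one-term Prony nucleus with $g_1 = 0.25$ caps the attainable phase lag
  well below the published −130 to −180 ms at a 1 Hz drive (whose true
  frequency is undocumented); generator delays are −6 to −17 ms with the
  correct ordering and near-equality of the two frozen groups.

## Inverse identification

Because the test is strain-controlled, the oscillation observables
constrain only stiffness *ratios*; the absolute scale comes second. The
identification pipeline is:

1. **Full factorial design** per condition over thickness, $\tau_1$, $F$
   and $N$. `build_factorial(ranges = "table")` reproduces the published
   grids verbatim (e.g. fresh: thickness {7.1, 7.4, 7.55, 7.8} mm,
   $\tau_1$ {0.25...7.5} s, $F$ 1.0-3.0 by 0.25, $N$ 0.65-1.05 by 0.05;
   2268 combinations; the de-cap $F$ row "1.0 to 4.0 by 0.4" is generated
   start-by-increment and stops at 3.8). The published frozen $F$ range
   (2.0-6.0) presupposes the 2D model; under the quasi-1D rule it forces
   strain ratios above 5 and cannot cover the frozen observables, so
   `ranges = "screening"` re-applies the published screening principle
   (cover each condition's observed behaviour) to this model, re-spanning
   only the frozen $F$ (1.0-2.0 by 0.1) and $N$ (0.85-1.15) rows. The
   pipeline fits on the screening ranges; the table ranges remain the
   default elsewhere.
2. **Response surface.** One forward simulation per combination records
   the predicted anterior/posterior/nuclear amplitudes and nucleus delay
   ($\kappa, \lambda, \mu, \nu$); failed rows are flagged, never silently
   dropped. A quadratic polynomial with pairwise interactions is fitted
   per output — amplitudes on the log scale (they vary over decades across
   the $F$ grid), $\tau_1$ as $\log\tau_1$ (the response is governed by
   $\omega\tau_1$), squared terms dropped for factors with fewer than
   three levels. Surrogate $R^2$ per output is reported with the surface.
3. **SSE objective.** $\mathrm{SSE} = \sum ((\alpha-\kappa)/s_1)^2 +
   ((\beta-\lambda)/s_2)^2 + ((\gamma-\mu)/s_3)^2 + ((\delta-\nu)/s_4)^2$,
   each component standardised by the observed condition spread (group
   SDs when several lenses are fitted; the design-row spread as proxy for
   a single lens) so "equal weight" is meaningful across permille and
   milliseconds. Missing components (undefined delay) are dropped.
4. **Optimisation.** An exact scan over the stored design rows seeds a
   box-constrained quasi-Newton refinement on the surrogate; a
   derivative-free Nelder-Mead polish then evaluates the true simulator
   (the surrogate proposes, the simulator decides), and each candidate is
   only accepted on a genuine SSE improvement. Results are clipped to the
   design ranges and flagged when they land on a boundary.
5. **Scale calibration.** A second round matches the simulated
   post-relaxation force to the observed condition-mean minimum force;
   force is exactly linear in the modulus scale at fixed kinematics, so
   one multiplicative factor yields the absolute
   $C_{10\text{-}N\infty}$, and $E = 6C_{10}$ converts ratios to Young's
   moduli.

**Identifiability.** The four observables constrain the stiffness-ratio
combination of $F$ and $N$ much more strongly than either parameter
separately: noise-free fits can wander along an $F$-$N$ ridge whose SSE is
numerically near zero while recovering $\tau_1$, thickness and the
nucleus:cortex E-ratio well. Excluding the delay from the SSE degrades
$\tau_1$ recovery measurably — the delay is the information carrier for the
relaxation time. Both behaviours are exercised in the test suite rather
than hidden.

## Statistics

Group comparisons follow a single normality-gated policy: Shapiro-Wilk per
group at $\alpha = 0.05$; if all groups are compatible with normality,
one-way ANOVA and Student's t pairwise, otherwise Kruskal-Wallis and
Wilcoxon rank-sum. Pairwise p-values are Bonferroni-adjusted over all
pairwise comparisons of one metric across the configured groups
($p_\text{adj} = \min(1, m\,p)$). Constant within-group data make the
normality test undefined; the non-parametric family is then used and
recorded. Correlations (e.g. thickness against maximum force) are
Spearman rank correlations with two-sided p-values.

## Problem sizes and reproducibility

The full acquisition geometry (9.5 µm axial sampling, 256 frames, 66-column
lateral zone) is the generator default. The test-suite and worked examples
run the same chain at reduced sizes chosen as a deliberate design point —
160-frame stacks, 8 lateral columns, 60 s holds, response surfaces
coarsened to 2-4 levels per factor, 3 lenses per group — which keeps a
complete end-to-end study in the minutes range on one core while exercising
every stage at the true axial sampling. Every output is reproducible from
the configuration seed; per-lens seeds are derived deterministically from
it.

## Known limitations

* No lateral/2D strain estimation, no phase unwrapping beyond the validity
  bound, no modelling of OCT roll-off, dispersion or galvo artifacts, no
  optical ray tracing (flat-lamella compression induces no geometric
  distortion).
* The quasi-1D composite cannot represent barreling, radial bulge, capsule
  pre-tension, or the decoupling of strain ratios from stiffness ratios
  that a 2D contact model provides; absolute E-ratio magnitudes are
  therefore not comparable with 2D-model results (orderings are).
* The speckle model is fully developed speckle with optional phase noise;
  real decorrelation from lateral motion or flow is not modelled, so
  passing tests bound estimator behaviour under ideal speckle statistics
  only.
* Statistics on 3-lens groups are power-limited by design; the package's
  group comparisons are contracts about the machinery, not claims about
  biological effect sizes.
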