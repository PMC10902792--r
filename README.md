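# flimmc

Monte Carlo simulation and phasor analysis of time-gated fluorescence
lifetime imaging (FLIM) in turbid media.

## What problem this addresses

Near-infrared fluorescence lifetime imaging can, in principle,
distinguish two dyes with similar emission spectra inside tissue by
their decay times alone — multiplexing by lifetime instead of by color.
Whether that works behind millimeters to a centimeter of scattering,
absorbing tissue, imaged wide-field with a time-gated SPAD array,
depends on the interplay of dye quantum yield, tissue optics, depth,
lateral separation, and the statistics of photon-starved pixels.

`flimmc` is a tool for studying exactly that question by simulation. It
is aimed at researchers designing NIR FLIM experiments (dye pairs such
as ICG and IRDye800, time-gated cameras at tens of MHz repetition
rates) who want to know, before building anything, whether two
lifetimes 0.35 ns apart can be told apart at a given depth and
separation — and at analysts who want a controlled sandbox for
phasor-based lifetime extraction at low photon counts.

## The model and the statistic

**Forward model.** Fluorescence photons (excitation is not modeled) are
emitted isotropically by a point source at depth `z` in a homogeneous
semi-infinite slab (`n = 1.4`, `mu_a = 0.4 /cm`, `mu_s = 300 /cm`,
Henyey–Greenstein `g = 0.96` by default), random-walk with exponential
hops, binary absorption/scattering fates, and exit through the top
surface onto a pixelated detector (512×512, 13% photon efficiency) in
contact with the tissue. The emission decay is sampled at the gate
times `t_k = (k−1)·428 ps` (117 gates, zero gate width):
`N(t_k) = round(A·exp(−t_k/τ))`, `A = round(a·QY)`, and each photon is
recorded in the gate it was emitted in.

**Analysis.** Each pixel's gate trace `F(t_k)` is condensed to a phasor
at the harmonic `f` = laser repetition rate (20 MHz),

    g = Σ F(t_k) cos(2πf t_k) / Σ F(t_k),   s = Σ F(t_k) sin(2πf t_k) / Σ F(t_k),

calibrated by a single complex factor mapping a simulated reference dye
(ICG-like, τ = 0.65 ns) onto its theoretical semicircle position, and
converted to a phase lifetime `τ_φ = tan(atan2(s, g)) / 2πf`. Per-pixel
lifetimes feed a histogram; a symmetric percentile **cutoff** removes
extreme values; single-dye lifetimes are read out as histogram means
(and, robustly at low counts, as the pooled-phasor aggregate), and
two-dye scenes are unmixed from the pixels of each dye's intensity spot
after the cutoff (`multiplex_lifetimes()`), with classic
histogram-peak and Gaussian-mixture extractors also available.

## Worked example

Simulate the IRDye800-like dye (τ = 1 ns, QY 1.3%) at 3 mm depth, at 5%
of the full photon budget, and recover its lifetime with a simulated
ICG-like reference:

```r
library(flimmc)
scene <- paper_scene("irdye800_single", z = 0.3)
stack <- simulate_scene(scene, seed = 42, scale = 0.05)
ref   <- simulate_gate_stack(
  fluorophore(0.65, 0.009, 7.6e7, source_position(0, 0, 0.3), "ICG-like"),
  scene$optics, scene$detector, scene$gates, scale = 0.05)
fit <- phasor_flim(stack, ref_tau = 0.65, ref = ref, components = "one")
fit
aggregate_lifetime(fit$field)
spot_summary(stack, center = c(0, 0))
```

```
Phasor FLIM fit
  4013 pixels in histogram (4013 after 0% cutoff)
  mean phase lifetime: 1.025 ns
[1] 0.988
Spot summary: <I> = 0.01551 counts/px, <R> = 0.264 cm, 4,066 photons, z = 0.3 cm
```

About 4,000 of the ~1.4 million emitted photons survive absorption,
escape within the detector footprint and pass the 13% efficiency
thinning. The per-pixel histogram mean (1.025 ns) runs slightly high —
most pixels hold a single photon, where the tangent transform is
convex — while the pooled-phasor aggregate recovers 0.988 ns; at full
budget both converge on 1.00 ns. The spot statistics say each frame
pixel averages 0.016 counts and the photon cloud has a 2.6 mm mean
radius — the quantities that shrink and grow, respectively, as the
source moves deeper.

Higher-level drivers run whole studies in one call:
`single_dye_depth_series()`, `two_dye_depth_series()`,
`two_dye_separation_series()`, `spot_depth_series()`, and
`run_pipeline()` for config-file-driven runs (also exposed by the
`exec/flimmc` command line: `simulate`, `analyze`, `stats`,
`multiplex`, `fixtures`, `run`).

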