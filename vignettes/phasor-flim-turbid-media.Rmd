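---
title: "Simulating and analyzing time-gated FLIM in turbid media"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing time-gated FLIM in turbid media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`flimmc` couples a deliberately simple Monte Carlo model of
fluorescent-photon transport in tissue with the phasor analysis used for
time-gated, wide-field fluorescence lifetime imaging (FLIM). Its purpose
is to study how well the fluorescence lifetimes of near-infrared dyes --
and in particular of *two* dyes sharing one image -- can be recovered
from behind increasing thicknesses of scattering, absorbing medium with
a time-gated SPAD array. This vignette documents the model, its
assumptions and parameters, the estimators, and the numerical and design
choices, in enough detail to judge what the package's passing tests do
and do not demonstrate.

## The forward model

The simulator tracks *emitted fluorescence photons only*. Excitation
transport, the instrument response function, and overlapping-gate
integration are all outside the model; these omissions are what make the
simulation fast, and they define its scope.

A fluorophore is an isotropic point source at depth $z$ inside a
homogeneous, semi-infinite slab (unbounded laterally and below, air
above the plane $z = 0$) with refractive index $n$, absorption
coefficient $\mu_a$, scattering coefficient $\mu_s$ and
Henyey-Greenstein anisotropy $g$. Each photon performs the standard
random walk:

* hop lengths are exponential with mean free path $1/(\mu_a + \mu_s)$;
* at each interaction the photon is **absorbed** with probability
  $\mu_a/(\mu_a+\mu_s)$, otherwise **scattered** into a new direction
  drawn from the Henyey-Greenstein distribution with mean cosine $g$;
* a hop crossing the surface is advanced exactly to the plane, where the
  photon escapes -- optionally after an unpolarized Fresnel /
  total-internal-reflection test against the air index.

Whole photons are tracked, never fractional statistical weights: the
paper-and-pencil bookkeeping (emitted = absorbed + escaped) stays exact
and detector counts remain integers. With $\mu_a > 0$ every walk
terminates; a hard cap of $10^6$ interactions per photon (configurable)
guarantees termination in the absorption-free limit, and photons hitting
the cap are reported as truncated rather than silently dropped.

Two surface rules are available. `tissue_optics(fresnel = TRUE)` (the
constructor default) applies the physically complete Fresnel/TIR test,
under which internally reflected photons re-enter and widen the exit
halo. The reproduction scenes (`paper_scene()` and the `*_series()`
functions) instead use `fresnel = FALSE` -- a photon reaching the
surface simply exits there. This matches the simplified exit rule the
simulation is meant to emulate ("absorbed or exited"), keeps the
intensity spots more compact, and is the single switch with the largest
effect on how strongly two neighbouring spots bleed into each other at
depth.

### Emission, gating, and detection

The decay is sampled at the gate times $t_k = (k-1) g_s$, $k = 1 \dots
G$, with zero gate width: the number of photons emitted at sample $k$ is

$$N(t_k) = \mathrm{round}\!\big(A\, e^{-t_k/\tau}\big), \qquad
  A = \mathrm{round}(a \cdot QY),$$

where $a$ is the initial photon budget, $QY$ the quantum yield and
$\tau$ the fluorescence lifetime. Rounding is round-half-to-even, which
is unbiased across gates. Every photon emitted at sample $k$ that
escapes onto the detector is recorded in gate page $k$ **regardless of
its time of flight in the tissue**: gates sample the emission decay, not
the arrival-time distribution. Path lengths are kept in the photon
records for diagnostics but never shift gates. This is the model's
central simplification; it is accurate as long as transport times
(tens of picoseconds) are small against the gate step (428 ps).

The detector is a pixelated rectangle in the surface plane in contact
with the tissue: an escaping photon's exit point is binned to the
enclosing pixel (no lens model), and each photon is kept independently
with probability equal to the photon efficiency (Bernoulli thinning, so
counts stay integral and Poisson-like; a deterministic multiplier would
match only the expectation).

### Default parameters

| quantity | symbol | default | unit |
|---|---|---|---|
| refractive index | $n$ | 1.4 | -- |
| absorption | $\mu_a$ | 0.4 | cm$^{-1}$ |
| scattering | $\mu_s$ | 300 | cm$^{-1}$ |
| anisotropy | $g$ | 0.96 | -- |
| gates | $G$ | 117 | -- |
| gate step | $g_s$ | 428 | ps |
| repetition rate | $f$ | 20 | MHz |
| detector | -- | 1 x 1 cm, 512 x 512 px | -- |
| photon efficiency | $PE$ | 13 | % |

These describe strongly pigmented skin-like tissue in the near infrared
around 800 nm and a large time-gated SPAD array. The dye presets are an
ICG-like dye (0.65 ns, QY 0.9%), an IRDye800-like dye (1.0 ns, 1.3%),
and two brighter hypothetical dyes (0.8 ns / 18%, 1.1 ns / 28%). Photon
budgets are $a = 5\times10^6$ for the single-dye characterization
scenes and $a = 7.6\times10^7$ for the intensity and multiplexing
scenes. A single `scale` factor multiplies every budget for scaled-down
runs.

A note on the literature this mirrors: the source text gives
$\mu_s = 300\,\mathrm{cm}^{-1}$ in its parameter caption but elsewhere
mentions $\mu_s = 403\,\mathrm{cm}^{-1}$ as the value its robustness run
deviated from. The caption value is the default here; any value is
reachable through `tissue_optics()`.

### Two-dye scenes

A two-dye scene places the short-lifetime dye at $x = -\Delta x/2$ and
the long-lifetime dye at $+\Delta x/2$, both at equal depth. The
detector images the whole two-spot field: 512 x 512 pixels over a 4 x 4
cm field of view (78 um effective pitch), centered between the sources.
With separations of 1-2 cm, imaging both spots at the camera's native
512 x 512 format necessarily means a coarser effective pitch than the
1-cm contact geometry; analyzing the full two-spot frame (rather than
only the sliver of pixels between the spots) is also what gives the
per-pixel histograms enough signal to be interpretable. The narrow
inter-spot ROI alternative was examined and rejected: at any realistic
budget it collects almost exclusively single-photon pixels, whose
discrete phase-lifetime values are identical for both dyes (see below),
so no analysis could separate the components there.

## Phasor analysis

For each pixel with decay trace $F(t_k)$ the phasor at harmonic $f$
(equal to the laser repetition rate, $f = 1/T$) is

$$g = \frac{\sum_k F(t_k)\cos(2\pi f t_k)}{\sum_k F(t_k)}, \qquad
  s = \frac{\sum_k F(t_k)\sin(2\pi f t_k)}{\sum_k F(t_k)}.$$

The angular argument is $2\pi f t_k$ -- frequency times gate time, the
only dimensionally consistent reading of the discretized transform; the
run log records this interpretation alongside the calibration reference
so the two conventions that commonly differ between implementations are
always explicit.

Phase and modulation are $\varphi = \mathrm{atan2}(s, g)$ and
$m = \sqrt{g^2+s^2}$, and the phase lifetime is
$\tau_\varphi = \tan(\varphi) / 2\pi f$. Phases outside $[0, \pi/2)$
cannot arise from a physical single-harmonic decay; they are flagged
rather than wrapped, and excluded from histograms.

**Calibration.** A known reference (here: a *simulated* stack of the
0.65 ns ICG-like dye, simulated with the same budget and at the same
depth as the target scene) is measured through the identical gating.
The single complex factor mapping its aggregate phasor onto the
theoretical mono-exponential point $1/(1 - i\,2\pi f \tau_{ref})$ is
applied to every pixel. This removes the bias of finite, discrete
gating; after calibration, noiseless mono-exponential stacks land
exactly on the universal semicircle $(g-\tfrac12)^2 + s^2 = \tfrac14$.
The aggregate used is the *pooled* phasor -- the count-weighted mean,
identical to the phasor of the summed decay -- because the plain mean of
per-pixel phasors is unstable when pixels hold few photons.

### Estimators and the low-count regime

At the study's budgets most detected pixels hold one to a few photons,
and this drives every estimator choice in the package:

* A pixel holding a single photon recorded in gate $k$ has phasor
  exactly on the unit circle at angle $2\pi f t_k$, so its
  $\tau_\varphi$ falls on a fixed discrete grid of values (about 0.2,
  0.62, 1.05, 1.50, ... ns after calibration at the default gating).
  The histogram of a sparse image is therefore a comb, and -- crucially
  -- the comb positions are the *same for every dye*; only the weights
  along the comb differ. This reproduces the "discrete histogram"
  character of sparse simulated data and explains why single-photon
  pixels alone cannot separate two dyes.
* The *mean of per-pixel* $\tau_\varphi$ is biased upward at low counts
  (the tangent is convex on $[0,\pi/2)$) and has a heavy tail from
  pixels whose phase lands near $\pi/2$.
* The *aggregate* (pooled-phasor) lifetime applies the tangent after
  averaging and is unbiased at arbitrarily low per-pixel counts, at the
  price of having no spatial resolution.

Accordingly, the single-dye depth series reports the aggregate estimate
as its lifetime readout (`pooled_tau`), alongside the per-pixel
histogram mean (`mean_tau`); `extract_single_lifetime()` implements the
latter for histogram-level work. Only the aggregate estimator can be
depth-invariant at the deep-tissue photon counts of these scenes.

### The cutoff method and two-dye extraction

For two dyes in one image the per-pixel histogram is indispensable. The
percentile **cutoff** (`apply_cutoff()`) removes pixels whose
$\tau_\varphi$ lies below the $p$-th or above the $(100-p)$-th
percentile of the retained values -- a symmetric two-tail trim with $p$
per tail (the convention adopted here; the source text does not fix
one), with sample quantiles of the default type 7 and $p = 1$ as the
standard operating point.

`multiplex_lifetimes()` then exploits that the image decomposes into
two pure-dye areas and a mixing zone: after the joint cutoff, the
component lifetimes F1 and F2 are the mean retained $\tau_\varphi$ over
a disc of radius $\Delta x / 4$ around each source (discs at half the
inter-source distance can never overlap). At generous per-pixel counts
these region means coincide with the positions of the two histogram
peaks; in the sparse regime they remain well-defined while literal
peak-finding collapses onto the single-photon comb (whose tallest bar,
from first-gate photons, carries no lifetime information at all).
`extract_two_lifetimes()` provides the direct histogram route --
prominence-ranked local maxima after a 3-bin moving average, with a
0.1 ns minimum peak separation -- and an opt-in two-component
Gaussian-mixture alternative (`method = "gmm"`), fitting the "two
Gaussian components" picture of well-populated two-dye histograms.

## What the generators emulate -- and what they do not

`analytic_stack()` produces transport-free mono-exponential stacks
(exact expectations or Poisson draws over a Gaussian spot): these are
oracles for the phasor arithmetic, calibration closure and semicircle
properties, not models of tissue. `paper_scene()` +
`simulate_scene()` produce the full study conditions above.
`inject_background()` adds uniform Poisson dark counts so that the
cutoff-plus-time-window workflow can be exercised against a
background-swamped histogram, qualitatively emulating the dispersed
phasor cloud of real measurements.

None of the generators include: instrument response broadening,
overlapping 10 ns gates, detector dark-count *structure* (afterpulsing,
hot pixels), lens imaging, autofluorescence, or heterogeneous or layered
optics. Passing tests therefore demonstrate internal correctness of the
transport-plus-phasor chain and reproduction of the simulation-level
results, not performance on experimental camera data.

## Numerical choices

* Histogram bin width 0.01 ns, bins anchored at 0; peak positions are
  reported as bin centers.
* Percentile cutoff: two-tailed, `percent` per tail, quantile type 7,
  closed retention interval.
* Peak finding: plateau-tolerant local maxima, topographic prominence
  ranking, 3-bin smoothing window, 0.1 ns minimum separation.
* Pixels need `min_count >= 1` photons to enter a histogram (default 1:
  every non-empty pixel).
* `round()` half-to-even for all photon-count rounding.
* Event cap $10^6$ per photon; truncations are warned about and
  reported, and occur only in absorption-free configurations.
* One seedable RNG stream per run (R's global generator, consumed
  sequentially by the compiled engine); a run is bit-reproducible given
  its seed, and series derive all randomness from a single upfront seed.
* The degenerate $z = 0$ source escapes immediately at its own
  position with zero scattering events.

## Problem sizes

The packaged depth and separation series, the acceptance script and the
test suite run the full parameter set (optics, gating, detector, dye
photophysics, separations, depths) at one tenth of the full photon
budgets (`scale = 0.1`), the size at which the whole reproduction suite
stays comfortable on a single CPU core. Scaling down photon budgets
leaves every expectation unchanged but enlarges Monte Carlo error and
deepens the sparse-pixel regime; the known consequence (verifiable by
re-running at larger `scale`) is a slight *underestimate* of the
long-lifetime component after the 1% cutoff, because the trim removes
part of the heavy single-photon tail that belongs disproportionately to
the longer-lived dye, together with growing halo cross-contamination of
the two dye regions at depths of 0.5 cm and beyond.

## Known limitations

* Without time-of-flight gating effects, lifetime recovery is by
  construction independent of depth up to statistics; the model cannot
  exhibit transport-induced lifetime distortion.
* The exit-halo width governs two-dye contamination at depth; with the
  Fresnel/TIR boundary enabled the halos widen further and the
  multiplexed estimates destabilize earlier.
* Phase lifetimes from a single harmonic saturate near a quarter
  period; values beyond a few ns at 20 MHz are dominated by noise, which
  is why time windows of 0-1.5 ns are sensible for these dyes.
* The peak-based two-component extractor needs well-populated
  histograms; in the sparse regime use the region-based
  `multiplex_lifetimes()` (as the packaged series do).
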