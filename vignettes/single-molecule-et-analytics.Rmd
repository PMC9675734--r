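---
title: "Models and methods: single-molecule electron-transfer and binding analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: single-molecule electron-transfer and binding analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smelt)
```

# Scope

`smelt` implements the quantitative analysis chain of a single-molecule study
of inter-protein electron transfer (ET) between redox partners — the kind of
experiment in which one cytochrome is immobilized on an electrode and its
partner on a scanning probe — together with the bulk binding assays and the
desk-scale ionic-environment models that accompany it. Every analysis stage
is paired with a synthetic-data generator whose ground truth is embedded in
the output, so the whole pipeline is validated by parameter recovery rather
than by comparison to downloaded data. The five stages are:

1. tunneling current–distance (I–z) spectroscopy and distance-decay factors;
2. feedback-off current blinks and junction conductance;
3. force-spectroscopy rupture statistics and Bell–Evans inference;
4. SPR 1:1 binding kinetics;
5. ion concentration maps, screened electrostatics, and association rates.

This document records the model behind each stage, the tunable parameters
with their defaults and units, the numerical choices, and what the synthetic
generators do and do not emulate.

# Tunneling decay (I–z)

## Model

During probe retraction at constant bias the current decays nearly
exponentially from the set point down to a distance-independent faradaic
leakage floor:

$$I(z) = I_{sp}\,e^{-\beta z} + I_{leak}$$

with $\beta$ (nm$^{-1}$) the distance-decay factor. Generator defaults follow
the recording protocol: set point 0.4 nA, 15 nm retraction span, 1024 points,
leakage 2 pA, 5% multiplicative noise, bias 0.8 V. Per-curve $\beta$ is drawn
from a Gaussian mixture: components are `(center, sd, weight)` rows so that a
single fixed decay constant (`sd = 0`) and a bimodal population (e.g.
0.22 N(1.3, 0.2) + 0.78 N(3.1, 0.4) nm$^{-1}$) are both expressible. Draws
are truncated at 0.05 nm$^{-1}$, as a decay constant must be positive.

## Fitting choices

The instrument-side analysis of the original experiments is unpublished
custom code, so the window selection here is our own, chosen to be robust and
parameter-light:

* leakage is estimated as the median of the last 10% of samples (a hint can
  be supplied instead);
* the fit window is the leading contiguous run of points with
  $I > 3 I_{leak}$, excluding the first two points after feedback-off (the
  switching transient);
* the nonlinear fit (`minpack.lm`) keeps the leakage free, initialized from
  log-linear regression of $I - I_{leak}$; if it fails, the log-linear slope
  is the fallback;
* at least 8 points above the floor are required (`NoDecayRegion`
  otherwise);
* curves with window $r^2 < 0.8$ are flagged, never silently dropped.

These choices make $\beta$ invariant to adding a constant leakage and
covariant under current rescaling, which the test suite asserts.

## Population modelling

`fit_beta_population()` fits 1- and 2-component Gaussian mixtures to the raw
$\beta$ values (never to the histogram) with `mclust` and selects by BIC.
Histograms for display use Freedman–Diaconis bins. With well-separated
components (≥ 3 s.d.) the BIC choice is stable across seeds; the degenerate
all-identical input returns a single zero-width component rather than
failing.

Group contrasts use the pooled-variance Student t-test, whose
$df = n_1 + n_2 - 2$ convention matches the published statistics of this kind
of data (e.g. df = 220 for groups of 134 and 88). We note that one published
figure reports df = 195 for groups of 103 and 64; the standard formula gives
165, and we implement the standard formula.

# Blink analysis

## Generator

Blinks are a two-state continuous-time Markov process: exponential dwells in
the off and on states (defaults: 50 ms on, 250 ms off — free choices, as no
dwell statistics are published for this system), simulated event-driven and
then rasterized at the sampling rate (default 10 kHz), so dwell statistics
are exact rather than Bernoulli-approximated. The in-blink level is
$I_{baseline} + G\,G_0\,V_{bias}$ with $G_0 = 2e^2/h = 77.5\ \mu S$; at
$G = 4.3\times10^{-6} G_0$ and 0.8 V the step is 0.267 nA. Additive Gaussian
noise (default 0.02 nA) is applied after rasterization. A configuration
whose sampling cannot resolve the mean blink (fewer than 10 samples per
lifetime) warns.

## Detection

The baseline is a rolling median (default 0.5 s window), robust to
excursions occupying less than half of any window and able to track slow
drift. Noise $\sigma$ is the MAD of below-threshold baseline-subtracted
samples. Segmentation uses two-threshold hysteresis: an event must exceed
$k\sigma$ (default $k = 5$) and extends over contiguous samples above
$k\sigma/2$; events shorter than 3 samples are discarded. We chose hysteresis
over hidden-Markov segmentation deliberately: for two-level data it has
fewer free parameters and its failure modes are transparent.

Conductance histograms are per-sample by default — every in-blink sample
contributes $I/(V G_0)$ — because published 2D-map counts (10^5–10^5.4)
far exceed any plausible event count; per-event histograms are available.
2D blink maps re-time every event to onset 0 and normalize the (time,
current) histogram so the maximum bin is 100. A small (few percent)
downward bias of the recovered conductance is expected: the rolling median
sits slightly above the true baseline when blinks occupy a nonzero duty
cycle. At the default duty cycle this bias is ~2–4%, well inside the 10%
recovery tolerance, and it shrinks with the duty cycle.

# Force spectroscopy

## Generator

Retraction curves are flat at zero force with (optionally) one sawtooth
event: load grows linearly at the effective stiffness $k_{eff}$ (default
56 pN/nm, i.e. the value implied by published loading rates of
28,000–224,000 pN/s at 0.5–4 µm/s) until the rupture force is reached at the
rupture length, then drops discontinuously to baseline. Adhesion is negative
in raw curves; $F_r$ is reported positive. Rupture forces come either from a
truncated Gaussian (Gaussian centers 55 ± 17 pN and 77 ± 24 pN are the two
study conditions) or from the Bell–Evans first-passage density at loading
rate $r = k_{eff} v$, sampled by its analytic inverse CDF

$$F(u) = \frac{k_BT}{x_u}\ln\!\Big(1 - \frac{x_u r}{k^0_u k_BT}\ln(1-u)\Big),$$

which avoids stochastic-ODE integration entirely. Rupture lengths are
Gaussian (default 12 ± 3 nm); a tether contour length, when nonzero, offsets
the rupture-length center (polymer-elasticity fitting of the stretch segment
is out of scope). The maximum contact force of the protocol (200 pN in one
published description, 300 pN in another) affects only the approach segment,
which the detector never sees; the generator does not model it.

## Detection and inference

The zero-force baseline and noise come from the far-retraction tail (last
10%). A rupture is a run of at least 3 samples below baseline $-3\sigma$
that returns to within $3\sigma$ of baseline within ≤ 3 samples with a jump
exceeding $3\sigma$. The 3-sample minimum is what separates shallow genuine
ruptures from single Gaussian-tail samples; without it, traces of pure noise
produce spurious ~$3\sigma$ "events". The pre-rupture force is extrapolated
from a local linear fit over up to 20 samples before the jump — this is also
the primary loading-rate estimator ($r = |dF/ds|\,v$), with the nominal
$k_{eff} v$ as documented fallback. Force accuracy is limited by sampling:
the true rupture lies up to one sample beyond the last below-threshold
point, so $F_r$ carries a quantization error of order
$k_{eff}\,\Delta s$ (≈ 1.6 pN at defaults) besides the noise-fit error.

Bell–Evans inference fits $F^* = a + b \ln r$ and inverts exactly:
$x_u = k_BT/b$, $k^0_u = (x_u/k_BT)e^{-a/b}$ (with $k_BT = 4.114$ pN nm at
298 K). Feeding the four forces generated by the closed-form law recovers
$(k^0_u, x_u)$ to machine precision; this algebraic round trip is an
acceptance requirement. With realistic force noise the recovered $k^0_u$ is
log-amplified (errors of tens of percent at 2 pN force scatter are normal),
while $x_u$ is comparatively stable — both behaviours are asserted
statistically, not point-wise. The regime call is `kinetic` iff the slope is
positive and significant (default $\alpha = 0.05$); a flat force-vs-rate
series — the near-equilibrium signature where rebinding outpaces pulling —
returns `near_equilibrium` with $k^0_u, x_u$ undefined.

# SPR kinetics

The 1:1 Langmuir model is fitted in closed form (no ODE integration, no
mass-transport term):

$$R_{assoc}(t) = R_{eq}(C)\big(1-e^{-(k_{on}C+k_{off})t}\big),\qquad
R_{eq}(C) = \frac{R_{max} C}{C + k_{off}/k_{on}},$$

with exponential dissociation at $k_{off}$ from the association endpoint.
`fit_global_1to1()` shares $k_{on}$, $k_{off}$ and (by default) $R_{max}$
across curves, optimizing on the log scale with `minpack.lm::nls.lm`.
Initialization is deterministic: $k_{off}$ from the log-linear dissociation
slope, $k_{on}$ from per-curve $k_{obs} = k_{on}C + k_{off}$ fits. Standard
errors come from the fit covariance by the delta method; $K_D$ is always
recomputed as $k_{off}/k_{on}$, never stored independently. Default
generator conditions are the two printed analyte concentrations (5 and
2.5 µM), 300 s association, 600 s dissociation, $R_{max} = 100$ RU (a
typical immobilization level; the published work does not state one).
Noiseless recovery is exact to optimizer tolerance; with 2% of $R_{max}$
noise both rate constants are recovered within 10% (median over seeds).

# Ionic environment

## What the stand-in is

The published ionic analysis rests on explicit-solvent all-atom MD, a
nonlinear Poisson–Boltzmann solver, and rigid-body protein Brownian
dynamics. None of those is desk-scale, and this package deliberately
replaces them with the simplest models that preserve the *direction* of the
physics:

* **Field**: linearized Debye–Hückel superposition
  $\phi(x) = \sum_i q_i l_B e^{-d_i/\lambda_D}/d_i$ in kT/e, with
  $\lambda_D = 1.36$ nm at 50 mM 1:1 salt and $l_B = 0.71$ nm in water at
  298 K. Linear screening underestimates saturation near strongly charged
  sites, which is acceptable for the qualitative conduit contrast.
* **Ions**: i.i.d. equilibrium frames, each placing
  $N = c_{bulk} N_A V_{box}$ ions by rejection sampling with weight
  $e^{-q\phi}$; a 0.3 nm hard core regularizes the point-charge divergence.
  Frames are uncorrelated — there is no dynamics, no ion–ion interaction,
  no explicit water. A sampler acceptance below 1% aborts (pathological
  field).
* **Rates**: a centrosymmetric two-body Brownian estimator. Trajectories are
  launched at radius $b$, stepped by Euler–Maruyama, and absorbed at the
  smallest reaction distance or past $q$; recombination probabilities become
  rates through $k(d) = k_D(b)P(d)/[1-(1-P(d))k_D(b)/k_D(q)]$, with
  $k_D$ from quadrature of the centrosymmetric integral. For free diffusion
  this reconstructs the Smoluchowski rate $4\pi D d$ (e.g.
  $4.5\times10^9$ M$^{-1}$s$^{-1}$ at $d = 0.6$ nm,
  $D = 10^{-9}$ m$^2$/s) within Monte-Carlo error, which the tests assert.

Consequently the published absolute prism molarities and BD rate constants
are *not* reproduction targets: passing tests show conservation, Boltzmann
consistency (regression slope $-1 \pm 0.1$ of $\ln c$ on $q\phi$ over
sampled voxels), the depletion-direction contrast (like-charged sites
deplete counter-co-ions between them; flipping the site charges accumulates
them), and agreement of the Brownian estimator with its quadrature oracle —
not agreement with all-atom numbers.

## Grids and prisms

Concentration maps are per-voxel mean occupancies converted to molarity,
$c = \langle N\rangle/(N_A V_{voxel})$ (one ion pinned in a (10 Å)$^3$ voxel
is 1.661 M); the sum over voxels always returns the mean ion count. The
prism average weights partial voxels by overlap fraction. "Prism units" are
1 Å grid cells: a 15 × 43 × 20 prism is 12,900 Å$^3$ = 12.9 nm$^3$, matching
the published volume, and this identity is a worked-constant test. Default
contour spacings follow published practice: 0.15 M for concentration maps,
0.2 kT/e for potentials. The Brownian stepper refuses configurations where a
step would change the potential by more than 1 kT.

# Problem sizes and determinism

Every generator takes a `seed` and identical configurations are
bit-reproducible. The validation suite and the acceptance analysis use the
published ensemble sizes where they exist (100–200 curves per condition,
four loading rates) and otherwise sizes chosen for stable statistics at
interactive runtimes: 10^4–10^5-sample blink traces, a few hundred ion
frames at 1–8 Å voxels, and 400–600 Brownian trajectories at 0.03–0.05 nm
steps. Stochastic recovery checks assert medians or peak centers at the
tolerances stated alongside each claim (typically 5–10%), with Monte-Carlo
standard errors used for the rate comparisons.

# Known limitations

* The decay-window heuristic assumes a monotone decay to a flat floor;
  curves with mid-retraction re-approach artefacts would need manual
  windows.
* Hysteresis blink detection assumes two conductance levels; multi-level
  traces and flicker-noise spectra are out of scope.
* The Bell–Evans inversion assumes a single rate-limiting barrier fixed
  over the probed loading-rate window.
* The SPR model omits mass-transport limitation and drift beyond reference
  subtraction.
* The ionic stand-ins are statistical, implicit-solvent models; they
  support direction-of-effect claims only, never absolute molarities or
  absolute association rates of the atomistic system.
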