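---
title: "Methods: a coupled stochastic Ca2+ release / action potential model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a coupled stochastic Ca2+ release / action potential model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`rogueryr` simulates a ventricular myocyte as two coupled systems.

**Subcellular sheet.** Free cytosolic Ca2+ on a 2D longitudinal section
(default 100 um x 20 um) obeys an anisotropic reaction-diffusion equation

$$\partial_t c = D_x \partial_x^2 c + D_y \partial_y^2 c
  + J_{dye} + J_{buf} - J_{pump} + J_{leak} + J_{rel}(x, y, t),$$

solved by explicit finite differences (5-point Laplacian, zero-flux
boundaries, default mesh 0.1 um, step 0.01 ms).  Fluorescent dye
(mobile) and an endogenous buffer (stationary) follow mass-action kinetics;
the field SERCA pump is a Hill function balanced at rest by a constant leak.

Release enters through two channel populations: RyR *clusters* on a regular
lattice (spacings 2.0 um longitudinally, 1.0 um along the Z-line; 49 x 19 =
931 clusters at the default geometry), and *rogue* (solitary) RyR channels
scattered uniformly at density $N_{rogue}$ per um^2 (2000 channels at
1/um^2).  An open cluster releases
$J_{cluster} = V_{cluster}([Ca]_{SR} - c)$, an open rogue channel the fixed
quark-scale flux $J_{rogue}$.  Channel opening is a Bernoulli trial per
gating interval with rate

$$P_j = \frac{P_{max}}{1 + (K_{mj}/c_{local})^{n_j}}\; k_{CaSR}, \qquad
  k_{CaSR} = \frac{k_{max}}{1 + (D_{SR}/[Ca]_{SR})^{n_{SR}}},$$

with cooperative gating for clusters ($n = 1.6$) and non-cooperative gating
for solitary channels ($n = 1$).  Open times are fixed (10 ms clusters, 5 ms
rogues) followed by a refractory period.

**Whole cell.**  Membrane potential and ionic balances follow the human
ventricular epicardial action-potential model (fast/late Na+, L-type Ca2+,
transient outward, rapid and slow delayed rectifier, inward rectifier,
NCX, Na/K pump, background and pump currents), integrated by forward Euler
with Rush-Larsen gating updates.  The reference model's intrinsic SR release
gating is removed entirely; instead the release current is the summed
subcellular flux, $J_{rel} = k_{rel} \sum_j J_j$ with $k_{rel} = 22.25$,
converted to cytosolic units through the cell volume.  The SR store
$[Ca]_{SR}$ is a single shared pool: it gates and feeds every channel of the
sheet and is depleted/refilled by the cellular balance.

**Heart failure** differs from control in exactly ten constants: SERCA
maximal rate (-45%), G_Ks (-50%), G_K1 (-20%), G_to (to 64%), G_Na (8.902
vs 14.838 nS/pF), P_NaK (-42%), G_bCa (raised with NCX), k_NaCa (+65%), and
the two release sensitivities K_m (7.5 vs 15 uM) and D_SR (2.5 vs 3.25 mM).

## Closures the source model leaves open

Several constants of the coupled system are not fixed by the published
equation set; the package adopts the following, all overridable and recorded
in every run manifest.

* **Unit of the release fluxes.** Release fluxes are carried in pmol/ms with
  $V_{cluster} = 1.97 \times 10^{-8}$ pmol ms$^{-1}$ mM$^{-1}$ and
  $J_{rogue} = 3.3166\times10^{-9}$ pmol/ms.  These correspond to ~10 pA per
  cluster at a full store gradient and ~0.64 pA per solitary channel — the
  canonical spark and quark currents — which is the only dimensionally
  consistent reading of the published constants.
* **Slab thickness (2.0 um).**  A 2D sheet needs a thickness to convert
  point fluxes into concentrations.  With the quasi-2D continuous-source
  solution $c(r) \approx S/(4\pi \bar D d)\,E_1(r^2/4\bar D t)$, a thickness
  of 2 um reproduces the free-space (3D) point-source concentration
  $I/(8\pi F \bar D r)$ at the 2-um inter-cluster distance: a few uM at a
  neighbouring cluster and tens of uM at the spark core.  A thinner slab
  over-concentrates release and sends the sheet into unphysical all-out
  CICR at rest.
* **Cluster footprint (radius 0.25 um).**  Cluster release is distributed
  over a disc of fixed physical radius, weighted by voxel-disc overlap, so
  that simulated spark amplitude changes by <1% when the mesh is halved.
  Rogue channels are true point sources (single channels).
* **Open and refractory times (10/5 ms, 400 ms).** Spark-like release
  requires a finite open time; regenerative waves require refractoriness.
  The refractory period is set to the spark restitution timescale
  (several hundred ms).  A shorter choice lets clusters re-fire repeatedly
  within one action-potential plateau, which drains the SR during pacing and
  produces grossly prolonged, overloaded beats.
* **Dyadic trigger sensing.**  Clusters sit at couplons facing the L-type
  channels, so their gating Ca2+ is the field value at the node *plus* a
  dyadic term proportional to the instantaneous inward L-type current
  (`gamma_dyad`, default 0.005 mM per pA/pF, sized so peak I_CaL yields the
  20-30 uM cleft concentrations of dyad models).  This makes paced beats
  trigger cell-wide release without injecting mesh-dependent point fluxes;
  the term vanishes at diastole, so spontaneous dynamics are unaffected.
  Rogue channels, outside couplons, sense the field only.
* **Field transport and buffering.**  Reference spark/wave-model defaults:
  $D_x = 0.30$, $D_y = 0.15$ um^2/ms; mobile indicator dye 50 uM
  (kon 80 /mM/ms, koff 0.09 /ms, D 0.02 um^2/ms); stationary buffer 123 uM
  (kon 100 /mM/ms, koff 0.1 /ms); field SERCA Vmax 2.08e-4 mM/ms (Km
  0.184 uM, Hill 4) with a constant leak balancing it at the resting Ca2+.
* **SR background leak (1.8e-4 /ms)** — half the reference cell model's
  value, calibrated once so that the coupled model's store equilibria sit at
  the stated operating point (control ~3.2 mM with the failing store ~15%
  lower).  With the reference value the stochastic release leak pins the
  store near 1.3-2.0 mM, below the luminal half-activation point, and no
  spontaneous release regime exists.
* **Initial store.**  Protocols start from the post-pacing diastolic store
  (control 3.2 mM, heart failure 2.7 mM) rather than the never-paced
  reference rest (1.3 mM): pacing the coupled model from rest to its loaded
  steady state takes upwards of thirty conditioning beats, which is not
  affordable per Monte Carlo repetition.  `scenario_config(init_casr = ...)`
  overrides.
* **Stimulus.**  52 pA/pF x 1 ms, a conventional twice-threshold pulse; the
  source protocol's nominal amplitude is stated in units that do not map
  onto the per-capacitance convention of the cell model, so the package
  defaults to an amplitude that reliably elicits an action potential and
  records it in the manifest.

## Event detection

After the last paced beat, the *end of the resting stage* is the time the
membrane potential returns to within 2 mV of the post-pacing diastolic
minimum.  The baseline is the mean over the 100 ms preceding the detected
event onset (first sustained positive dV/dt above a 0.02 mV/ms floor), or
the first 100 ms of quiescence when no onset is found.  `delta_Vm` /
`delta_Ca` are peak rises above baseline; `T_peakVm` / `T_peakCa` are times
from the end of the resting stage to the peaks.  A run is *triggered* when
V_m crosses -40 mV with dV/dt > 10 mV/ms: the threshold separates fast-Na
upstrokes from even the largest DADs (~15-20 mV above a -84 mV diastole),
and protocols can zero G_Na after pacing to measure DAD amplitudes without
triggered upstrokes.

## Ensembles and statistics

`ensemble()` repeats a protocol with per-run seeds drawn deterministically
from the master seed, summarises each run, and reports mean +/- SEM
(SD/sqrt(n)) per density, one-way ANOVA across densities (`stats::aov`),
and the triggered-AP fraction.  Failed repetitions are excluded with a
warning; groups with fewer than two survivors are dropped.

## Numerical choices and problem sizes

The explicit scheme enforces $dt\,(D_x + D_y)/h^2 \le 0.5$ at construction.
Stochastic gating is evaluated every 0.1 ms (probabilities per interval stay
well below 1; a violation raises an error instructing a smaller step).
Concentrations are clamped non-negative; NaN or out-of-range membrane
potentials abort the run with the failing time reported.

The full-resolution configuration (h = 0.1 um, dt = 0.01 ms, 1001 x 201
nodes) reproduces the source geometry but costs hours per multi-second
realisation on one core.  The packaged tests and the acceptance script use
a coarsened sheet (h = 0.5 um, dt = 0.02 ms)
and a scaled protocol (two conditioning beats at 1000 ms cycle length
followed by a 1.5 s observation window, 3-5 repetitions per group), chosen
so a Monte Carlo group completes in minutes; the deterministic spark peak
differs by under 5% between h = 0.2 and h = 0.1, and under 1% in the
footprint-resolved range.

## What the simulations do and do not show

The synthetic protocols emulate: steady-pacing twitches in control and
failing cells, spontaneous diastolic release after pacing, the dependence of
DAD amplitude and latency on rogue-channel density, and fast-Na-mediated
triggered action potentials.  They do not emulate: 3D geometry, mechanical
feedback, beta-adrenergic or kinase-mediated RyR regulation, stochastic
L-type gating, or inter-cellular coupling.  Quantitative DAD amplitudes in
this implementation run below previously reported values at matched
densities (the desynchronised wave regime yields ~1-2 mV depolarisations at
1 rogue/um^2, bounded by the spark duty cycle t_open/t_refractory); trends
across density and the control/failure contrasts are the robust outputs.  Conclusions about real
myocytes should rest on the directional results, not the absolute mV/mM
values.
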