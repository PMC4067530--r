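---
title: "Models and methods: Brownian-dynamics simulation of ParABS-mediated chromosome segregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The biological problem

In *Caulobacter crescentus* the ParABS system segregates the duplicated
chromosomal origin region: the ParB/*parS* partition complex travels about
1 um from near the old pole to the new pole in a few minutes, following a
receding cloud of DNA-bound ParA-ATP dimers. `dnarelay` implements three
candidate physical mechanisms as stochastic simulations, together with the
estimation procedures that supply every model parameter from experimental
observables, and seeded synthetic-data generators so the full analysis chain
is testable without any external data.

The three mechanisms share one set of measured parameters (no free fitting):

* **diffusion** — the complex diffuses with `D_PC = 1e-4 um^2/s`; ParA plays
  no role.
* **diffusion-binding** — DNA-bound ParA-ATP dimers are immobile; the
  complex binds any dimer whose disk it overlaps and is released when
  ParB-stimulated hydrolysis (rate `k_cat`) dissociates the dimer. While
  attached the complex is stalled; no force is ever exerted.
* **DNA-relay** — identical to diffusion-binding except that DNA-bound
  dimers fluctuate in anisotropic harmonic wells (the elastic dynamics of
  the chromosomal loci they are bound to). A dimer captured away from its
  well centre pulls the complex toward that centre until hydrolysis releases
  it; the intracellular ParA gradient makes captures ahead of the complex
  more likely, rectifying the elastic kicks into directed motion.

## The integrator

Each coordinate is advanced per axis with a second-order scheme,

x(t+dt) = x(t) + R0 + (D/kT) F dt + (D^2 / 2(kT)^2) F F' dt^2 + (D/kT) F' R1,

where (R0, R1) is a correlated Gaussian pair with Var(R0) = 2 D dt,
Var(R1) = (2/3) D dt^3 and Cov(R0, R1) = D dt^2, drawn by conditional
decomposition (R1 | R0 ~ N(dt/2 R0, D dt^3/6)). With F = 0 the update is the
exact free-diffusion increment. Harmonic forces enter only through
`k_sp/kT = 1/sigma^2` per axis, so absolute temperature affects reported
forces (via kT at the 303 K growth temperature) but never the dynamics.

For a tether of SD `sigma` the update is linear and its stationary variance
deviates from `sigma^2` only at relative order `(D dt / sigma^2)^2 / 6`;
at the default `dt = 1 ms`, `D_A = 0.01 um^2/s`, `sigma_short = 0.04 um`
this is below 1e-5. The configuration validator enforces
`dt <= 0.1 min(sigma^2)/D_A`. Validation tests check the noise-pair
covariance against its closed form, the free-diffusion MSD slope, and the
stationary tether density against the Boltzmann Gaussian by a
Kolmogorov-Smirnov test.

## Geometry, state machine, and numerical choices

* The cell is a reflective rectangle `[0, l0] x [-w0/2, w0/2]` with
  `l0 = 2.6 um`, `w0 = 0.4 um`; reflection is the mirror fold, applied
  repeatedly for large overshoots. A run terminates when the complex
  reaches `x_finish = 2.5 um` (absorbing), the mean position at which
  complexes anchor at the new pole. The printed sources disagree on whether
  the box is 2.5 or 2.6 um long and whether crossing is at 2.5 or 2.6 um;
  we follow the parameter table (box 2.6, crossing 2.5) and expose both as
  configuration.
* The elastic force is implemented as restoring (toward the tether point).
  One printed form of the force equation carries the opposite sign, which
  would be anti-restoring; the surrounding text ("moves the complex toward
  the equilibrium point") makes the intended sign unambiguous.
* Springs act independently per axis with `1/sigma_long^2 = 278 um^-2`
  along x and `1/sigma_short^2 = 625 um^-2` along y; the force equations
  are written in 1-D, and axis-wise application is our explicit choice.
* A dimer's tether equilibrium point is its (re)binding location; captures
  therefore find dimers in stretched, out-of-equilibrium states.
* Capture is immediate and deterministic whenever the disks overlap
  (centre distance at or below `R_PC + R_ParA = 52 nm`, tested after the
  position updates of each step; simultaneous multi-dimer capture is
  allowed). Release and rebinding are exponential waiting times (means
  `1/k_cat` and `tau_db`) drawn at state entry, which is statistically
  identical to per-step Bernoulli trials and immune to time-step
  refinement. `k_cat = 0` disables release.
* While attached in the DNA-relay model a dimer contributes no independent
  noise; its coordinate increment equals the complex's, and its tether
  enters the complex's force sum with derivative `-n_AB k_sp` per axis.
* In the diffusion-binding model attached dimers are immobile and exert no
  force, and the complex is **stalled** (zero increment) while at least one
  dimer is attached. We weighed the alternative — binding as pure
  bookkeeping with the complex free to diffuse — and rejected it
  quantitatively: under that reading the probability of a 1-um crossing
  within 30 min is the free-diffusion value (about 0.005 per trajectory,
  analytically 2*Phi(-1.7/0.6) and confirmed by simulation), so the
  mechanism's reported null result (no crossings in over a thousand
  trajectories) could not be a structural property, only a fluke. With the
  stall — which is also how the mechanism is described in words, transient
  interactions "intermittently stalling" the complex — the null is
  structural: 0 of 300 trajectories cross, and the maximum excursion stays
  around 2 um because the dimer gradient densifies toward the pole and
  stalls the complex ever more frequently as it advances.
* Rebinding positions follow the linearly increasing density
  `P(x) = 2(x - x_pc)/(l - x_pc)^2` between the complex and the new pole
  (inverse CDF `x = x_pc + (l - x_pc) sqrt(u)`), uniform across the cell
  width, emulating the observed ParA distribution; initial dimer placement
  uses the same law with `x_pc = x0`.
* Reproducibility: the compiled engine uses a self-contained xoshiro256++
  generator with ziggurat normal sampling, seeded from the configuration;
  a run is a pure function of `(config, seed)` and ensemble run `i` uses
  `seed + i - 1`. Free ParA monomers are not simulated explicitly (their
  diffusion is fast enough to randomize between rebinding events), matching
  the source model's scope.

## Parameters

| name | default | units | meaning |
|------|---------|-------|---------|
| `dt` | 0.001 | s | integrator step |
| `t_fin` | 2000 | s | maximum simulated time |
| `l0`, `w0` | 2.6, 0.4 | um | cell length, width |
| `x0`, `y0` | 0.8, 0 | um | complex position at duplication |
| `x_start`, `x_finish` | 1.5, 2.5 | um | fast-phase analysis window / absorbing target |
| `R_PC`, `R_ParA` | 0.05, 0.002 | um | interaction disk radii |
| `n_ParA` | 90 | — | DNA-bound ParA-ATP dimers per cell |
| `k_cat` | 0.03 | /s | ParB-stimulated hydrolysis rate (tether lifetime 33 s) |
| `tau_db` | 33.3 | s | mean free-to-DNA rebinding time |
| `D_PC` | 1e-4 | um^2/s | partition-complex diffusion coefficient |
| `D_A` | 1e-2 | um^2/s | DNA-bound dimer diffusion coefficient (1-ms scale) |
| `sigma_long`, `sigma_short` | 0.06, 0.04 | um | locus fluctuation SDs; `k_sp/kT = 1/sigma^2` |

All are measured quantities; none were adjusted to produce the simulation
outcomes.

## Estimation procedures

**Locus elasticity.** Deviations from each trajectory's own mean position
are pooled across cells and fitted per axis by a zero-mean Gaussian
(maximum likelihood by default — the ML sigma is the RMS deviation — with a
binned least-squares alternative, since the original fitting route is not
recorded and the two differ slightly in their standard errors).
`k_sp = kT/sigma^2` converts SDs to spring constants. Finite 2-s sampling
of an Ornstein-Uhlenbeck process with a 0.36-s relaxation time leaves the
frames essentially uncorrelated, and subtracting the per-trajectory sample
mean shrinks the SD only by order `1/(2 n_frames)`; no correction is
applied.

**Diffusion of the complex.** Two estimators are provided: the variance of
pooled 1-D displacements (`Var = 2 D dt`, the physics convention; the
`msd_equals_Dt` flag reproduces the alternative convention in which the
MSD-vs-time slope is quoted directly as D, a factor-2 ambiguity that the
source leaves open), and an OLS fit to the first four MSD lags with a free
offset that absorbs localization noise. Trajectory segments for these
estimators follow three rules: pre-duplication frames at least 320 nm from
the old pole; the proximal complex from 1 min after visible separation
until it returns within 320 nm of the pole; and the distal complex's
longest stretch confined in a 500-nm window. "Visibly separated" is
operationalized as linked spots at least 0.25 um apart (about twice the
localization SD); all three thresholds are configurable.

**Fast-phase detection.** The long-axis series is interpolated onto its
frame grid, smoothed with a 5-frame moving average, and its
central-difference second derivative (smoothed with the same window)
provides candidate inflection points: clusters of significant curvature
plus the global curvature extremes. The opposite-sign pair covering the
longest travelled distance (near-ties resolved toward the tightest
bracket, with a 0.3-um minimum so featureless traces report no run) gives
a coarse bracket, refined within +-4 frames by profile likelihood under a
three-segment Gaussian-increment model (zero-mean slow phase, drifting
run, zero-mean anchored phase, free variance per segment). The original
pipeline relied on visual inspection to confirm the automatically assigned
endpoints; the likelihood refinement replaces that manual step with an
objective one.

A resolution limit is worth stating plainly: at the measured values the
slow phase's per-frame step SD (`sqrt(2 D_PC dt_frame)` = 63 nm) nearly
equals the run's per-frame drift (73 nm), so single-frame localization of
the slow-to-fast changepoint is not statistically identifiable — a global
mean-shift MLE has a median error of about 3 frames on such data. The
package's tests therefore check frame-level changepoint accuracy (+-2
frames) on trajectories whose slow and anchored phases are stationary
(where the detection example that motivates the check is posed), and check
the diffusive default through population means of run length, period and
speed, which land within the experimentally observed per-cell SD bands
(1.0 +- 0.2 um, 4.7 +- 1.2 min, 220 +- 50 nm/min). The extracted period
retains a mild (~7%) downward bias at that SNR; this is a property of any
changepoint estimator here, not of the generator.

**ATPase kinetics.** Initial velocities are OLS slopes of A340 time
courses, corrected by matched no-enzyme controls; the NADH standard curve
is a single uM-per-absorbance factor. Specific activities (per uM ParA)
are fitted by `v = Vmax S/(K + S)` via nonlinear least squares
(Gauss-Newton with a Levenberg-Marquardt fallback), initialised at
`Vmax0 = max(v)`, `K0 = median(S)`; the ParA titration uses a
through-origin linear fit (the figure implies proportionality; a
free-intercept variant is exposed). Because the raw plate-reader data are
unpublished, fits are validated by parameter recovery on synthetic curves
generated at the printed constants, not by reproducing printed values from
data.

**Cell-level scoring.** Concentrations follow `N/(N_A V)`. The partition
fraction ranks segments by fluorescence density, treats the lowest decile
(`ceiling(0.1 n)` segments, ties broken by index) as diffuse signal, and
reports `1 - diffuse/total`; it is invariant to overall intensity scaling.
The two-population fluorescence split is a two-component Gaussian mixture
(maximum likelihood via `mclust`), components ordered by mean, flagged as
collapsed when their means are within two pooled SDs (a mixture closer
than that is unimodal). The aspect ratio comes from the ellipse matching
the second central moments of a detected-object point set (the
`4 sqrt(eigenvalue)` axis-length convention); `AR > 1.5` flags a
decompacted complex. One tabulated concentration (total ParB at 1.8 uM) is
inconsistent with its own mole and volume entries (which give 4.8 uM); it
is excluded from all checks.

## Synthetic data: what it does and does not emulate

Every generator is seeded, returns its ground truth alongside the data,
and writes the schemas the analysis functions read. The locus generator
runs the same compiled tether integrator as the simulator (internal step 5
ms, subsampled at the 2-s frame interval, stationary initialization,
per-cell equilibrium points). Its default adds no localization noise: the
target SDs are treated as the total observed spread, since the
experimental SDs already fold localization error in. The spot-table
generator keeps a 20-nm localization SD, the scale reported for the
imaging used. Defaults elsewhere are the study's values: 641 cells at 2-s
frames for fluctuations; 20-s frames, 1.0-um runs at 220 nm/min for
segregation; the printed kinetic constants for titrations.

What the generators deliberately omit: photobleaching and blinking, uneven
illumination, cell-to-cell parameter variability, segmentation errors,
anomalous-diffusion memory in the slow phase, and pixelation. Passing
recovery tests therefore demonstrates the correctness of the estimators
under the stated noise models, not robustness to every artifact of real
microscopy or plate-reader data.

## Ensemble sizes and runtimes

Published-scale ensembles (1024 trajectories) are unnecessary for the
qualitative contrasts the package asserts; the analysis scripts and tests
use 50 runs for the forceless models (with `dt` coarsened to 2 ms, exact
for diffusion) and 25 runs for the DNA-relay model at `dt = 1 ms`, sizes
at which the null result (0 crossings), the relay contrast (most runs
complete, mean displacement > 0.5 um) and the hydrolysis-rate optimum are
all stable across seeds. A full-length relay run integrates 2e6 steps for
91 particles in a few seconds.

## Known limitations

* Two spatial dimensions; no explicit chromosome polymer, no ParA
  filament/polymerization variants, no PopZ/TipN anchoring mechanics, and
  free ParA monomers are not simulated.
* The diffusion-binding stall is all-or-none; partial drag while attached
  is not modelled (no measurement constrains it).
* Changepoint localization at the measured slow-phase diffusivity is
  population-accurate but not frame-accurate (see above).
* The mixture fit assumes exactly two Gaussian populations; heavier-tailed
  autofluorescence would bias the split.
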