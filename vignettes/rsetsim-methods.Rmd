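---
title: "Simulating heterogeneous R-SET oscillator ensembles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating heterogeneous R-SET oscillator ensembles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsetsim)
```

## The device model

An R-SET is a metallic nanoparticle (NP) protected by an organic ligand that
acts as a tunnel junction, connected through a high charging resistance to an
input electrode.  Its equivalent circuit is a capacitance $C_i$ in parallel
with a tunnel junction of resistance $R_i$, in series with the charging
resistance $r_i$.  Three ingredients make it a relaxation oscillator:

1. **Charging.**  Between tunneling events the NP potential obeys
   $dV_i/dt = (V - V_i)/(r_i C_i)$, relaxing toward the applied potential
   $V$ with time constant $\tau_i = r_i C_i$.
2. **Coulomb blockade.**  A single electron tunneling onto the island
   changes the electrostatic energy by $\Delta E = e\,(V_i - V_{th,i})$ with
   threshold $V_{th,i} = e/(2C_i)$; tunneling is energetically favourable
   only above threshold.
3. **Reset.**  An event instantaneously lowers the NP potential by
   $2V_{th,i}$, and charging resumes — the integrate-and-fire cycle.

At the reference operating point ($C = 1$ aF, $r = 10$ GΩ, $R = 10$ MΩ,
$T = 5$ K) the threshold is $e/2 \approx 80.11$ mV and the charging time
constant is 10 ns.  All computation uses natural units
(mV, ns, aF, GΩ, aF·mV²) in which $1\,\text{aF} \times 1\,\text{GΩ} =
1\,\text{ns}$ and $e = 160.2176634$ aF·mV, so no $10^{-19}$-scale floats
appear; SI conversion happens only at I/O boundaries.

## The mixed continuum–Monte Carlo engine

`run_rset()` advances the deterministic charging with the exact exponential
update over fixed steps `dt` and draws one stochastic tunneling decision per
member per step, with $\Delta E$ evaluated at the post-charging potential.
Event times are logged at the end of their step, so the timing resolution is
`dt`.  A single RNG stream drives the whole run (member decisions drawn in
member order), which makes runs bit-reproducible under a fixed seed.

Two decision rules are provided:

* **`metropolis`** (default): accept with probability
  $\min(1, e^{\Delta E / kT})$.  Above threshold the electron tunnels in the
  step where it first becomes favourable; below threshold the Boltzmann
  factor produces the thermal smearing of the response around the threshold
  (scale $kT/e \approx 0.43$ mV at 5 K).
* **`kmc`**: kinetic Monte Carlo with per-step probability
  $1 - e^{-\Gamma \Delta t}$ from the orthodox-theory rate
  $\Gamma = \Delta E / \{e^2 R\,[1 - e^{-\Delta E/kT}]\}$ (the removable
  singularity at $\Delta E = 0$ is replaced by its limit $kT/(e^2 R)$ for
  $|\Delta E/kT| < 10^{-6}$).

The default matters for oracle checks.  With a finite tunnel resistance the
rate rule fires stochastically *after* the threshold crossing: near
$V = 120$ mV the hazard grows linearly with the overshoot and the mean
firing lag is $\tfrac12\sqrt{\pi e R / s}\approx 0.8$ ns (slope
$s \approx 4$ mV/ns), which biases the mean inter-spike interval by about
0.7 ns relative to the closed form below.  The Metropolis rule fires within
one step of the deterministic crossing, so the zero-temperature engine
reproduces the closed-form period to within $2\,dt$ — the package's primary
correctness oracle — while leaving the low-temperature thermal behaviour
qualitatively identical.  The rate rule remains available for
rate-faithful studies.

Two closed forms serve as independent oracles for an isolated unit at
constant drive $V > V_{th}$: the steady-state period
$P = \tau \ln[(V + V_{th})/(V - V_{th})]$ (about 16.13 ns at 120 mV) and the
first-spike time from a zero initial state,
$t_1 = -\tau\ln(1 - V_{th}/V)$.  From these, `stair_boundaries()` locates
the voltages where a homogeneous ensemble observed over a fixed window gains
its $k$-th spike per member — the level transitions of its staircase
response — which the tests use to separate plateau levels from thermally
smeared transition regions.

**Step size.**  The default is `dt = tau_min/100` (0.1 ns for homogeneous
reference ensembles); steps coarser than `tau_min/50` warn.  The per-step
cost is a handful of vectorised operations over the ensemble, so a 600 ns,
64-member run takes ~10⁴ steps and a fraction of a second.

## Heterogeneous ensembles

Fabricated nanostructures scatter in size and shape, so capacitances and
charging resistances are modelled as independent uniform draws of relative
half-width $\delta$ around the central values (1 aF, 10 GΩ):
$C_i \in [0.75, 1.25]$ aF and $r_i \in [7.5, 12.5]$ GΩ at the
representative $\delta = 0.25$, giving thresholds spread over roughly
64–107 mV.  The tunnel resistance is held at its central value by default —
only the capacitances and charging resistances are described as variable —
with an optional flag to spread it too.  $\delta = 0$ reproduces identical
units exactly (no residual sampling noise).  Only the uniform family is
implemented; the spec's `distribution-family` hook is kept in the
constructor signature for forward compatibility.

## Image coding

Pixels map linearly to input potentials, $V = V_{black} + g_{in} V_{white}$
with $V_{black} = 60$ mV and $V_{white} = 100$ mV by default, and every
pixel is processed independently by a freshly reset ensemble for a time
$\tau_{pixel}$ (pixels scan row-major; pixel $k$ uses child seed
`seed + k`).

* **Rate coding** ($\tau_{pixel} = 330$ ns): the output level is the
  ensemble's average spike frequency mapped linearly onto $[0, 255]$.  The
  anchors of that map are a package decision (the source material says only
  "proportional"): the mean rates measured at the black and white extremes,
  estimated once per ensemble/configuration.  This reproduces the full
  dynamic range by construction; `N_grey < 256` quantizes the output
  (rounding half-up, clamped).  For homogeneous ensembles the response is
  stair-like in the voltage, so rate-coded output occupies few levels; with
  $V_{black} = 60$ mV a homogeneous ensemble is silent for dark pixels, and
  the classical workaround of raising $V_{black}$ to 75 mV places black just
  inside the thermal response region.
* **Rank-order coding** ($\tau_{pixel} = 30$ ns, of the order of the
  charging time): the output level is the fraction of members that spiked
  at least once, times 255.  Identical units give an essentially binary
  output (all or none spike, up to thermal smearing near threshold), while
  threshold diversity grades the response — the headline advantage of
  heterogeneous ensembles.  Windows longer than three nominal charging
  times warn that the no-spike/one-spike reading degrades.

Images are exchanged as 8-bit PGM (plain P2 by default, binary P5
supported) or greyscale PNG; `generate_test_image()` provides ramp,
checkerboard and Gaussian-blob fixtures in code.

## Analog-signal reconstruction

The test input is a raised sinusoid starting at its minimum,
$V(t) = V_0 + (V_1/2)\,[1 - \cos(2\pi t/T_s)]$, so $V_0$ is the minimum
applied potential and $V_1$ the peak-to-peak swing.  (Only the
minimum/amplitude/period semantics of the source equation are certain; the
start-at-minimum phase is the literal reading of "$V_0$ is the minimum
applied potential".)  The ensemble output is the total spike count in 30 ns
bins over a 600 ns processing window.  Reconstruction fidelity is scored by
the Pearson correlation between the binned counts and the input resampled
at bin centers — the source compares the curves only visually, so the
metric is a package decision (it is reported, not hidden, and degenerate
all-zero counts yield an explicitly flagged undefined fidelity rather
than 0).

With $V_0 = 60$ mV: $V_1 = 100$ mV exercises the supra-threshold regime
(N = 10), where diversity smooths the staircase response; $V_1 = 18$ mV
keeps even the signal peak (78 mV) below the 80 mV homogeneous threshold,
so identical units respond only through rare thermal events while a
64-member heterogeneous ensemble — whose lowest thresholds sit near 64 mV —
tracks the waveform collectively (threshold diversity acting as
suprathreshold-stochastic-resonance-style static noise).  Homogeneous
ensembles driven fast (120 ns period) still reveal the input frequency in
the binned counts' spectrum even when the waveform shape is lost.

## Synchronization of coupled ensembles

A common coupling resistance $r_c$ sits between the input electrode and the
members' charging resistances.  Current conservation at the star node gives

$$V_n = \frac{V/r_c + \sum_j V_j/r_j}{1/r_c + \sum_j 1/r_j},$$

and every member charges toward $V_n$ instead of $V$ ($r_c = 0$ pins
$V_n = V$, the uncoupled limit).  Eliminating the node for homogeneous $r$
gives the equivalent all-to-all form

$$r C\,\frac{dV_i}{dt} = \frac{(V - V_i) + (K_c/N)\sum_j (V_j - V_i)}{1 + K_c},
\qquad K_c = \frac{N r_c}{\langle r\rangle},$$

which motivates the dimensionless coupling strength $K_c$ used throughout
(zero at $r_c = 0$, linear in $r_c$).  Within a step the node potential is
frozen at its start-of-step value and each member then uses the exact
exponential update; this is accurate because `dt` is one per-cent of the
fastest charging time.

**Phases and order parameter.**  A member's oscillation maxima are exactly
its pre-reset peaks, i.e. the logged event times, so phases are interpolated
between consecutive events,
$\varphi_i(t) = 2\pi (t - t_k)/(t_{k+1} - t_k)$, with no numerical peak
finding.  The phase is undefined outside a member's first/last event and for
members with fewer than two events; the complex order parameter
$z(t) = M^{-1}\sum e^{i\varphi_j(t)}$ averages over the $M$ members with
defined phase and is masked when $M < 2$.  One estimator caveat: because
phases interpolate to the *next* event, a perturbation occurring after $t$
influences phase estimates up to one cycle before it.

**The experiment.**  All NP potentials start at zero (synchronized), the
coupling strength holds at zero for 20 ns, rises linearly to $K_{peak}$ and
falls back to zero (total 600 ns by default; the hold and triangle shape
follow the study design, the total duration is a package choice sized so the
high-coupling window spans several collective periods).  With $V = 120$ mV
and $N = 20$:

* in the zero-coupling window, parameter diversity dephases $\delta = 0.25$
  ensembles within ~20 ns, while identical units desynchronize only through
  slow thermal jitter — a robust directional contrast;
* at $K_{peak} = 40$ the heterogeneous ensemble reaches high synchrony in
  the central window (mean over replicates of the central-window maximum
  $|z| > 0.9$).  Mechanistically, strong coupling lets the sagging node
  suppress high-threshold members while the lowest-threshold unit keeps
  firing and entrains the remainder — a commanding-oscillator state;
* at $K_{peak} = 10$ the ensemble never *sustains* $|z| > 0.95$ (measured
  as the fraction of central-window time above 0.95);
* as the coupling returns to zero the ensemble desynchronizes again.

One behaviour of the exact star-node circuit deserves note: for *identical*
members, strong coupling does not stabilise the in-phase state.  A firing
member's potential drop increases its current draw, sagging the node — an
effectively inhibitory pulse that splays identical oscillators into firing
queues (the classic behaviour of relaxation oscillators sharing a supply
resistor).  Exploration across $r_c \in [0.05, 20]$ GΩ and an alternative
diffusive coupling form found no regime in which identical ensembles
sustain high $|z|$ at strong coupling under this circuit; the package
therefore reports synchronization claims only for the heterogeneous
ensemble, where they are robust.

## Reproducibility and configuration

Experiments are driven by a JSON config (`load_config()` /
`run_experiment()`) whose defaults are the reference parameter set;
validation errors name the offending field path.  Every experiment written
to disk includes the effective config and a provenance record, and re-runs
to byte-identical outputs under the same seed.  Master seeds spawn child
seeds by a documented counter scheme (per pixel: `seed + pixel_index`,
row-major).  The command-line front end
(`inst/scripts/rset-cli.R`) is a thin wrapper over these functions.

## What the synthetic data does and does not emulate

The generators reproduce the *study conditions*: uniform parameter spread,
noiseless sinusoidal inputs, and synthetic grey images (ramps,
checkerboards, blobs) standing in for a photograph.  They do not emulate
correlated fabrication disorder (C and r are drawn independently), offset
charges, co-tunneling, multi-electron events, gate electrodes, input noise,
or temperature-dependent parameter drift.  Passing tests therefore
demonstrate the collective-coding mechanisms under idealised diversity, not
device-accurate predictions for any particular fabrication process.

## Problem sizes used by the test suite

Unit tests run on small ensembles (1–64 members) and sub-microsecond
windows; the end-to-end suite uses the study's ensemble sizes (N = 64 for
image and sub-threshold signal work, N = 10 supra-threshold, N = 20 for
synchronization), 20 paired replicates for the stochastic directional
contrasts and 12 for the synchronization statistics.  The full suite
completes in well under a minute on one core.

## Known limitations

* The per-step Metropolis acceptance has no intrinsic timescale below
  threshold, so *sub-threshold* event rates scale with `1/dt`; at 5 K they
  are dominated by the threshold diversity, but quantitative sub-threshold
  rate studies should use `rule = "kmc"`.
* Event times are quantised to `dt`; phase estimates inherit that
  resolution.
* The order parameter over few active members is a coarse synchrony
  measure; with a single active member it is trivially 1 (such times are
  masked by the $M \ge 2$ rule).
* The coupled engine freezes the node potential per step rather than
  solving it self-consistently within the step; halving `dt` is the
  sensitivity check.
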