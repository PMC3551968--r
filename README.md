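# rsetsim

Simulation of spiking ensembles of **R-SETs** — single-electron transistors
(a nanoparticle capacitance `C` in parallel with a tunnel junction `R`) in
series with a high charging resistance `r`.  Coulomb blockade turns each
unit into an integrate-and-fire relaxation oscillator: the nanoparticle
potential charges toward the applied potential with time constant
`tau = r*C`, and once it exceeds the threshold

```
V_th = e / (2 C)        (~80.11 mV at C = 1 aF)
```

a single electron tunnels and resets the potential by `-2*V_th`.

Real nanostructures are never identical: the package models fabrication
variability as uniform spreads of relative half-width `delta` in `C` and `r`
(`delta = 0.25` spans 0.75–1.25 aF and 7.5–12.5 GΩ, i.e. thresholds from
~64 to ~107 mV).  The scientific question it addresses is whether such
*heterogeneous* ensembles can still process information — and where
diversity actively helps.  Three biologically inspired population-coding
schemes are implemented on top of a mixed continuum–Monte Carlo engine
(deterministic RC charging between events, stochastic per-step tunneling
decisions):

* **Image coding** — pixels map to input potentials
  (`V = V_black + g_in * V_white`); the output grey level is recovered from
  the ensemble's average spike rate (rate coding, 330 ns/pixel) or from the
  number of members that spiked at least once (rank-order coding,
  30 ns/pixel).
* **Analog-signal reconstruction** — a raised sinusoid
  `V(t) = V_0 + (V_1/2)(1 - cos 2πt/T)` drives the ensemble; the total
  spike count in 30 ns bins reconstructs the waveform, scored by Pearson
  correlation.  Threshold diversity lets ensembles track signals that stay
  *below* every nominal threshold.
* **Synchronization** — ensembles coupled through a common resistance `r_c`
  (dimensionless strength `K_c = N r_c / <r>`) under a triangular coupling
  schedule; synchrony is measured by the complex Kuramoto order parameter
  `z = mean(exp(i φ))`, with phases interpolated between tunneling events.

Intended users: computational neuroscientists and nanoelectronics modellers
studying threshold diversity, suprathreshold stochastic resonance and
collective dynamics in threshold-unit arrays.

## Worked example

```r
library(rsetsim)

# a 64-member heterogeneous ensemble (delta = 0.25)
ens <- sample_ensemble(64, heterogeneity_spec(delta = 0.25), seed = 1)
sp  <- threshold_spread(ens)
sprintf("thresholds: %.1f to %.1f mV", sp$min, sp$max)
#> "thresholds: 64.3 to 105.9 mV"

# drive it at a constant 120 mV for 120 ns
run <- run_rset(ens, input = 120, cfg = sim_config(duration = 120, seed = 2))
run$spikes
#> spike train: 64 members, 463 events over 120 ns
average_spike_rate(nrow(run$events), 120)   # MHz
#> 3858.333

# rank-order coding of a grey ramp: diversity widens the output palette
img   <- generate_test_image("ramp", 64, 8)
out   <- process_image(img, ens, coding_config("rank"),
                       sim_config(duration = 1), seed = 3)
ens0  <- sample_ensemble(64, heterogeneity_spec(delta = 0), seed = 1)
out0  <- process_image(img, ens0, coding_config("rank"),
                       sim_config(duration = 1), seed = 3)
c(heterogeneous = length(unique(as.vector(out))),
  homogeneous   = length(unique(as.vector(out0))))
#> heterogeneous   homogeneous
#>            49             9

# sub-threshold signal (peaks at 78 mV, below the 80 mV nominal threshold)
rep <- run_signal_experiment(sinusoid_spec(V_0 = 60, V_1 = 18, period = 300),
                             ens, sim_config(duration = 600, seed = 4))
rep
#> signal reconstruction (sub-threshold): 245 spikes in 20 bins, fidelity 0.972
run_signal_experiment(sinusoid_spec(60, 18, 300), ens0,
                      sim_config(duration = 600, seed = 4))
#> signal reconstruction (sub-threshold): 96 spikes in 20 bins, fidelity 0.586
```

The numbers tell the story: on the ramp image the identical ensemble can
only answer in ~9 grey levels (essentially black/white plus thermal
smearing) while the diverse ensemble resolves ~49; for the weak sinusoid the
diverse ensemble reconstructs the waveform with fidelity 0.97 against 0.59
for identical units, because members with low thresholds respond to the
troughs and high-threshold members only near the peaks.

A command-line front end wraps the same functions:

```sh
Rscript inst/scripts/rset-cli.R fixture --kind ramp --width 256 --height 64 --file ramp.pgm
Rscript inst/scripts/rset-cli.R encode-image --scheme rank --N 64 --delta 0.25 --seed 1 --out out/
Rscript inst/scripts/rset-cli.R signal --V1 18 --N 64 --delta 0.25 --out sig/
Rscript inst/scripts/rset-cli.R sync --Kpeak 40 --out sync/
```

Every run writes its effective config and a provenance JSON; the same
config + seed reproduces outputs byte-for-byte.

## Package layout

* `R/` — device physics (`rset_params`, `threshold_potential`,
  `tunneling_rate`, `deterministic_period`), ensemble sampling
  (`sample_ensemble`), the Monte Carlo engine (`run_rset`,
  `bin_spike_counts`, `node_potential`, `coupling_strength`), image codecs
  (`process_image`, `read_pgm`/`write_pgm`), signal experiments
  (`run_signal_experiment`), synchronization (`run_sync_experiment`,
  `extract_phases`, `order_parameter`) and JSON-config plumbing
  (`load_config`, `run_experiment`).
* `vignettes/rsetsim-methods.Rmd` — the model, its assumptions, numerical
  choices and known limitations.
* `tests/testthat/` — unit, property and end-to-end suites.
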