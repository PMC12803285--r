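# tandemtimer

Tandem fluorescent timer (tFT) analysis of protein trafficking and
turnover in epithelia.

## The problem

A tFT fuses a fast-maturing (GFP-like) and a slow-maturing (Cherry-like)
chromophore to one protein. Because each chromophore becomes fluorescent
by a first-order maturation step — half-times `ln 2 / m` of ~3 h and ~6 h
for the calibrated default pair — the normalized Cherry/GFP ratio of a
protein pool reports the pool's age: newly made protein is green-only,
old protein is red-and-green. In the wing-disc epithelium this readout
resolves the life history of the Hedgehog (Hh) signal transducer
Smoothened (Smo): synthesis into the basolateral membrane, Hh-dependent
residence there, then transit to acidic apical endosomes (where the
GFP-like chromophore is quenched) and degradation.

`tandemtimer` is built for analysts who want to turn such two-channel
ratio images into residence-time estimates with honest uncertainties. It
provides the forward models, seeded synthetic-data generators with full
ground truth, the image quantification operators, and the calibration and
inversion machinery, all under one tested roof.

## The model in brief

For a chromophore with maturation rate `m`:

* **Pulse synthesis** over `[0, D]`: normalized matured fluorescence
  `F_m(t) = (min(t, D) - (exp(-m * max(t - D, 0)) - exp(-m t)) / m) / D`;
  the calibration curve is `F_ms(t) / F_mf(t)`, rising from `ms/mf` to 1.
* **Constitutive synthesis** with exit rate `k` (residence time
  `tau = 1/k`): matured fraction `m / (m + k)`, so the ratio is
  `R(k) = (ms / (ms + k)) * ((mf + k) / mf)`, inverted algebraically by
  `k = ms mf (1 - R) / (R mf - ms)`.
* **Trafficking**: per region, `dB/dt = sigma - k_exit B`,
  `dE/dt = k_exit B - k_deg E`, with matured amounts per chromophore
  carried alongside (ODE solved with `deSolve`, checked against the
  closed-form steady state).

Residence estimates are upper bounds under the assumption that all
protein transits the basolateral membrane.

## Worked example

```r
library(tandemtimer)

pair <- default_fluorophore_pair()
pair
#> <fluorophore_pair> half-times: fast 3 h, slow 6 h; acid quench: fast 0.00, slow 1.00

# ratio of a membrane pool with 4 h basolateral residence
steady_state_ratio(1 / 4, pair)
#> [1] 0.6580257

# full synthetic experiment: generate a wild-type disc, quantify it,
# invert the regional membrane ratios into residence times
run <- run_scenario("wild_type", seed = 1, n_boot = 300, verbose = FALSE)
run
#> <scenario_run> preset 'wild_type', seed 1
#>   Hh partition (P): 95.0%
#>   Hh-Rab7 overlap: apical A 84.8%, apical P 49.7%
#>   residence far_A       1.82 h [1.75, 1.89] (ok)
#>   residence ptc_band    3.97 h [3.88, 4.05] (ok)
#>   residence P           7.98 h [7.92, 8.05] (ok)
#>   ptc_band / far_A residence fold change: 2.18
```

Reading the output: 95% of morphogen-channel signal stays in the
producing (P) compartment; ~85% of apical anterior Hh intensity lies in
Rab7-positive vesicles versus ~50% posteriorly; and the basolateral
slow/fast membrane ratios invert to residence times of ~8 h (P), ~4 h
(ptc band) and ~1.8 h (far anterior) — the ptc band versus far-anterior
contrast being roughly two-fold. Each estimate carries a bootstrap 95%
CI, and the generator's ground truth (in `run$disc$truth`) lets you check
every number.

Calibrating maturation half-times from a pulse-chase series:

```r
ps <- generate_pulse_series(pair, noise_cv = 0.05, n_replicates = 3, seed = 1)
fit_maturation(ps$series, seed = 1)
#> <maturation_fit> half-times: fast 2.940 h [2.821, 3.049], slow 5.845 h [5.661, 5.997]; amp 0.988
```

A thin CLI over the same functions lives at `inst/cli/tandemtimer`
(subcommands `simulate-disc`, `simulate-pulse`, `quantify`, `calibrate`,
`infer-residence`, `run-scenario`).

## Package layout

* `R/` — kinetics and trafficking models, generators, quantification,
  calibration/inference, I/O and the pipeline runner.
* `tests/testthat/` — unit, property and end-to-end recovery tests.
* `vignettes/tandem-timer-methods.Rmd` — model assumptions, generator
  design, measurement choices and limitations.
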