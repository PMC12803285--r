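---
title: "Models and measurement choices in tandemtimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and measurement choices in tandemtimer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemtimer)
```

## The timer model

A tandem fluorescent timer (tFT) fuses two chromophores to one protein: a
fast-maturing GFP-like one and a slow-maturing Cherry-like one. Maturation
is modelled as a single first-order step per chromophore, with rate
constant $m$ (1/h) and half-time $\ln 2 / m$. A protein molecule of age $a$
is fluorescent in a channel with probability $1 - e^{-m a}$, so the
normalized slow/fast fluorescence ratio of a pool is a monotone function of
the pool's age distribution. All fluorescence is reported in normalized
units in which a fully matured pool has ratio 1; per-fluorophore brightness,
detector gain and labelling stoichiometry cancel out of every quantity the
package reports, which is why only ratios and fractions are meaningful
outputs. We deliberately omit dark intermediate states and photobleaching:
the calibration data constrain only effective half-times, and a richer
photophysical model would not be identifiable from them.

The default pair has half-times of 3 h (fast) and 6 h (slow), the values
calibrated from pulse-chase imaging of the cytoplasmic tandem fusion in
wing discs. Acidic compartments quench the fast chromophore but not the
slow one; this enters as multiplicative per-pool quench factors
(`q_fast_acidic = 0`, `q_slow_acidic = 1` by default) and an
ammonium-chloride flag that sets both to 1, mimicking neutralization of
acidic endosomes.

### Pulsed synthesis

For synthesis at a constant rate during $[0, D]$ with no degradation, the
matured fraction (normalized to its $t \to \infty$ limit) is

$$F_m(t) = \frac{1}{D}\Big(\min(t, D) - \frac{e^{-m\,\max(t-D,0)} - e^{-m t}}{m}\Big),$$

implemented in `pulse_matured_fraction()` and checked in the tests against
direct numerical quadrature of the cohort integral. The calibration curve
`pulse_ratio_curve()` is the ratio $F_{m_s}(t) / F_{m_f}(t)$: it rises
strictly from the small-age limit $m_s / m_f$ (0.5 for the default pair)
towards 1. An expression-onset lag parameter exists (default 0): first
detection of fluorescence in a live experiment also reflects transcription
and translation delays that pure first-order maturation does not capture,
and we do not attempt to fit them.

### Constitutive synthesis and the membrane pool

A membrane pool fed at constant rate and exited at rate $k$ has an
exponential age distribution, so its matured fraction per chromophore is
$m / (m + k)$ and its ratio is

$$R(k) = \frac{m_s}{m_s + k}\cdot\frac{m_f + k}{m_f},$$

with algebraic inverse $k = m_s m_f (1 - R) / (R\,m_f - m_s)$
(`steady_state_ratio()`, `invert_steady_state_ratio()`).

## Trafficking model

Each region of the epithelium is a two-pool linear system: synthesis at
rate $\sigma$ into the basolateral pool $B$, exit to the apical pool $E$ at
rate $k_{exit}$ (basolateral residence time $\tau_B = 1/k_{exit}$), and
apical degradation at rate $k_{deg}$. Matured amounts per chromophore
follow the same fluxes plus maturation of the unmatured fraction. The
system is integrated with a stiff-capable adaptive solver
(`deSolve::lsoda`, relative tolerance 1e-8) and validated against the
closed-form steady state ($B = \sigma/k_{exit}$,
$B_{mat} = mB/(m + k_{exit})$, $E = \sigma/k_{deg}$,
$E_{mat} = (k_{exit} B_{mat} + mE)/(m + k_{deg})$) to 1e-6 relative, with
an explicit mass-balance bookkeeping check. The model assumes all protein
transits the basolateral membrane before apical degradation; if some is
routed directly to degradation, the basolateral pool is younger than the
ratio suggests, so inferred residence times are upper bounds. Degradation
is exclusively apical in the model, and `k_deg` is not identifiable from a
single membrane ratio — it is a generator parameter, not an inference
target.

## Which inversion to use

`infer_residence_map()` offers two inversions of a measured membrane
ratio. The curve-lookup method reads the age off the pulse calibration
curve by monotone bisection (tolerance 1e-6 h), treating the pool as a
single-age cohort; this mirrors how a calibration figure is used by eye.
The steady-state method inverts $R(k)$ algebraically, treating the pool as
a constitutively fed, exponentially age-mixed pool. For a membrane pool at
steady state the second description is the self-consistent one: the old
tail of the exponential age mixture contributes disproportionately to the
slow channel, so reading the same ratio off the single-age pulse curve
systematically overstates the pool's mean age (for the default timer, a
4 h-residence pool reads as roughly 6 h on the pulse curve). Because the
synthetic discs are generated at trafficking steady state, the
steady-state inversion recovers the generator's residence times exactly at
zero noise and is therefore the package default; both estimates are
reported by `run_scenario()` so the two conventions can be compared, and
they always agree in how they order regions (both are monotone transforms
of the same ratio).

## The synthetic-data generator

The generator encodes the study conditions the measurements assume; its
defaults are fixed and are not tuned per run.

* **Geometry** — a 64 x 48 um field at 0.2 um/px, cells of 2.5 um, the
  A/P boundary at x = 36 um and a 4-cell ptc band immediately anterior.
  Two 2D sections (apical, basolateral) stand in for confocal planes; all
  quantified measurements are per-section, so no 3D stack is rendered.
* **Regional kinetics (wild type)** — basolateral residence times of
  8 h (P), 4.0 h (ptc band) and 1.8 h (far anterior). The anterior values
  are package choices consistent with the measured upper bounds (4.5 h and
  2 h) and their roughly two-fold contrast; they are not measurements.
  Apical clearance is slowest far anteriorly (`k_deg` 0.5, 0.4, 0.25 /h
  for P, band, far-A): cells with little Hh shunt the protein quickly off
  the basolateral membrane into a large, slowly cleared acidic apical
  pool, which reproduces the bright anterior apical Cherry signal together
  with the low anterior total. Total protein still ranks P > band > far-A.
* **Perturbation presets** — `disp_mutant` gives anterior regions
  short-residence parameters (anterior Hh lost), `hh_cd2` gives them
  posterior-like parameters, `usp8_dorsal` halves `k_exit` in the dorsal
  half (reduced internalization), `nh4cl` lifts the acid quench, and
  `uniform_turnover` is the spatially uninformative null in which all
  regions share one parameter set and the ratio field is flat.
* **Morphogen channel** — apical Hh puncta carry 95% of their total
  intensity in P and 5% in A; Rab7 late endosomes are filled discs of
  0.9 um radius, co-centred with 85% (A) and 50% (P) of the Hh puncta by
  intensity. Vesicles are deliberately larger than the diffraction-limited
  puncta so that a co-localized punctum's intensity lies almost entirely
  within the vesicle footprint; with the 0.2 um PSF this makes the
  realized intensity overlap match the intended fraction to within 0.02,
  which the tests assert.
* **Noise** — Gaussian PSF blur (sigma 0.2 um) followed by Poisson shot
  noise (gain 1). The Gaussian read-noise term exists but defaults to 0:
  modern GaAsP confocal detection is shot-noise limited, and a zero-mean
  additive term of realistic size would be invisible next to the photon
  noise at the rendered intensities. Amplitudes are arbitrary units; the
  scale (100 photons per protein unit at the membrane) only sets the
  signal-to-noise ratio.

What the generator does *not* emulate: real membrane geometry (cell
outlines are a brick lattice), punctum size and brightness heterogeneity,
out-of-focus light and 3D PSFs, tissue curvature, embryo stripes and
myoblast monolayers, and any receptor-level signalling. Passing tests
therefore demonstrate that the estimators are correct and calibrated under
the stated imaging model — not that they are robust to every property of
real micrographs; the quantification operators accept external TIFFs and
mask files so that real data can be run through the identical code path.

## Quantification choices

* **Colocalization** is intensity-weighted (Manders M1): the fraction of
  signal-channel intensity inside the partner channel's Otsu mask,
  after background subtraction. A correlation coefficient would answer a
  different question than "what proportion of the signal overlaps".
  The bootstrap CI resamples detected puncta (1000 draws), since puncta
  are the independent units apically.
* **Background** is the 5th percentile of the region's pixel values,
  floored at zero — robust to the sparse bright foreground and exact for
  offset shifts.
* **Membrane pixels** come from Otsu thresholding of the membrane-marker
  channel; external data may supply a mask file instead. For per-region
  ratios the region masks are eroded 1 um away from region borders so PSF
  bleed from a neighbouring region cannot bias the ratio; the remaining
  estimator error is covered by the pixel bootstrap, which a 20-seed
  calibration test holds to >= 90% CI coverage.
* **Puncta detection** is Laplacian-of-Gaussian filtering at the known
  spot scale with an Otsu threshold on the response and
  connected-component centroids, sorted for determinism. On generated
  fields of 100 spots at moderate noise it achieves >= 95% recall and
  precision against the ground-truth table.
* **Undefined ratios** — a region whose fast-channel membrane signal does
  not exceed the noise floor reports `defined = FALSE` rather than a
  number, mirroring the regime in which the fast chromophore is quenched
  or absent; undefined ratios propagate as undefined residence estimates.

## Calibration fitting

`fit_maturation()` fits both channels jointly by nonlinear least squares
(`minpack.lm::nlsLM`) with a shared amplitude and per-channel rates on the
log scale. Initial values come from the time each channel reaches half its
plateau; on failure the fit restarts from three jittered initializations.
Confidence intervals are residual-resampling bootstrap (200 draws). At the
study's sampling design (1 h pulse, 15-min sampling to 12 h, 5% CV noise,
3 replicates) recovery is within 10% per run and biased by under 2% across
seeds, which the tests assert.

## Numerical conventions

Hours everywhere; micrometres for image coordinates, with pixel centres at
`(index - 0.5) * pixel_um` and row/column = y/x. ODE tolerances 1e-8
(relative) / 1e-10 (absolute); curve bisection 1e-6 h; the algebraic ratio
inversion round-trips to 1e-9. Every generator and every bootstrap takes
an explicit seed, and `run_scenario()` derives per-stage child seeds from
one run seed so stages can be rerun independently; rerunning a scenario
with the same seed reproduces images and summaries byte-for-byte. The
default problem sizes (320 x 240 px fields, 150-230 puncta per disc,
300-1000 bootstrap draws) keep a full scenario run to a few seconds while
leaving every estimate's Monte-Carlo error well inside the tolerances the
tests use.

## Known limitations

Residence-time estimates are upper bounds under the all-transit
assumption; the curve-lookup and steady-state conventions differ by up to
~50% for old pools and should not be mixed across studies; absolute
amounts, synthesis rates and degradation rates are not identifiable from
single-timepoint ratios; and the image model's simplifications listed
above mean that real-data applications should validate the membrane mask
and background choices against their own controls.
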