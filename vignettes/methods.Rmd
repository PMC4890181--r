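---
title: "Models and methods behind thylakoidr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thylakoidr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thylakoidr)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, what the synthetic
generators do and do not emulate, and the choices made where the design
was genuinely open.

## Single-channel electrophysiology

### Conventions

Voltages are given on the cis side (the protein-addition side of a planar
lipid bilayer) relative to trans, and positive current is carried by
cations moving from cis to trans.  No orientation of the channel relative
to the thylakoid lumen/stroma axis is asserted: reconstitution into a
bilayer does not fix it.

### Gating model

Each channel is a continuous-time two-state Markov chain
(closed ⇌ open) with exponential dwell times.  The opening rate carries
the voltage dependence through a Boltzmann factor,

$$k_\text{open}(V) = k_{0}\, e^{z\,V F/RT},$$

with the closing rate constant.  This is the simplest kinetic scheme that
reproduces a channel that is more active at positive than at negative
potentials; it makes no claim about the real gating mechanism — no
kinetic rate constants for the channel have been published, and the
generator defaults ($k_0 = 50\,\mathrm{s^{-1}}$,
$k_\text{close} = 50\,\mathrm{s^{-1}}$, $z = 0.3$) are placeholders
chosen to give rich gating within a 60-s trace, not estimates.  Partial
conductance substates are drawn per opening with probability
`substate_prob` at level `substate_fraction`, and cooperative-looking
stacked openings arise from independent superposition of `n_channels`
identical channels.  The unitary current is linear per branch,
$i(V) = \gamma_\pm (V - V_\text{rev})/1000$ pA, with separate slopes
above and below the reversal potential.  Recording noise is additive
Gaussian; no filter or instrument response is modelled.

### Analysis chain

* **Amplitude histogram** — all-points histogram at a fixed bin width
  (default 0.1 pA, about one eighth of the recording noise scale used in
  the tests).  Counts always sum to the number of samples.
* **Unitary current** — a Gaussian mixture fitted by
  expectation-maximization to the bin centers weighted by counts,
  initialized from the highest peaks of the running-median-smoothed
  histogram.  Whether the histogram resolves an open level at all is
  decided by BIC between the one- and two-component binned likelihoods;
  a histogram preferring one component raises a `no_open_events` error
  rather than returning a meaningless separation.  With more than two
  components the dominant pair is the two largest mixing weights, ties
  broken towards the larger separation, which excludes minor substate
  modes.
* **Idealization** — half-amplitude threshold crossing on the raw trace
  (no digital filtering by default; an optional moving-average prefilter
  exists but is off, because filtering trades dwell-time resolution for
  amplitude stability and the default should be reproducible from the
  raw samples alone).  Open probability counts substate time as open.
* **Conductance** — per-branch least-squares slope of the signed unitary
  currents against $V - V_\text{rev}$, constrained through the reversal
  point, in pS.  Whether published branch conductances come from such a
  regression or from single-voltage amplitudes is generally unstated;
  both are available (`fit_branch_conductance`, or the per-voltage
  separations directly), with the regression as default because it uses
  all voltages symmetrically.  Nitrate recordings are fitted with a
  single slope across both branches, matching how a single conductance
  is quoted for that condition.

### GHK selectivity

For a K⁺/Cl⁻ condition the GHK voltage equation (anion on the opposite
side of the fraction) is

$$V_\text{rev} = \frac{RT}{F}\,
\ln\frac{p\,[K]_t + [Cl]_c}{p\,[K]_c + [Cl]_t},\qquad p = P_K/P_{Cl},$$

with $RT/F = 25.693$ mV at the default 298.15 K.  The inversion is closed
form and the forward/inverse round trip is the identity to machine
precision; a symmetric condition is rejected as unidentifiable and a
reversal potential outside the Nernst interval
$[(RT/F)\ln([K]_t/[K]_c),\ (RT/F)\ln([Cl]_c/[Cl]_t)]$ as unattainable.
Concentrations are used as-is: whether activity coefficients were applied
before published inversions is unstated, and at a 3:1 gradient the
correction largely cancels in the ratio.

For estimating the reversal potential from noisy current–voltage data the
package provides the GHK *current* equation (summed K⁺ and Cl⁻ fluxes,
relative permeabilities) as the forward model, and two zero-crossing
estimators: linear interpolation between the bracketing pair, and the
root of a least-squares cubic (`method = "poly"`).  The cubic is the
right tool for single noisy sweeps — the bracketing-pair estimator uses
two points out of eleven and its sampling error on the recovered
permeability ratio is several times larger.  Replicate sweeps are
averaged on the ratio scale, mirroring the usual practice of reporting
the mean of n = 3 measurements.

## ECS dark-interval relaxation

The 550–515 nm electrochromic shift is treated as a linear voltmeter.  A
dark interval inserted into steady actinic light relaxes as a single
exponential towards an inverted quasi-stable level:

$$S(t) = S_\text{inv} + (S_\text{light} - S_\text{inv})\,e^{-t/\tau}.$$

The partition reduces the interval to three level estimates:

| level | estimate | default window |
|---|---|---|
| $S_\text{light}$ | mean before light-off | last 20 ms |
| $S_\text{inv}$ | mean at interval end | last 50 ms |
| $S_\text{base}$ | mean of the dark baseline | protocol window |

Then $ECS_t = S_\text{light} - S_\text{inv}$,
$f_{\Delta\Psi} = (S_\text{light} - S_\text{base})/ECS_t$ and
$f_{\Delta pH} = 1 - f_{\Delta\Psi}$.  The interval length (600 ms) and
the 100-ms decay-fit window are taken from the established protocol; the
level-estimation windows are not published anywhere and are explicit,
configurable choices here — short enough to sit inside the quasi-stable
phases at τ ≈ 25 ms, long enough to average noise.  $f_{\Delta\Psi}$
outside $[0,1]$ is clipped with a warning instead of erroring, because a
genuinely over-range value is informative: it flags an underestimated
total amplitude, which is exactly the situation discussed for strongly
ΔpH-shifted genotypes.

The proton conductivity fit uses `minpack.lm::nlsLM` on
$S_\infty + \Delta S\,e^{-t/\tau}$ over the first 100 ms after
light-off, initialized from a log-linear regression with the asymptote
seeded from the last 5 ms of the window; $g_{H^+} = 1/\tau$ (τ in s).
The inverted level is not subtracted before fitting — the free asymptote
absorbs it.  A non-decaying segment (non-positive τ or ΔS, or an
amplitude within twice the residual noise) raises `no_decay`.

Flash normalization multiplies each total amplitude by
$\max(ECS_{ST})/ECS_{ST}$, so the measurement with the largest flash
response anchors the set; the operation is invariant to a common
rescaling of the flash amplitudes.  The flash amplitude itself is the
peak within 5 ms after each flash minus the 10-ms pre-flash baseline,
averaged over flashes (three in the default protocol).

**What the generator does not emulate:** biphasic or multi-exponential
decays, slow relaxation of the inverted level within the interval,
zeaxanthin/qE contamination of the 515-nm band, and any mechanistic
link between ion fluxes and the levels — the ECS generator is
phenomenological by design.

## PAM fluorescence

The quenching parameters are algebraic:
$NPQ = (F_m - F_m')/F_m'$ and $\Phi_{II} = (F_m' - F)/F_m'$, both
invariant under joint rescaling of all fluorescence levels.  $F_m'$ is
read as the maximum within an 800-ms window centred on each saturating
pulse and $F$ as the mean over the 200 ms preceding that window; the
instrument protocol does not publish extraction windows, so these are
package defaults sized to a 300-ms pulse and slow (≥10 s) pulse spacing.
The generator is the exact inverse — $F_m' = F_m/(1+NPQ)$, steady level
$F_m'(1-\Phi)$ — so analysis∘generation is the identity on noiseless
traces, which the tests assert at $10^{-9}$ relative tolerance.  Each
trace carries its own dark-adapted $F_m$; no batch $F_m$ is assumed.
The windowed maximum assumes pulses are far enough apart that a
neighbouring segment never exceeds the pulse plateau inside the window;
pathological courses violating this are a known limitation.

## SANS Bragg-peak fitting

The 1-D model is a flat background, a power law for diffuse scattering,
and a Gaussian peak (amplitude parameterization; an area form is not
recoverable from the published description, and the amplitude form keeps
$B$ in intensity units):

$$I(q) = I_0 + A\,q^{-p} + B\,\exp\!\big(-(q-q^*)^2/(2c^2)\big).$$

Fits are weighted ($1/\sigma^2$ when uncertainties are present,
unweighted otherwise — whether the original fits were weighted is
unstated) over a fixed q window: 0.0151–0.0380 Å⁻¹ for leaves,
0.0194–0.0310 Å⁻¹ for isolated thylakoids.  All six parameters are free
with $q^*$ bounded inside the window.  Because background and peak trade
off strongly over so narrow a window, the optimizer runs a small
multi-start (the candidate peak from a log-space power-law background
residual, plus three window positions, crossed with three widths) and
keeps the lowest weighted deviance; a fitted amplitude consistent with
zero (below $2\,\mathrm{se}(B)$ or $10^{-6}\max I$) raises
`no_bragg_peak`.  The repeat distance is $RD = 2\pi/q^*$.  Replicate
curves on a shared grid are averaged pointwise, with the sd of the mean
as uncertainty from three replicates up.

The generator's default constants ($I_0 = 0.02$, $A = 2\times10^{-6}$,
$B = 0.2$, $p = 3$, $q^* = 0.025$ Å⁻¹, $c = 0.004$ Å⁻¹, grid
0.012–0.045 Å⁻¹) were chosen from the forward model so that the peak is
a resolvable hump over the local background, as in measured grana
curves; noise is multiplicative Gaussian as a desk-scale proxy for
counting statistics, not an instrument model.  Detector reduction,
contrast variation and structure-factor physics beyond this model are
out of scope.

## Circular dichroism

Psi-type band amplitudes are two-point differences
$cd(\lambda_\text{band}) - cd(\lambda_\text{ref})$ with linear
interpolation, using the conventional pairs 505/550, 675/600 and
690/750 nm; the measure is invariant to constant offsets, and baseline
handling is deliberately limited to such offsets (polynomial detrending
would interact with the reference-wavelength convention).  No peak
search around the nominal band positions is performed by default — a
deterministic two-point rule is reproducible and testable, whereas
"around 505 nm" is not.  Spectra are normalized to the red-most
absorption peak with the cumulative factor recorded, so normalizations
compose multiplicatively.

## Randomness, determinism and problem sizes

All stochastic generators draw from R's Mersenne–Twister stream seeded
per call; multi-trace operations derive one sub-stream per trace
(`seed + 10007·k`, kept within 32-bit range) so any single trace can be
regenerated in isolation.  The caller's RNG state is saved and restored.
Fixed seeds give bit-identical outputs, which the I/O layer preserves:
trace files use a deterministic `key: value` header plus tab-separated
columns with fixed `%.10g` formatting, so identical objects produce
byte-identical files.

The test suite and the acceptance script use the study-scale recording
conditions directly — 60-s traces at 5 kHz (3×10⁵ samples each, three
voltages per branch), 11-point current–voltage sweeps in three
replicates, 600-ms dark intervals at 1 kHz, 50-seed Monte-Carlo loops
for the noisy-recovery properties — chosen to match the conditions the
recovered values refer to while keeping a full run in well under a
minute of CPU.

## Known limitations

* The gating generator is two-state; it produces flicker-like and
  burst-like statistics only through its rate constants, not through
  modal kinetics, and recovery tests on it say nothing about real
  channels with correlated gating.
* The ECS partition assumes the inverted level is stable over the last
  50 ms of the interval; strongly drifting signals bias
  $f_{\Delta\Psi}$.
* The Bragg-peak model is single-peak; curves with higher-order lamellar
  reflections inside the window will confuse the dominant-peak tie-break
  (largest amplitude wins).
* Dwell-time distribution fitting, hidden-Markov idealization,
  inhibitor dose–response analysis, qE/qI decomposition and CD band-shape
  fitting are intentionally out of scope.
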