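# thylakoidr

Quantitative analysis of thylakoid anion-channel biophysics and its
consequences for the photosynthetic membrane, in one tested R package.
It is written for researchers who record voltage-gated chloride channels
(such as VCCN1) in planar lipid bilayers and follow up with in-vivo
spectroscopy and membrane-structure measurements, and it covers five
analysis chains:

- **Single-channel electrophysiology** — all-points amplitude histograms,
  unitary-current estimation by Gaussian-mixture fitting, half-amplitude
  threshold idealization and open probability, branch-wise slope
  conductance, and ionic selectivity through the Goldman–Hodgkin–Katz
  (GHK) voltage equation.
- **Electrochromic shift (ECS)** — dark-interval relaxation analysis of the
  550–515 nm absorbance difference: single-turnover flash normalization,
  total proton-motive force (ECS_t), its partition into ΔΨ and ΔpH, and
  the proton conductivity g_H⁺ from a single-exponential decay fit.
- **PAM chlorophyll fluorescence** — NPQ = (F_m − F_m′)/F_m′ and
  Φ_II = (F_m′ − F)/F_m′ from saturating-pulse-annotated traces.
- **Small-angle neutron scattering (SANS)** — lamellar Bragg-peak fitting
  of 1-D curves with I(q) = I₀ + A·q^(−p) + B·exp(−(q − q*)²/(2c²)) and
  the grana repeat distance RD = 2π/q*.
- **Circular dichroism** — psi-type band amplitudes ((+)505, (−)675,
  (+)690 nm against references 550, 600, 750 nm).

Every stage is paired with a synthetic-data generator carrying known
ground truth (a continuous-time Markov gating model with voltage-dependent
opening, phenomenological ECS/PAM traces, the Bragg-peak model with
counting-like noise, Gaussian CD bands), so the whole pipeline is
verifiable by parameter recovery without access to instrument data.

## The core relations

Selectivity is inverted from the reversal potential under an asymmetric
KCl gradient (cis relative to trans, p = P_K/P_Cl):

    V_rev = (RT/F) ln[ (p·[K]_trans + [Cl]_cis) / (p·[K]_cis + [Cl]_trans) ]

Slope conductance is the per-branch least-squares slope of unitary current
against voltage through the reversal point, γ = 1000·i/(V − V_rev) pS.
The PMF partition reduces a 600-ms dark interval to three levels — light
steady state, dark baseline and the inverted quasi-stable level — giving
ECS_t = S_light − S_inv, f_ΔΨ = (S_light − S_base)/ECS_t, and
g_H⁺ = 1/τ from the first 100 ms of the decay.

## Worked example

Simulate 60-s recordings in symmetric 100 mM KCl at six holding
potentials with 0.8 pA recording noise, then recover the branch
conductances from scratch:

```r
library(thylakoidr)

kcl <- ionic_condition(c(K = 100, Cl = 100), c(K = 100, Cl = 100))
gating <- channel_gating_params(gamma_pos = 96.1, gamma_neg = 60)
rec <- recording_config(kcl, c(-80, -60, -40, 40, 60, 80),
                        duration = 60, noise_sd = 0.8, seed = 42)
traces <- simulate_channel_trace(gating, rec)

iv <- do.call(rbind, lapply(traces, function(tr) {
  h <- build_amplitude_histogram(tr, bin_width = 0.1)
  i_unit <- estimate_unitary_current(h)
  data.frame(voltage = tr$holding_potential,
             current = sign(tr$holding_potential) * as.numeric(i_unit))
}))
fit_branch_conductance(iv)
#> <conductance_fit>
#>   gamma_pos: 96.1 pS, gamma_neg: 60.0 pS
#>   constrained through V_rev = 0 mV
```

The recovered slopes match the generating truth (96.1 and 60.0 pS): the
unitary currents behind them run from −4.80 pA at −80 mV to 7.69 pA at
+80 mV.  Selectivity follows the same round-trip logic — the reversal
potential produced by P_K/P_Cl = 0.17 under 300/100 mM KCl inverts back
exactly:

```r
asym <- ionic_condition(c(K = 300, Cl = 300), c(K = 100, Cl = 100))
fit_permeability_ratio(ghk_reversal_potential(0.17, asym), asym)
#> <selectivity_result> V_rev = 19.05 mV, P_Cl:P_K = 1:0.170
```

and an ECS trace generated with f_ΔΨ = 0.6 and τ = 25 ms partitions to

```r
ecs <- simulate_ecs_trace(ecs_sim_params(s_light = 1, f_dpsi = 0.6,
                                         tau_decay = 25, noise_sd = 0.01,
                                         seed = 1))
partition_pmf(ecs)
#> <pmf_partition> ECS_t = 1.667, f_dPsi = 0.600, f_dpH = 0.400,
#>                 tau = 24.8 ms, g_H+ = 40.3 1/s
```

meaning 60% of the proton-motive force is carried by the membrane
potential and the ATP-synthase proton conductivity is ~40 s⁻¹.

Configuration-driven runs (YAML in, JSON summary out) are available
through `run_pipeline()` or the thin `exec/thylakoid-biophys` wrapper.

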