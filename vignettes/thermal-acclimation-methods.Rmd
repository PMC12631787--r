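---
title: "Modelling thermal acclimation of leaf gas exchange: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling thermal acclimation of leaf gas exchange: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermacclim)
```

`thermacclim` implements the analysis chain used to ask whether plants —
here an invasive windmill palm (*Trachycarpus fortunei*) and two co-occurring
natives, European holly (*Ilex aquifolium*) and small-leaved linden (*Tilia
cordata*) — adjust their photosynthetic and respiratory temperature responses
to the prevailing air temperature, and what that acclimation is worth in
annual carbon terms. This vignette explains the models, the assumptions, the
tunable parameters, and the design decisions taken where more than one
reasonable implementation existed.

## Temperature-response curves

Net assimilation measured at different air temperatures over a day is fitted
with a parabola

$$A_i = A_\mathrm{opt} - b\,(T_i - T_\mathrm{opt})^2,$$

whose three parameters are the optimal temperature $T_\mathrm{opt}$ (°C), the
assimilation at that optimum $A_\mathrm{opt}$ (µmol m⁻² s⁻¹), and the curve
width $b$ (µmol m⁻² s⁻¹ °C⁻²). Because the parabola is a reparameterised
quadratic, `fit_parabolic()` obtains the exact global least-squares optimum
from the linear fit of $A$ on $(T, T^2)$; standard errors follow by the delta
method. The thermal breadth

$$T_{80} = 2\sqrt{0.2\,A_\mathrm{opt}/b}$$

is the width of the interval where $A$ exceeds 80 % of its optimum — the two
roots of $A(T) = 0.8\,A_\mathrm{opt}$.

Dark respiration is fitted with the exponential
$R_i = R_{25}\,Q_{10}^{(T_i - 25)/10}$, started from the exact log-linear
regression and refined by nonlinear least squares.

Fit-quality policy: fits with non-positive curvature, with $Q_{10} \le 1$, or
whose optimum falls outside the sampled temperature range are flagged and
excluded from downstream regressions (with counts retained). The last rule
matters in practice: with 5–6 points and realistic noise, a near-zero
curvature estimate sends $T_\mathrm{opt} = c_1 / 2b$ anywhere on the real
line, and a handful of such fits would dominate any ordinary-least-squares
regression of the traits.

## Acclimation functions

The acclimation predictor is the mean air temperature of the 14 days before
a measurement (`antecedent_mean_tair()`), computed over the closed-open
interval $[t - 14\,\mathrm{d}, t)$ — closed at the start, open at the
measurement instant, so the measurement step is not double-counted.
Campaign-level trait values (the mean over the 4–10 individuals measured per
campaign) are regressed on this antecedent temperature by ordinary least
squares (`regress_trait()`), exactly as the field analysis does; no variable
transformation is applied.

The respiration base rate acclimates along species-specific lines
(µmol m⁻² s⁻¹, $T$ in °C):

| species | $R_{25}(T)$ |
|---|---|
| *T. fortunei* | $0.50 - 0.0037\,T$ |
| *I. aquifolium* | $1.42 - 0.0293\,T$ |
| *T. cordata* | $1.36 - 0.0317\,T$ |

`acclimated_r25()` clamps the line at a floor of 0.01 µmol m⁻² s⁻¹ so that
extrapolation beyond ~43–45 °C never yields non-positive respiration. $Q_{10}$
acclimation is enabled only for the palm, the one species in which it was
observed; the field relationship was reported without coefficients, so the
default slope (−0.02 per °C, anchored at $Q_{10} = 2$ at 16.5 °C) is an
explicit placeholder that callers can replace.

## The coupled leaf model

`solve_leaf_states()` closes, at every met step, a leaf gas-exchange model
against a leaf energy balance:

1. **Biochemistry.** Carboxylation is the minimum of a Rubisco-limited term
   $W_c = V_\mathrm{cmax}(C_i - \Gamma^*)/(C_i + K_m)$ and an
   electron-transport-limited term
   $W_j = (J/4)(C_i - \Gamma^*)/(C_i + 2\Gamma^*)$, with $J$ from a
   non-rectangular hyperbola of PPFD ($\alpha = 0.24$, $\theta = 0.85$).
   $\Gamma^*$, $K_c$, $K_o$ follow standard Arrhenius forms with the widely
   used kinetic constants of Bernacchi and colleagues; $V_\mathrm{cmax}$ and
   $J_\mathrm{max}$ follow the peaked Arrhenius response, normalised to their
   25 °C values.
2. **Thermal acclimation of capacity.** The entropy factors of the peaked
   response are linear in growth temperature with the general coefficients of
   Kattge & Knorr (2007): $\Delta S_V = 668.39 - 1.07\,T_g$,
   $\Delta S_J = 659.70 - 0.75\,T_g$ (J mol⁻¹ K⁻¹), with
   $H_{a,V} = 71.513$, $H_{a,J} = 49.884$, $H_d = 200$ kJ mol⁻¹. Growth
   temperature is the same 14-day antecedent mean used everywhere else.
3. **Stomata.** The optimisation expression
   $g_{s,\max} = \left[B(C_i - \Gamma) - R_d(D\,C_i + E)\right] /
   \left[(E + F)(C_i - C_a)\right]$
   is exported verbatim in `gs_max_optimal()` (floored at zero). The
   constants `D`, `E` and `F` are not fixed by the expression itself, so
   inside the solver we adopt the reading under which the expression
   reproduces the Fickian conductance:
   $B$ is the capacity of the active limitation ($V_\mathrm{cmax}$ or
   $J/4$), $E$ its Michaelis metric ($K_m$ or $2\Gamma^*$), $D = 1$, and
   $F = 280$ ppm, the operating intercellular concentration at ambient
   CO₂ — with the denominator oriented atmosphere-ward, $(E+F)(C_a - C_i)$,
   consistent with our reading of the net-uptake equation below. The
   expression is evaluated at the operating point $C_i = 0.7\,C_a$
   (configurable `ci_ratio`). Evaluating it instead *inside* the $C_i$
   solver is degenerate: the expression is itself a rearranged diffusion
   relation, so supply and demand cancel and $C_i$ drifts to $C_a$. All
   four constants are exposed and are natural calibration targets.
4. **Hydraulic down-regulation.** `hydraulic_gs()` solves
   $E = 1.6\,g_s\,\mathrm{VPD}/P$, $\psi_\ell = \psi_s - E/K(\psi)$,
   $g_s = g_{s,\max}\,c(\psi_\ell)$ with the sigmoid
   $c(\psi) = [1 + (\psi/\psi_{50})^s]^{-1}$ applied both to the stomatal
   cost and to the soil-to-leaf conductance $K$. Because the same sigmoid
   appears in demand and supply it cancels, giving $\psi_\ell$ in closed
   form; only the $g_\mathrm{min}$-floored branch requires a bisection.
   Defaults ($k_\mathrm{max} = 0.002$ mol m⁻² s⁻¹ MPa⁻¹, $\psi_{50}$
   species-specific, $s = 2$) put midday leaf water potentials of
   well-watered saplings near −0.5 MPa.
5. **Net uptake.** A circulating form of the net-assimilation balance
   ($A_\mathrm{net} = g_s(C_a - C_i) + R_d$) adds respiration where the
   standard convention subtracts it; we treat the $+R_d$ as a
   sign-convention artifact and implement the diffusion constraint
   $A_\mathrm{net} = g_s(C_a - C_i)$ (with $g_s$ in CO₂ units; water-vapour
   fluxes use the 1.6 diffusivity ratio) against the biochemical rate
   $A_\mathrm{net} = \min(W_c, W_j) - R_d$. The literal printed reading
   remains available behind `uptake_convention = "printed"` for audit.
6. **Energy balance.** `leaf_energy_balance()` balances absorbed shortwave
   (PPFD converted at 4.57 µmol J⁻¹, doubled for the non-PAR half of the
   spectrum, times an absorptance of 0.5) and incoming longwave against
   emitted longwave, sensible heat (flat-leaf forced-convection boundary
   layer, $g_{bH} = 1.4 \times 0.135\sqrt{u/d}$) and latent heat, by damped
   Newton iteration to a residual below 0.01 W m⁻².

The nesting is: an outer damped fixed point on leaf temperature (damping
0.5, tolerance 0.01 °C, cap 50 iterations) encloses an inner bisection on
$C_i$ (32 steps, resolving the diffusion–biochemistry balance to well below
10⁻⁶ µmol m⁻² s⁻¹), followed by a short damped polish that settles the leaf
temperature exactly on the energy-balance root at the converged conductance.
Non-converged steps are flagged, never silently accepted. Every step is
deterministic; all temperatures cross interfaces in °C and are converted to
kelvin only inside the Arrhenius forms.

Two monotonicity caveats follow from the coupling and are deliberate: at
fixed leaf temperature, rising VPD can only close stomata and rising PPFD
can only raise gross assimilation; in the fully coupled model, evaporative
cooling (VPD) and radiative heating (PPFD) can locally oppose those
tendencies by small amounts. The tests check the strict monotonicities at
fixed leaf temperature and the end-to-end tendencies in the coupled model.

## Scenarios and carbon budgets

`integrate_season()` converts per-step fluxes to gC m⁻² (molar mass 12.011,
negative night-time values retained), over a default annual window of
15 October to 15 October. Deciduous species integrate only their flushing
window (configuration dates; defaults April–October for the linden);
evergreens integrate the full year. `run_scenarios()` runs each site twice
per species: *acclimated*, with $\Delta S$, $R_{25}$ and $Q_{10}$ tracking
the local 14-day antecedent temperature, and *non-acclimated*, with exactly
those four quantities ($V_\mathrm{cmax}$/$J_\mathrm{max}$ temperature
response via $\Delta S$, $R_{25}$, $Q_{10}$) frozen at the reference-site
configuration — stomata and the energy balance still respond to the weather.
Freezing at the reference configuration makes the two scenarios bit-identical
at the reference site, which the tests exploit.

## The synthetic experiment

The generator emulates the transplant design: five sites with measured-period
mean annual temperatures 8.4, 13.3, 15.2, 17.7 and 21.8 °C (coldest to
warmest; the sub-Mediterranean 15.2 °C site is the reference), three species
with distinct trait means, six campaigns of several individuals, and 5–6
point diurnal curves.

* **Drivers** are seasonal plus diurnal cosines with additive Gaussian
  noise; only site means are known from the field, so amplitudes (defaults
  8 °C seasonal, 8 °C peak-to-trough diurnal, noise sd 1.5 °C) are exposed
  configuration. PPFD is a half-sine over a fixed 13-h window scaled by the
  70 % shading of the experimental infrastructure; RH derives from a fixed
  site dew point, making it anti-correlated with temperature without extra
  configuration. All randomness flows from one seed through per-individual
  sub-streams.
* **Gas-exchange observations** are the generating curve — whose parameters
  are the species trait lines evaluated at the campaign's antecedent
  temperature — plus iid Gaussian noise (defaults 0.2 µmol m⁻² s⁻¹ light,
  0.03 dark; no field noise magnitudes are published, so these are
  documented assumptions). The parabola width is derived per campaign from
  the $A_\mathrm{opt}$ and $T_{80}$ lines ($b = 0.8 A_\mathrm{opt}/T_{80}^2$)
  so that the generating $T_{80}$ is exactly linear in antecedent
  temperature. Trait-line slopes are the published field estimates; the
  intercepts are not published, so each line is anchored through the species
  mean at the mid-gradient antecedent temperature of 16.5 °C. Measurement
  temperatures are drawn one per stratum of the sampling window (the
  sunrise-to-afternoon sequence); with `track_ambient = TRUE` the window
  follows the campaign's prevailing conditions, as the cuvette did in the
  field — for light curves it centres on the campaign optimum (the protocol
  extended cuvette temperature ±5 °C to bracket the peak). A fixed window
  makes the curvature leverage, and hence the $T_{80}$ estimation bias,
  covary with antecedent temperature; the tracking window removes that
  artifact, and Monte Carlo checks (30–40 replicates) confirm the recovered
  slopes are unbiased for all five traits.
* **What the generator does not emulate:** cloud-driven radiation
  variability, seasonal day-length change, frost damage and mortality,
  phenology detection, and within-individual correlation of measurement
  errors. Passing recovery tests therefore demonstrate that the estimators
  are correct and unbiased under the stated statistical structure, not that
  field data of arbitrary structure would be recovered equally well. The
  fixed day length in particular biases absolute annual budgets high at
  mid-latitude winters; scenario *differences* (acclimated vs.
  non-acclimated, site vs. reference), which are the quantities of
  interest, are far less sensitive.

## Calibration

Unmeasured parameters are calibrated against diurnal $A_\mathrm{net}$
observations: a seeded 70/30 calibration/validation split
(`split_calibration()`; sizes exactly $\mathrm{round}(0.7 n)$ and the rest),
a Gaussian likelihood whose residual sd is a free nuisance parameter,
bounded-uniform priors, and a hand-implemented differential-evolution MCMC
with snooker updates sampling from a thinned archive of past states
(`demc_sample()`, the DEzs scheme of ter Braak & Vrugt 2008; 10 % snooker
probability, $\gamma = 2.38/\sqrt{2d}$ with a unit-γ pulse every tenth
generation). Convergence is judged by the Gelman–Rubin potential scale
reduction factor with the conventional 1.1 threshold after discarding the
first half of each chain; goodness-of-fit (RMSE, percent bias,
Nash–Sutcliffe efficiency) is computed only on the held-out 30 %. The test
suite exercises the sampler against a known Gaussian target, a bounded
uniform target (Kolmogorov–Smirnov), and a parameter-recovery problem on
synthetic diurnal data ($V_\mathrm{cmax,25}$ recovered within 10 % at
3 × 2000 iterations).

## Problem sizes used by the tests and the acceptance script

Simulation sizes are chosen so the whole chain demonstrates its properties
at the scale of the original experiment: recovery runs use 30 campaigns of 6
individuals (the field design pooled 6 campaigns across 5 sites with 4–10
individuals each, a comparable number of curves); the driver-fidelity check
integrates one year at 30-min resolution (17,520 steps); the calibration
demonstration uses ~200 hourly daytime observations and 3 chains of 2,000
iterations, a reduced count that the Gelman–Rubin diagnostic shows is already
well converged for a two-parameter posterior.

## Known limitations

* The stomatal-optimum constants $D$, $E$, $F$ and the hydraulic formulation
  reproduce the *structure* of the source model; absent its supplement, the
  defaults are physically reasoned, clearly labelled, and calibratable — not
  field-validated values.
* Whole-plant totals multiply leaf-level budgets by a species-mean total
  leaf area; per-individual areas are supported but not defaulted.
* The field study's headline per-site trait means and annual $C_\mathrm{leaf}$
  values depend on the archived field dataset and are context for this
  package, not quantities it reproduces; its tests instead verify exact
  identities, closure properties, and recovery of the published acclimation
  coefficients from data generated under the published equations.
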