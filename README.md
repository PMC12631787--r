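# thermacclim

Thermal acclimation of leaf gas exchange and its consequence for seasonal
carbon budgets.

Plants exposed to warmer air adjust their physiology within weeks: the
optimal temperature of photosynthesis (T_opt) and the assimilation there
(A_opt) shift upward, the thermal breadth (T_80, the range where
assimilation stays above 80 % of its optimum) widens, and dark respiration
standardised to 25 °C (R_25) and its temperature sensitivity (Q_10) can
decline. `thermacclim` is for ecophysiologists who want to quantify that
acclimation from gas-exchange campaigns along a temperature gradient — here,
an invasive windmill palm (*Trachycarpus fortunei*) versus two native
competitors (*Ilex aquifolium*, *Tilia cordata*) transplanted across five
European sites spanning 8.4–21.8 °C mean annual temperature — and to
propagate it through a coupled leaf model to annual carbon budgets.

The chain, each stage a tested module:

* **Response curves** — fit `A_i = A_opt − b (T_i − T_opt)²` to diurnal
  assimilation–temperature points and `R_i = R_25 · Q_10^((T_i−25)/10)` to
  dark-respiration points; derive `T_80 = 2 √(0.2 A_opt / b)`.
* **Acclimation** — regress campaign-mean fitted traits on the mean air
  temperature of the preceding 14 days (OLS), with species-specific
  R_25 lines (e.g. `R25 = 0.50 − 0.0037 T` for the palm) exposed as
  functions; two-way species × climate ANOVA with Tukey HSD.
* **SPAC leaf model** — Farquhar-type limitation with peaked-Arrhenius
  temperature responses whose entropy factors acclimate to growth
  temperature, a stomatal optimum down-regulated by plant hydraulics, Q_10
  respiration at leaf temperature, all closed by a leaf energy balance via
  nested iteration (vectorised over time steps).
* **Carbon budgets** — 30-min integration from flushing to senescence into
  gC m⁻² and whole-plant totals; acclimated vs. non-acclimated scenarios
  (V_Cmax/J_max response, R_25 and Q_10 frozen at the reference site).
* **Calibration** — 70/30 split, differential-evolution MCMC with snooker
  updates (DEzs), Gelman–Rubin ≤ 1.1 convergence rule, RMSE / percent bias /
  Nash–Sutcliffe on the held-out set.
* **Synthetic experiment** — a generator emulating the five-site,
  three-species transplant design so every stage is testable without field
  data.

## Worked example

Generate a year of drivers for the warm site, simulate six dark-respiration
campaigns for holly, fit the exponential per individual, and regress fitted
R_25 on the two-week antecedent temperature:

```r
library(thermacclim)

site <- site_config("semi_arid", mean_annual_tair = 21.8)
met  <- generate_met_series(site, "2023-01-01", n_days = 200, step_minutes = 30, seed = 1)

truth  <- species_truth("I.aquifolium")      # generating line: R25 = 1.42 - 0.0293 T
design <- campaign_design(n_campaigns = 6, n_individuals = 6, n_timepoints_per_day = 5)
obs  <- generate_response_observations(truth, design, met, mode = "dark", seed = 1)
fits <- fit_curves(obs)
head(fits[c("campaign", "individual", "t_antecedent", "r25", "q10", "r2_dark")], 3)
#>   campaign individual t_antecedent       r25      q10   r2_dark
#> 1        1      ind01     13.85320 1.0357316 2.121773 0.9978839
#> 2        2      ind01     14.98103 0.9952963 2.230854 0.9956633
#> 3        3      ind01     18.71294 0.8899130 2.111139 0.9997016

m <- regress_trait(fits$r25, fits$t_antecedent, trait = "r25", species = "I.aquifolium")
sprintf("R25 = %.3f %+.4f x T_ant   (R2 = %.2f, n = %d)", m$intercept, m$slope, m$r_squared, m$n)
#> "R25 = 1.431 -0.0298 x T_ant   (R2 = 0.99, n = 36)"
```

The regression recovers the generating acclimation line (intercept 1.42,
slope −0.0293) from the noisy synthetic campaigns: the fitted R_25 declines
by ~0.03 µmol m⁻² s⁻¹ for every degree of antecedent warming.

One step of the coupled leaf model (mid-day, 25 °C, 60 % RH, 500 µmol m⁻²
s⁻¹ PPFD):

```r
st <- solve_leaf_state(data.frame(tair_C = 25, rh_pct = 60, ppfd_umol_m2_s = 500,
                                  wind_m_s = 1, co2_ppm = 400, pressure_kPa = 101.325),
                       species_params("I.aquifolium"))
sprintf("T_L = %.1f C, gs = %.3f mol m-2 s-1, Ci = %.0f ppm, A_net = %.2f umol m-2 s-1",
        st$t_leaf, st$gs, st$ci, st$a_net)
#> "T_L = 27.1 C, gs = 0.040 mol m-2 s-1, Ci = 278 ppm, A_net = 4.89 umol m-2 s-1"
```

The leaf runs 2.1 °C above air temperature under this radiation load, the
intercellular CO₂ sits near 0.7 of ambient, and the states close exactly:
`a_gross = a_net + rd` at every step, energy-balance residual < 0.01 W m⁻²
wherever `converged` is `TRUE`. `run_scenarios()` chains this over sites,
species and scenarios into a budgets table; see the methods vignette
(`vignettes/thermal-acclimation-methods.Rmd`) for the model description and
the design decisions.

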