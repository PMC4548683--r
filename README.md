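# attenuate

Column- and site-scale modelling of **monitored natural attenuation (MNA)**
of dissolved chlorinated solvents in shallow groundwater, built around the
paired-column study design for 1,1,1-trichloroethane (TCA): a biotic column
fed with site groundwater and a sterilised control separate microbial
degradation from abiotic removal, and the column-calibrated parameters
drive a site-scale plume forecast.

The package is aimed at contaminant hydrogeologists and environmental
engineers who need a tested, scriptable version of that workflow:

* **Forward column model** — the 1-D advection–dispersion–reaction
  equation with one-site kinetic linear sorption and first-order aqueous
  biodegradation,

  θ ∂c/∂t = ∂/∂x(θD ∂c/∂x) − q ∂c/∂x − ρ_b ∂s/∂t − θkc,  ∂s/∂t = α(K_d c − s),

  solved by a finite-volume Crank–Nicolson scheme (C++ core) with a
  flux inlet and round-off-level discrete mass balance
  (`simulate_column()`, `mass_balance()`), plus the semi-infinite
  closed-form solution as an independent oracle (`analytic_ade()`).
* **Tracer analysis** — conductivity calibration, temporal moments, and
  least-squares inversion of dispersivity and effective porosity from a
  conservative NaCl breakthrough (`calibrate_conductivity()`,
  `temporal_moments()`, `fit_tracer()`).
* **Parameter estimation** — sorption coefficient from the sterile
  control, then the biodegradation rate constant k from the biotic column
  with sorption fixed (`fit_sorption()`, `fit_decay()`), the quasi-steady
  cross-check k = ln(c_control/c_biotic)/t_res (`quasi_steady_k()`), and
  residual-bootstrap intervals (`bootstrap_ci()`).
* **Site model** — steady 3-D groundwater flow with constant-head
  boundaries (`solve_steady_flow()`) and a no-source reactive plume
  forecast with retardation and first-order decay (`simulate_plume()`,
  `plume_metrics()`, `compare_wells()`).
* **Synthetic data** — generators for column, tracer and site data with
  the ground truth recorded alongside (`generate_column_btc()`,
  `generate_tracer_btc()`, `generate_site()`), so every estimator is
  testable by round-trip recovery.

## Worked example

Generate a noiseless synthetic column pair under the calibrated truth
(K_d = 0.068 m³/kg, k = 0.0045 d⁻¹) and invert it back:

```r
library(attenuate)

tca_column_spec(2)            # the sterile control column
#> Packed column 'column_2'
#>   length 0.3 m, diameter 0.1 m, porosity 0.289
#>   bulk density 1880 kg/m^3, flow 0.000144 m^3/d (0.1 mL/min)
#>   pore volume 681 cm^3, residence time 4.73 d

scen  <- synthetic_scenario(c0_sd = 0, noise_sd = 0)   # noiseless twin
ctrl  <- generate_column_btc(scen, sterile = TRUE,  seed = 1)
bio   <- generate_column_btc(scen, sterile = FALSE, seed = 1)
inlet <- constant_inlet(31.36, 25)

fit_sorption(ctrl, scen$spec_control, inlet,
             dispersivity = 0.005, sorption_rate = 1e-4)
#> Estimation result
#>   sorption_coeff = 0.068
#>   objective (SSR) = 2.684e-19 (mg/L)^2, converged: TRUE

fit_decay(bio, ctrl, scen$spec_biotic, inlet, dispersivity = 0.005,
          sorption_coeff = 0.068, sorption_rate = 1e-4)
#> Estimation result
#>   decay = 0.0045
#>   objective (SSR) = 3.449e-16 (mg/L)^2, converged: TRUE

# plateau cross-check: ln(31.36/30.68) / 4.84 d
quasi_steady_k(31.36, 30.68, residence_time(tca_column_spec(1)))
#> [1] 0.004526
```

The estimators recover the generating sorption coefficient and decay rate
exactly, and the closed-form quasi-steady estimate agrees with the fitted
0.0045 d⁻¹ — the influent–effluent deficit it implies at 31.36 mg/L is
0.68 mg/L over one residence time.

A command-line pipeline wraps the same functions
(`inst/scripts/attenuate.R`): `make-synthetic`, `simulate-column`,
`fit-tracer`, `fit-params`, `simulate-site` and `report`, each writing its
outputs, the resolved YAML configuration, the seed and a log.

```sh
Rscript inst/scripts/attenuate.R make-synthetic --out run1 --seed 7
Rscript inst/scripts/attenuate.R fit-params --out run1 \
    --control run1/btc_control.csv --biotic run1/btc_biotic.csv
```

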