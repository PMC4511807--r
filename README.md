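# galswitch

Tools for studying how the *rate* of extracellular glucose depletion shapes
the timing and cell-to-cell variability of galactose (GAL) network
induction in budding yeast.

When *S. cerevisiae* grows on glucose plus galactose, the GAL regulon is
repressed until glucose is nearly exhausted. In microfluidic depletion
assays — 2 % (w/v) glucose held 4 h, ramped linearly to 0 % over a
depletion time T<sub>d</sub> ∈ [0, 8] h, galactose constant at 2 % — the
time at which each cell's GAL reporter turns on, and how much that time
varies between cells, depend systematically on the depletion rate.
`galswitch` implements the computational core of that analysis for
quantitative biologists working with single-cell time-lapse data:

* **Threshold model of induction timing.** A cell initiates GAL expression
  a delay τ after glucose drops below its threshold g\*, so for a linear
  ramp

  T<sub>i</sub> = ((g<sub>s</sub> − g\*)/g<sub>s</sub>) T<sub>d</sub> + τ,  σ²(T<sub>i</sub>) = (σ²(g\*)/g<sub>s</sub>²) T<sub>d</sub>² + σ²(τ),

  with OLS fitting in the exactly-linear coordinates, delta-transformed
  95 % CIs, and bootstrap uncertainty (`predict_initiation_mean()`,
  `fit_initiation_mean()`, `fit_initiation_variance()`, `bootstrap_sd()`).
* **Delayed stochastic energy model.** A minimal Gal4p/Gal2p network
  (Hill-repressed activator, Hill-activated transporter) whose propensities
  and growth rate are scaled by an energy term
  E = max{E<sub>glu</sub>(glu), E<sub>gal</sub>(g₂), ε}; simulated with a
  delayed Gillespie algorithm (1-min capped steps for time-varying rates,
  5-min maturation delay, exponential volume growth, division at V = 2
  with binomial protein partitioning). C++ core, full reproducibility
  under R seeds (`energy_params()`, `simulate_cell()`,
  `simulate_population()`, `constant_energy_params()`).
* **Trajectory feature extraction.** Initiation points (falling-to-rising
  turn of fluorescence), accumulation times with sub-sample interpolation,
  cell-cycle lengths from budding events, retention filtering, and the
  progressive three-group Glucose/Diauxie/Galactose cycle classification
  (`detect_initiation()`, `accumulation_time()`, `classify_cycles()`).
* **Synthetic-data generator.** Populations with the statistical structure
  the analysis assumes — per-cell threshold/delay draws, V-shaped
  fluorescence with a sigmoidal rise to an 8200 ± 2000 AU plateau,
  regime-structured budding sequences — with ground-truth latents kept
  separate (`generator_config()`, `generate_threshold_population()`,
  `simulator_to_fi()`).
* **Pipeline.** End-to-end seeded runs with CSV/JSON outputs and the
  full-model vs constant-energy comparison (`run_pipeline()`,
  `accumulation_sd_curve()`, `compare_models()`).

## Worked example

Generate a synthetic population at the standard study conditions (ten
depletion times spanning 0–8 h, 150 cells each) and fit both threshold
models:

```r
library(galswitch)
gen <- threshold_params(g_star = 1.4, tau = 17, sigma_g_star = 0.2,
                        sigma_tau = 18, g_s = 2)
data <- generate_initiation_dataset(gen, Td_hr = depletion_grid(),
                                    n_cells = 150, seed = 1)
fit_initiation_mean(data, g_s = 2)
#> Initiation-time fit (OLS on condition means )
#>   g* = 1.405 % w/v  [1.388, 1.421]
#>   tau = 16.99 min    [14.60, 19.37]
#>   R^2 = 0.9988 over 10 conditions
fit_initiation_variance(data, g_s = 2)
#> Initiation-time variance fit (OLS on Td^2)
#>   sigma(g*) = 0.201 % w/v
#>   sigma(tau) = 19.87 min
#>   R^2 = 0.9892 over 10 conditions
```

The fitted threshold (1.405 % w/v) and delay (17.0 min) recover the
generating values; the variance fit recovers the threshold SD (0.201 %)
and delay SD (19.9 min) within sampling error. The same machinery applied
to the stochastic energy model reproduces its signature prediction — the
dispersion of protein-accumulation times is non-monotone in the depletion
time for the full model but monotone for a constant-energy control:

```r
p <- energy_params()
full  <- accumulation_sd_curve(p, n_cells = 300, seed = 100)
const <- accumulation_sd_curve(constant_energy_params(p),
                               n_cells = 300, seed = 600)
compare_models(full, const)
#> Accumulation-time SD: full energy model vs constant-E control
#>      Td_hr   sd_full  sd_const   difference
#>  0.0000000 1.6778817 0.1463312  1.531550479
#>  0.8888889 1.2810515 0.1960072  1.085044273
#>  1.7777778 1.4992988 0.2610340  1.238264790
#>  2.6666667 0.3903820 0.3380688  0.052313197
#>  3.5555556 0.4263495 0.4175712  0.008778342
#>  4.4444444 0.4585075 0.4503842  0.008123302
#>  5.3333333 0.5049380 0.5197393 -0.014801361
#>  6.2222222 0.5268278 0.5304197 -0.003591937
#>  7.1111111 0.5801325 0.5759558  0.004176613
#>  8.0000000 0.6825737 0.6168305  0.065743261
#>   full-model SD minimum at Td = 2.67 hr (interior: TRUE)
#>   constant-E SD minimum at Td = 0.00 hr (monotone: TRUE)
```

With carbon-source-dependent energy, cells depleted instantaneously crash
onto a heterogeneous basal metabolic rate before they can build
transporter, making accumulation slow and highly variable (SD ≈ 1.7 h at
T<sub>d</sub> = 0); slowly depleted cells hand over from glucose-powered
to galactose-powered growth smoothly (SD minimal at intermediate
T<sub>d</sub>). See `vignette("gal-induction-timing")` for the model,
its assumptions, and all calibration choices.

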