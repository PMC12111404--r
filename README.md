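# dephenolize

Surrogate-based optimization of rapeseed-cake dephenolization, plus the
protein-chemistry bookkeeping that goes with it.

Rapeseed press cake is a protein-rich oil by-product whose phenolics
(sinapine, tannins) degrade protein isolates unless removed by an ethanol
wash before alkaline extraction. The wash has three controls — ethanol
concentration (70–90 %), solid-to-liquid ratio (10–60 mL/g) and ultrasound
time (5–25 min) — and one response, the total phenolic content (TPC)
extracted, in mg gallic-acid equivalents per 100 g dry cake. This package
implements the full response-surface workflow used to optimize such
processes:

* a three-layer tanh perceptron surrogate
  `ŷ = b₀ + Σₖ wₖᵒ tanh(bₖ + Σᵢ wₖᵢ xᵢ)` on standardized variables,
  trained by Levenberg–Marquardt on the penalized least-squares objective
  `Q(θ) = Σ r² + α‖θ‖²` (`train_lm`), with repeated-initialization
  topology selection by mean R² (`select_topology`);
* signed connection-weight relative importance
  `RIᵢ = 100·Σₖ wₖᵢ wₖᵒ / Σᵢ'|Σₖ wₖᵢ' wₖᵒ|` (`yoon_ri`);
* particle-swarm maximization over the process box (20 particles, 800
  iterations, c₁ = 1.5, c₂ = 2, constant inertia 0.729) with restart-
  stability reporting and a brute-force grid oracle (`pso_minimize`,
  `optimize_surrogate`, `grid_oracle`);
* a synthetic experiment generator with a known optimum (calibrated
  noiseless maximum 1887.76 mg GAE/100 g at 84 % / 60 mL/g / 15 min) and
  known main-effect ordering (S/L > EtOH > time), with Monte-Carlo Sobol
  ground truth (`make_default_spec`, `simulate_experiments`,
  `true_optimum`, `true_main_effects`);
* explicit chemistry formulas: extraction-yield mass balance
  (`protein_mass_in_feed`, `protein_mass_in_isolate`, `extraction_yield`),
  Bradford concentration with the 1.9899 BSA calibration factor
  (`bradford_concentration`), Folin–Ciocalteu GAE quantitation
  (`tpc_gae`), amino-acid summaries against WHO thresholds (`aa_summary`)
  and the TCA-soluble digestibility gain (`digestibility_gain`).

See `vignettes/surrogate-optimization.Rmd` for the model, the design
choices and their rationale.

## Worked example

```r
library(dephenolize)
cfg <- pipeline_config(master_seed = 7)  # 33-run synthetic table, defaults
report <- run_pipeline(cfg, verbose = TRUE)
report
```

prints (computed output):

```
Dephenolization optimization report
  data: 33 runs (synthetic: y0=2674.33 e*=84 sig_e=15 k_r=25 t*=15 sig_t=20 noise_sd=40 seed=1181570764)
  surrogate: 10 hidden neurons, R2 = 0.9979, MAE = 10.10 mg GAE/100 g
  importance: etoh +26.66%, sl +67.14%, time -6.20%
  optimum: 81.1% EtOH, 60 mL/g, 9.7 min
  predicted TPC: 1864.33 mg GAE/100 g (restart spread 1.54%)
```

Reading it: the surrogate fits the noisy 33-run table closely (R² 0.998,
MAE ≈ 10 mg GAE/100 g against noise sd 40); the connection weights
attribute about two thirds of the response to the solid-to-liquid ratio,
about a quarter to ethanol, and a minor (negative) share to time — the
generator's true effect ordering; and the swarm pushes S/L to its 60 mL/g
bound with near-optimal ethanol, predicting a maximum within 1.3 % of the
true noiseless optimum (1887.76 mg GAE/100 g). All five restarts agree to
1.5 %.

The chemistry helpers are one-liners:

```r
m1 <- protein_mass_in_feed(100, 40.42)   # 40.42 g protein in the feed
m3 <- protein_mass_in_isolate(15, 80)    # 12 g in the isolate
extraction_yield(m1, m3)                 # 29.6883 %
bradford_concentration(1.0)              # 1.9899 mg/mL
```

A thin command-line front end over the same functions lives at
`inst/scripts/dephenolize-cli.R` (subcommands `pipeline`, `yield-calc`,
`aa-summary`).

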