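# kuramotoRC

Physics-informed hybrid reservoir computing for forecasting nonlinear
oscillator networks, with the Kuramoto and bi-harmonic Kuramoto simulators,
evaluation protocol and experiment harnesses needed to study it end to end.

## What it does

Surrogate models of oscillator networks (neural populations, synthetic gene
circuits, power grids) must cope with imperfect knowledge of the real
system. This package implements and benchmarks a *hybrid reservoir
computer*: a leakless echo state network

    r_{t+1} = tanh(A r_t + B u_t)

whose input and readout are augmented with a one-step prediction
`ũ_{t+1}` from an expert ODE model — the standard Kuramoto network

    dθ_i/dt = ω_i + (K/N) Σ_j sin(θ_j − θ_i).

The reservoir input is the concatenation `[ũ_{t+1}; u_t]` (each node wired
to the expert block with probability KR, the knowledge ratio) and the linear
readout `C`, the only trained component, maps `[ũ_{t+1}; g(r_{t+1})]` to the
next state by ridge regression (`g` squares even-indexed states). States are
*phase components* `(cos θ_i, sin θ_i)`, renormalized to the unit circle at
every closed-loop step.

Two evaluation tasks are built in:

* **Parameter error** — the expert equals the ground truth up to
  multiplicative parameter error `p → (1+ξ)p`, `ξ ~ N(0, 0.05²)`; forecast
  quality is the trajectory-mean NMSE.
* **Residual physics** — the ground truth is the *bi-harmonic* Kuramoto
  model (an extra harmonic `a sin(2(θ_j−θ_i)+γ_2)` plus phase shift `γ_1`,
  producing heteroclinic cycles and self-consistent partial synchrony that
  the expert cannot express); quality is the valid time `t*`, the longest
  prefix with NMSE ≤ 0.4.

The shared protocol simulates 6200 s at Δt = 0.1 s, trains on the first
1000 steps and forecasts twenty 2500-step test segments after 100-step
warm-ups, over ensembles of independently initialized reservoirs.

## Worked example

Compare hybrid, standard and expert-only forecasters on the
heteroclinic-cycles regime (desk scale: 5 reservoirs, 5 test segments):

```r
library(kuramotoRC)
plan <- segmentation_plan(n_segments = 5)
for (mk in c("hybrid", "standard", "ode_control")) {
  print(run_ensemble("residual_physics", "heteroclinic_cycles", mk,
                     n_instantiations = 5, metric = "valid_time",
                     plan = plan, base_seed = 7))
}
#> Forecast ensemble: residual_physics / heteroclinic_cycles / hybrid
#>   5 instantiations x 5 forecasts; valid_time = 2.324 +/- 0.2896
#> Forecast ensemble: residual_physics / heteroclinic_cycles / standard
#>   5 instantiations x 5 forecasts; valid_time = 0.916 +/- 0.06542
#> Forecast ensemble: residual_physics / heteroclinic_cycles / ode_control
#>   5 instantiations x 5 forecasts; valid_time = 0.508 +/- 0.01789
```

The numbers are mean ± sd (over reservoir instantiations) of each
instantiation's mean valid time in seconds: on this regime the hybrid stays
within the 0.4-NMSE envelope roughly 2.3 s (23 steps) — more than twice the
standard reservoir and four times the mis-specified expert integrated alone.
`run_sweep()` and `run_grid_search()` drive the full hyper-parameter
studies; `report_summary()` aggregates their long-format tables. A thin CLI
over the same functions lives at `inst/cli/kuramotoRC.R`
(`simulate`, `sweep`, `gridsearch`, `report`).

See the vignette (`vignettes/hybrid-reservoir-forecasting.Rmd`) for the
models, protocol, parameter meanings and known limitations.

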