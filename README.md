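# lactomc

Lactate-based model predictive control of adherent cell expansion.

Cell-therapy manufacturing expands adherent progenitor cells whose number
cannot be measured until harvest, so feeding usually follows a fixed
protocol regardless of how each batch is actually doing. `lactomc` is for
bioprocess engineers and modellers who want to close that loop with the one
measurement that is nearly free: lactate in the spent medium. Since fresh
medium contains almost no lactate and cells in high-glucose medium produce
two lactate molecules per glucose consumed, the *cumulative* lactate
produced since seeding is a soft sensor of biomass, and the amount of
medium replaced becomes the control input.

The package provides:

* **Dilution mass balance** — a medium exchange of fraction `U` drops the
  concentration to `C2 = C1·(1−U) + C0·U`; inverting this bookkeeping turns
  daily concentration samples plus a replacement log into the cumulative
  lactate output `y(t) = (C(t) − C0) + Σ_k U(k)·(C1(k) − C0)` and the
  cumulative medium input `u(t)`, interpolated piecewise-linearly onto an
  hourly grid.
* **Time-varying DARX identification** — the first-order model
  `y_t = B(z⁻¹,t)/A(z⁻¹,t) u_{t−δ} + e_t/A(z⁻¹,t)` with a fixed pole `a1`
  and a drifting gain `b0,t`, estimated by least squares plus a random-walk
  Kalman filter with fixed-interval smoothing; model orders selected by
  R²/YIC scan; goodness of fit as `NRMSE = 1 − ‖y_ref − y_fit‖ /
  ‖y_ref − mean(y_ref)‖` (1 = perfect).
* **Receding-horizon control** — minimising
  `J = Σ δ(j)[ŷ(k+j|k) − r(k+j)]² + Σ λ(j)[Δu(k+j−1)]²` over the medium
  moves, with non-negative moves, per-step bounds, and an optional 20 mM
  lactate-concentration cap; closed-form unconstrained solution, small QP
  otherwise.
* **A mechanistic virtual culture** — logistic-Monod growth with lactate
  inhibition and starvation-driven death, generating realistic multi-donor
  12-well-plate expansion datasets under the six benchmark feeding
  strategies for end-to-end validation.

## Worked example

```r
library(lactomc)

# one virtual donor cultured under the six benchmark feeding strategies
records <- generate_dataset(n_donors = 1, n_replicates = 1, master_seed = 7)
rec <- records[["d1_c5_r1"]]       # condition 5: 50% replacement daily
rec
#> <culture_record> d1_c5_r1: 6 samples over 120 h, 4 replacement events, V = 1 mL
#>   harvested cells: 1.81e+05

# dilution mass balance -> hourly cumulative trajectories
pair <- resample_pair(rec)
pair
#> <trajectory_pair> d1_c5_r1: 121 points over 120 h; y in [0, 14.6] mM-eq, u total 3 mL

# identify the fixed-pole, time-varying-gain DARX model
model <- estimate_darx_tv(pair$y, pair$u, orders = c(1, 1), delay = 0,
                          grid = pair$grid)
model
#> <darx_model> na=1 nb=1 delay=0 on 121-point grid; a1 in [-1.004, -1.004],
#>   b0 in [0.01996, 0.06488], sigma2=0.000568
round(100 * attr(model, "fit")$nrmse, 2)
#> [1] 99.89

# replay the culture in closed loop: the identified model as the plant,
# the measured trajectory as the reference
plant <- darx_model(1, 1, 0, a = model$a, b = model$b, grid = model$grid)
trace <- receding_horizon_simulate(plant, pair, config = mpc_config(u_min = 0))
trace
#> <control_trace> 121 samples; output NRMSE 0.9960, input NRMSE 0.9598, total medium 3 mL
```

The record's 6 daily samples and 4 exchanges become a 121-point hourly
trajectory pair; the identified model reproduces its own record with a
one-step self-fit of 99.89 % NRMSE, and the controller re-creates the
culture's feeding history to within 4 % on the input while keeping the
simulated output within 0.4 % of the reference. Endpoint summaries come out
in the benchmark study's units:

```r
y <- cumulative_lactate(rec)
total <- cumulative_medium(benchmark_schedules()$schedules[["5"]], 1)$total
c(efficiency_1e4_per_mL = medium_efficiency(rec$harvested_cells, total) / 1e4,
  lactate_rate_1e7 = 1e7 * lactate_per_cell_rate(y[length(y)], rec$harvested_cells, 120))
#> efficiency_1e4_per_mL      lactate_rate_1e7
#>              6.038658              6.728707
```

i.e. 6.0 × 10⁴ cells harvested per mL of medium used and 6.7 × 10⁻⁷ mM of
lactate produced per cell per hour — squarely in the ranges the benchmark
study reports for this feeding strategy.

A thin command-line front-end wrapping these functions ships in
`inst/cli/lactomc` (`generate`, `identify`, `control`, `evaluate`
subcommands).

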