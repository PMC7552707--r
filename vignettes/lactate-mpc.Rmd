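---
title: "Lactate-based model predictive control of adherent cell expansion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lactate-based model predictive control of adherent cell expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactomc)
```

## The problem

Adherent progenitor cells (such as human periosteum-derived cells) cannot be
counted during expansion without sacrificing the culture, so feeding is
usually run open-loop from a fixed protocol, over-feeding most batches to
protect the worst ones. Lactate offers a way out: in high-glucose medium the
cells produce roughly two lactate molecules per glucose consumed, fresh
medium contains almost none, and concentrations are cheap to measure in the
spent samples that are drawn anyway. The *cumulative* lactate produced since
seeding therefore acts as a soft sensor of biomass, and the amount of medium
replaced becomes the manipulated variable of a feedback loop.

`lactomc` implements that loop end to end: the dilution mass balance that
turns sparse concentration measurements plus a replacement log into
cumulative trajectories, a time-varying model linking cumulative medium to
cumulative lactate, a receding-horizon controller tracking a reference
trajectory, and a mechanistic virtual culture used as the test bed.

## From raw measurements to trajectories

A medium exchange replaces a fraction $U(k)$ of the working volume with
fresh medium of lactate concentration $C_0$, so the concentration drops from
$C_1(k)$ to

$$C_2(k) = C_1(k)\,(1-U(k)) + C_0\,U(k).$$

Tracking what each exchange removed, the lactate *produced* by the cells up
to time $t$, expressed per working volume (mM-equivalent), is

$$y(t) = \bigl(C(t) - C_0\bigr) + \sum_{k:\,t_k < t} U(k)\,\bigl(C_1(k)-C_0\bigr),$$

which is continuous across exchanges and non-decreasing as long as the
culture only ever adds lactate. A sample drawn at an exchange time is
treated as the pre-exchange measurement (sample first, then replace — the
wet-lab order). When $C_1(k)$ was not measured it is reconstructed from the
first post-event sample by inverting the dilution balance; a record whose
pre-event concentration is unrecoverable (a 100 % exchange with no co-timed
sample) is rejected rather than guessed at.

Daily samples are far too sparse for hourly control decisions, so both
cumulative series are interpolated piecewise-linearly onto an hourly grid.
Interpolating the *cumulative* series (not raw concentrations) absorbs the
concentration step at each exchange into smooth knots. The cumulative
medium input $u(t)$ includes the 1 mL seeding fill by default — that is the
only convention under which harvested cells divided by total medium
reproduces the benchmark efficiency table — and is represented either as a
linear ramp between events (default) or as a right-continuous staircase.
No extrapolation beyond the last sample is ever performed.

## The time-varying DARX model

The input–output relation is modelled as a first-order DARX (dynamic
auto-regressive exogenous) structure

$$y_t = \frac{B(z^{-1},t)}{A(z^{-1},t)}\,u_{t-\delta} + \frac{1}{A(z^{-1},t)}\,e_t,
\qquad e_t \sim N(0, \sigma^2),$$

with $A = 1 + a_1 z^{-1}$ and $B = b_{0,t}$: a *fixed* pole and a
*time-varying* gain. A single drifting coefficient keeps the model
interpretable — $b_{0,t}$ measures how strongly additional medium converts
into additional lactate production. Cultures with leftover medium show a low
$|b_{0,t}|$ (resources wasted), starved cultures a high one; on the
synthetic study the minimal-feeding condition's mean $|b_{0,t}|$ is roughly
double the full-replacement condition's.

### Estimation

Estimation is two-stage:

1. a whole-record constant-parameter least-squares fit supplies the
   initial coefficients and the innovation variance $\hat\sigma^2$;
2. a Kalman filter over the joint coefficient state $(a_1, b_{0,t})$, with
   random-walk drift variance $\mathrm{nvr}\cdot\hat\sigma^2$ on the gain
   and *zero* drift variance on the pole, followed by fixed-interval (RTS)
   smoothing.

Giving the pole a zero drift variance — constant but unknown — rather than
freezing it at the stage-1 value matters: when $b_{0,t}$ genuinely drifts,
the constant-parameter regression absorbs part of the drift into a biased
pole, and because $y$ is large a pole error of 0.005 can corrupt the whole
gain trajectory. Letting the filter keep learning the pole removes that
bias; in simulation experiments (pole $-0.98$, gain drifting 0.2 to 0.4
over 121 hourly samples, 1 % noise) the smoothed gain tracks the truth to
about 2 % of its range.

One caveat is fundamental rather than numerical: with a smooth ramp-like
input the pole and a drifting gain are *not* jointly identifiable — a
slightly more integrating pole with a flatter gain reproduces the data
essentially exactly (a likelihood ridge). Parameter-recovery experiments
therefore use a persistently exciting step-type input; on real cumulative
feeding inputs the estimated coefficient trajectories should be read as one
valid representation of the dynamics, not as uniquely determined physical
constants.

### Tunable estimator settings

* `nvr` (default 0.1): the noise-variance ratio, i.e. how far the gain may
  drift per hour relative to the measurement noise. The default was fixed
  from the recovery experiments above: large enough to follow drifts of
  tens of percent over a five-day record, small enough not to chase 3 %
  measurement noise. Raising it never degrades the one-step self-fit (more
  freedom), at the price of noisier coefficient estimates.
* `init_covariance` (default 100): a diffuse prior on the initial
  coefficients; after a handful of samples it is forgotten.
* `fix_a1` (default `TRUE`): zero drift on the pole. Setting it `FALSE`
  lets the pole drift like the gain.
* Order selection scans $n_a, n_b \in \{1,2\}$ and $\delta \in \{0,1\}$;
  candidates within 0.01 of the best one-step $R^2$ are re-ranked by the
  Young identification criterion
  $\mathrm{YIC} = \ln(\hat\sigma^2/\sigma_y^2) + \ln\bigl(\tfrac1{n_p}\sum_i
  p_{ii}\hat\sigma^2/\hat\theta_i^2\bigr)$, with ties broken towards fewer
  parameters and shorter delays. Goodness of fit is reported as
  $\mathrm{NRMSE} = 1 - \lVert y_{\mathrm{ref}} - y_{\mathrm{fit}}\rVert /
  \lVert y_{\mathrm{ref}} - \overline{y_{\mathrm{ref}}}\rVert$ (Euclidean
  norm; 1 is a perfect fit), usually quoted as a percentage.

## The receding-horizon controller

At each decision the controller minimises

$$J(N_c, N_p) = \sum_{j=1}^{N_p} \delta(j)\,[\hat y(k+j\mid k) - r(k+j)]^2
             + \sum_{j=1}^{N_c} \lambda(j)\,[\Delta u(k+j-1)]^2$$

over the move sequence $\Delta u$, applies the first move, and re-plans one
sample later. Predictions iterate the DARX recursion with the gain held at
its latest smoothed value (no future-parameter look-ahead) and the future
cumulative input built from the moves, $u(k+j) = u(k) + \sum_{i \le
\min(j,N_c)} \Delta u_i$; the prediction is affine in the moves, so the
unconstrained problem has a closed-form least-squares solution and box
bounds on the moves turn it into a small convex quadratic program (solved by
projected quasi-Newton iterations, verified against exhaustive grid search).

Defaults, all exposed in `mpc_config()`: $N_p = 24$ samples (one day ahead
on the hourly grid, the natural actuation cadence), $N_c = 4$,
$\delta(j) = 1$, $\lambda(j) = 0.1$, moves bounded below by zero — medium
cannot be un-replaced — and above by the working volume per step. These are
tuning knobs, not claims; analysis configurations (e.g. $\lambda = 0$,
unbounded moves for deadbeat tracking studies) are equally valid.

Two constraints from the application are built in but off by default, since
a well-fed culture never approaches them: per-step move bounds, and a cap
on the lactate *concentration* (20 mM, the commonly quoted toxicity
threshold). Because the model predicts cumulative production, the
controller converts predictions back to concentration through the dilution
bookkeeping (exchange first, production within the period after) and, when
the cap would be violated, iteratively raises the lower bound of the
responsible move — forcing extra dilution — until the predicted
concentration path stays below the cap. Infeasibility (no dilution
head-room under the move bounds) is reported as an error, not silently
clipped.

## The virtual culture plant

No raw trajectories are published for the benchmark study, so validation
runs against a mechanistic virtual culture. Its state is cell number $X$,
a lumped substrate proxy $S$ (glucose *and* growth factors), lactate $L$
and the production ledger; per hour,

$$\mu = \mu_{\max}\,\frac{S}{K_s+S}\,\frac{K_i}{K_i+L}\,
        \Bigl(1-\frac{X}{X_{\max}}\Bigr), \qquad
  k_d = d_{\max}\Bigl(1 - \frac{S}{K_s/10+S}\Bigr),$$

$$\dot X = (\mu - k_d)\,X, \qquad
  \dot L = q_{\mathrm{lac}}\,\frac{X}{10^5}\,\frac{S}{K_s/10+S}, \qquad
  \dot S = -\tfrac12 \dot L,$$

integrated by classical fixed-step RK4 at $\mathrm{d}t = 0.1$ h with exact
event handling at exchange times (both $S$ and $L$ are diluted by the
exchanged fraction; the production ledger is not). The $2{:}1$
lactate-to-substrate yield anchors production to consumption. Two
deliberate asymmetries drive the biology:

* production (maintenance glycolysis) saturates at a ten-fold lower
  substrate level than growth, so starved cultures keep producing lactate
  after proliferation stalls;
* sustained starvation kills cells ($k_d$), so under-fed wells harvest
  fewer cells than ever lived — which is exactly why minimal-replacement
  cultures show the *highest* lactate per harvested cell.

Without the death term that signature pattern cannot emerge: substrate
exhaustion would stop production and growth together and the
lactate-per-cell ratio would stay flat across feeding strategies.

Default parameter means (packaged in `default_donor_params.yaml`) were
calibrated once so that the six benchmark feeding strategies give endpoint
cumulative lactate of 10–16 mM-equivalent, harvests of about 0.9–2.1 × 10⁵
cells with full daily replacement highest and 10 % replacement lowest, and
peak concentrations near 11 mM — comfortably below the 20 mM toxicity
threshold, as in the benchmark experiments. Donor-to-donor variability is
log-normal with CVs of 5–12 % on the kinetic parameters, chosen so the
population harvest CV per condition falls in the 5–30 % band the benchmark
harvest table shows; replicates within a donor differ by a 5 % seeding
jitter and 3 % multiplicative (log-normal) measurement noise — relative
noise, because concentration analysers have relative error. The time-zero
sample is recorded as the fresh-medium calibration value.

What the plant does *not* emulate: pH and dissolved-gas dynamics,
evaporation, metabolic shifts, passage effects, or any spatial
heterogeneity. Passing tests against this plant therefore demonstrate that
the identification and control machinery works on realistic monotone,
event-punctuated trajectories with donor-scale variability — not that the
specific kinetic constants describe any real donor.

## Numerical choices

* Interpolation queries outside the knot span raise an error (no
  extrapolation); refining the grid and downsampling back is exact.
* The least-squares stage rejects rank-deficient regressors ("input not
  sufficiently exciting") instead of returning pseudo-inverse estimates.
* The RTS smoother adds a $10^{-12}$-scaled ridge before inverting the
  predicted covariance, which collapses to singularity on noise-free
  records.
* The QP solver seeds the box-constrained search at the clipped
  unconstrained solution; the concentration-cap loop linearises the
  dilution head-room and terminates after 25 rounds or the first feasible
  path.
* Closed-loop simulations treat a non-finite plant output as divergence
  and stop with an error rather than producing NaN traces.

## Problem sizes

The shipped tests and the acceptance script run, by choice, at the scale of
the benchmark study itself: 54 wells (3 donors × 6 conditions × 3
replicates), 121-point hourly grids, 1 000 randomised records for the
mass-balance identities, 10-seed repetitions for order-selection and
ordering checks, and grid-search verification of the controller on two-move
problems. A full acceptance run takes well under a minute on a laptop-class
machine.

## Known limitations

* The coefficient trajectories of the DARX model are representation, not
  biology: on poorly exciting inputs different (pole, gain-path) pairs are
  observationally equivalent.
* The controller assumes the identified model class is adequate over the
  prediction horizon; there is no explicit robustness margin or
  disturbance model beyond the move penalty.
* The virtual plant's parameters are calibrated to endpoint summary tables
  of one published study, not fitted to trajectories; absolute simulated
  values should be read as orders of magnitude.
* Real-time deployment (instrument interfaces, asynchronous measurements,
  missed samples) is out of scope; records are assumed complete and
  time-stamped on a regular daily protocol.
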