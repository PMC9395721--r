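---
title: "Methods: simulating a deep Cox survival network on RRAM crossbars"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating a deep Cox survival network on RRAM crossbars}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

memsurv is a design-flow simulator for running a DeepSurv-style survival
network on an analog in-memory-computing substrate built from resistive
memory (RRAM) crossbar arrays. It chains six stages: a calibrated synthetic
survival-data generator, a deep Cox proportional-hazards network and
trainer, incremental network quantization (INQ) onto a 17-level weight
grid, a behavioral statistical model of multilevel RRAM programming and
drift, differential weight mapping plus Monte-Carlo crossbar inference, and
an analytic latency/power/energy model of the accelerator. This vignette
records the models behind each stage, the tunable parameters and their
defaults, and the design decisions taken where the design was genuinely
open.

## The survival model and the network

Survival data consist of covariates $x$, an observed time $T$ and an event
indicator $E$. The Cox proportional-hazards model factorizes the hazard as
$\lambda(t \mid x) = \lambda_0(t)\, e^{h(x)}$; DeepSurv replaces the linear
log-risk $h(x)=\beta^T x$ with a small feed-forward network
$\hat h_\theta(x)$. The architecture here is fixed at 6–48–48–1: five
patient covariates (age, sex, BMI, CHF, MIORD) plus a constant bias input
of 1, two rectifier hidden layers of 48 neurons, and a linear output
neuron whose value is the log-risk. Per-layer additive biases are kept as
well; in the hardware mapping they are applied digitally, never stored in
RRAM cells.

Training minimizes the negative log partial likelihood
$$L(\theta) = -\sum_{i:E_i=1}\Big[\hat h_\theta(x_i) -
\log\!\!\sum_{j:T_j \ge T_i}\!\! e^{\hat h_\theta(x_j)}\Big],$$
with Breslow's convention for tied event times (ties share the full risk
set at their common time) — the standard default when the tie-handling
rule is otherwise unspecified. Ranking quality is scored by Harrell's
concordance index: the credited fraction of permissible pairs (earlier
time carries an event), with tied risks credited 0.5. Baseline-hazard
estimation and absolute survival curves are out of scope: the concordance
index depends only on the risk ordering.

Trainer choices (all in `train_config()`):

* **Optimizer.** Full-batch RMSprop ($\rho = 0.9$, $\epsilon = 10^{-8}$),
  a momentum-free adaptive method; learning rate default $10^{-3}$,
  500 epochs. Backpropagation and the $O(n \log n)$ partial-likelihood
  gradient are implemented directly in R; the gradient is verified against
  finite differences in the test suite.
* **Dropout** 0.2 per hidden layer during training (inverted convention),
  always disabled at inference.
* **Weight range.** Weights are hard-clipped to $[-2, +2]$ after every
  optimizer step, so a finished network always fits the conductance range
  the 17-level differential grid can represent. Clipping (rather than a
  penalty) is the simplest mechanism that makes the bound exact.
* **Input scaling.** Covariates are min-max scaled to $[0,1]$ (constants
  stored on the network object). Min-max rather than z-scoring is
  deliberate: the crossbar DACs emit non-negative read voltages, so
  network inputs must be non-negative for the analog pass to equal the
  digital one exactly.
* **Determinism.** Every stochastic operation in the package draws from a
  local RNG seeded by the call's integer seed and restores the global RNG
  state afterwards; identical calls are bit-identical.

## The synthetic cohort generator

The generator emulates a heart-attack-registry cohort of 1,638 subjects of
which 42.1% die during follow-up with a median observed death time of
516 days — the two marginal statistics the study states. Event times
follow a Weibull proportional-hazards model
$\lambda(t\mid x) = \lambda_0 k t^{k-1} e^{\beta^T(x - x_{ref})}$ (shape
$k = 1.1$, a mild aging hazard typical of post-infarction cohorts);
censoring is administrative at 2,000 days plus independent exponential
dropout. The Weibull family was chosen for its closed-form quantiles,
which make median calibration a one-dimensional root solve.

Covariate marginals are not stated in the study and are package defaults
chosen to be clinically plausible for an acute-myocardial-infarction
registry: age $\sim N(70, 12^2)$ truncated to $[30,100]$ years, BMI
$\sim N(27.5, 5.2^2)$ truncated to $[15,60]$ kg/m², sex
$\sim\mathrm{Bern}(0.40)$, CHF $\sim\mathrm{Bern}(0.45)$, MIORD
$\sim\mathrm{Bern}(0.30)$; log-hazard ratios 0.035/yr (age), 0.30 (sex),
−0.035 per kg/m² (BMI), 0.90 (CHF), 0.45 (MIORD). `calibrate_generator()`
fixes the remaining two free parameters — the Weibull rate scale and the
dropout rate — by nested root solves on common random numbers
($n \ge 10{,}000$), so the achieved event fraction and median death time
are deterministic functions of the parameters and the calibration is
reproducible. The shipped defaults are the output of that calibration at
$n_{cal} = 50{,}000$.

What the generator does *not* emulate: covariate correlations (age–CHF,
say), time-varying effects, non-proportional hazards, or informative
censoring. Passing tests therefore demonstrate correctness of the
pipeline under a well-specified proportional-hazards world, not
performance on the real registry data.

## Incremental network quantization

The differential conductance representation yields 17 representable
weights, $\{-2.00, -1.75, \dots, +2.00\}$ in steps of 0.25 weight units
(1 weight unit = 100 µS). INQ locks growing fractions of the weights onto
this grid — 50, 75, 87, 100% (87 as printed in the source study, not
87.5) — retraining between steps so the free weights compensate the
rounding of the locked ones.

Open details resolved as follows (all deterministic):

* Per layer, $\lceil f \cdot \mathrm{count}\rceil$ weights are locked at
  cumulative fraction $f$; masks never unlock.
* Selection policies: greatest absolute value, lowest absolute value
  (the default — the most training-stable choice in the source study),
  and lowest quantization error. Ranking ties break in storage order.
* Rounding maps to the nearest level; exact midpoints break toward the
  smaller absolute level, and out-of-range values clamp to $\pm 2$.
* Locked weights still receive gradient between projections and are
  re-projected onto the grid at the end of every epoch ("rounded at the
  end of each training epoch"); selection is recomputed only at step
  boundaries. After the final step every weight lies exactly on the grid.

## The RRAM device model

A cell programmed to level $L_k$ (targets 25, 50, …, 225 µS) is modeled
*behaviorally*: pulse-level program-and-verify physics is out of scope and
the programming recipes are carried only as annotation in the YAML config.
The programmed state at time $t$ hours is a two-component Gaussian
mixture: with probability $1 - p_d$ the cell stays at
$N(G_{trg}, \sigma_0^2)$, and with probability $p_d$ it belongs to a
drifting subpopulation at
$N\!\big(G_{trg} + s\,\mu_\infty (1 - e^{-t/\tau_d}),\ (g\sigma_0)^2\big)$,
with drift sign $s$, saturation amplitude $\mu_\infty$, time constant
$\tau_d = 24$ h (so the drift has effectively saturated by 168 h, the
one-week horizon used throughout), and spread growth $g$. Samples are
truncated at 0 µS (conductance is physical) by bounded resampling; the
analytic mixture moments ignore the truncation, which only matters when a
drifted component approaches 0 µS.

The two programming algorithms differ only in how L2–L5 are reached:
ML-Set programs them from the reset state (one pass, cost 1 per cell) and
leaves a sizable downward-drifting subpopulation; ML-Hybrid reaches them
by a controlled reset from a high state (reset + set, cost 2 per cell)
with a much smaller displaced fraction of inverted sign. L6–L9 are
produced by the same set procedure in both algorithms and share identical
models — the config loader enforces this. All numeric values in
`device_defaults.yaml` are qualitative calibrations, not measurements:
they reproduce the directional facts (L2–L5 most drift-affected under
ML-Set, drift magnitude decreasing toward higher levels, hybrid
mitigation with inverted sign, large L1 instability), and the package's
quantitative claims are restricted to self-consistency and closed-form
checks rather than figure numerics.

## Differential mapping and the base-level strategy

A quantized weight $W$ (µS target $= 100 W$) is realized as
$W = G^+ - G^-$ on two cells. Among all level pairs realizing the target
exactly, `assign_pairs()` picks the pair whose conductance midpoint is
closest to the chosen *base level*'s target; ties break toward the lower
total conductance (the energy-relevant quantity). This midpoint rule is
our formalization of "using each conductance level as a starting point":
it reproduces the expected behavior that weights near 0 use the levels
adjacent to the base, and for base L6 it selects, e.g., (150, 125) µS for
a +25 µS weight. A zero weight maps to (base, base). L1 — the unstable
reset state — is never a base level and enters assignments only where it
is unavoidable: the two full-scale weights ±200 µS, which force the
(225, 25) pair. The statistic maps (`sigma_map()`,
`quant_error_rate_map()`) cover L2–L9 only, with independent draws for
the two cells of a pair (they are distinct physical devices). The error
bound of the quantization-error-rate map is 12.5 µS — half the grid step,
i.e. the distance at which a programmed weight reads closer to a
neighboring level.

## Crossbar inference and read power

The network occupies four 64×64 crossbars (positive and negative polarity
for each hidden layer); the final 48→1 combination and all biases stay
digital. Per layer, activations are scaled so the batch maximum maps to
`v_read_max` (default 0.3 V, a typical non-disturbing read amplitude;
negative values clip to 0 V at the DAC, a no-op for in-range data since
inputs are min-max scaled and hidden activations are post-rectifier), the
two polarity arrays are read by Ohm/Kirchhoff MVM, and the DSP subtracts,
un-scales, adds the bias and rectifies. The voltage scale cancels
algebraically, so risks are exactly invariant to `v_read_max`, and the
ideal-device analog pass equals the quantized digital forward pass to
round-off — an equivalence the test suite asserts at $10^{-9}$ relative.

Read power is Joule dissipation in the cells,
$P = \sum_{ij} V_i^2 G_{ij}$ over all four arrays, averaged over the
inference inputs; a supply-referenced convention
($V_{supply}\sum V_i G_{ij}$) is available behind a flag since the exact
accounting convention is not fixed by the source material. Layer-2
voltages for power come from the ideal-device activations, decoupling the
power figure from any single Monte-Carlo draw. ADCs and DACs are ideal
(infinite resolution); converter quantization noise, wire resistance,
sneak paths and read noise are out of scope. The three studied operating
points are `operation_mode("P")` (ML-Set, base L9, accuracy-first),
`"S"` (ML-Set, base L6) and `"H"` (ML-Hybrid, base L2), and the package
reproduces their qualitative power ordering P > S > H.

Monte-Carlo evaluation (`monte_carlo_cindex()`) redraws every cell from
its level distribution at time $t$, rebuilds the arrays, and scores the
concordance index per realization. The full-scale experiment
(1,000 runs × 8 base levels × 2 algorithms × 2 time points) runs in
minutes on one CPU; the shipped tests use scaled versions (20–50 runs on
a 300-subject cohort) that exercise the same code paths.

## Latency, throughput and energy

Peripheral defaults follow published component figures: DSP 18.35 µW /
20 ns, ADC 41.3 µW / 20 ns, DAC 100 µW / 500 ns, with the DSP clock equal
to its 20 ns latency. One layer costs
$t_{DAC} + 48\, t_{ADC} + t_{DSP} = 1.48$ µs: DACs convert in parallel,
the two polarity ADCs each stream their 48 outputs, and the pipelined DSP
adds one tail stage. For the full inference the final 48-wide linear
combination occupies 10 DSP clocks, but since the DSP accumulates
products as ADC values stream in, only the last clock extends the
critical path; the default model therefore gives
$\tau_i = 1.48 + 1.48 + 0.02 = 2.98$ µs and a displayed throughput of
$\lfloor 1/\tau_i \rfloor = 335{,}570$ inferences/s. This pipelined
reading is the only way the per-layer figure, the total and the
throughput are mutually consistent; the fully serialized alternative
(3.16 µs) remains available via `pipelined = FALSE`.

Derived figures of merit: $Tr = 1/\tau_i$, $E_{inf} = P_{inf}\tau_i$,
$\gamma = Tr/P_{inf}$, with
$P_{inf} = P_{MVM} + 54 P_{DAC} + 4 P_{ADC} + 2 P_{DSP}$ (counts from the
four-crossbar floor plan, overridable since other accountings are
possible). GOP metrics offer two op-counting conventions — counting each
differential synapse once (5,280 ops/inference) or once per polarity
array (10,560) — because the convention behind published totals is
generally unstated; neither is asserted to match any printed GOP/s
figure. `amortization_breakeven()` converts ML-Hybrid's doubled L2–L5
programming energy and a per-inference saving into the number of
inferences after which the overhead is repaid.

## Numerical choices and degenerate inputs

* Quantization tie-breaks toward smaller absolute level; selection
  tie-breaks in storage order; pair-choice ties toward lower total
  conductance — all deterministic.
* The partial likelihood centers risks before exponentiation; losses and
  gradients are exact to round-off against enumeration oracles.
* Datasets require ≥ 2 records and ≥ 1 event; all-censored data raise
  typed errors (`memsurv_undefined_loss_error`,
  `memsurv_undefined_cindex_error`) rather than returning NaN.
* Conductance sampling truncates at 0 µS with a bounded resampling loop
  (50 attempts, then clamp) so extreme stress configurations cannot hang.
* Calibration failures (unreachable event fractions under administrative
  censoring, non-bracketing targets) raise `memsurv_calibration_error`
  with the achieved marginals in the message.

## Problem sizes used by the shipped tests

The test suite trains on cohorts of 120–2,000 subjects (300 for the
shared fixture), uses 300–500 training epochs, 40 epochs per INQ step,
2,000 Monte-Carlo draws per statistic-map cell, and 20–50 device
realizations per Monte-Carlo concordance study; the acceptance script
averages 20 replicates of the full 1,638-subject cohort. These sizes were
chosen so the whole suite exercises every stage at statistically
meaningful scale while remaining quick to run.

## Known limitations

* The device model is distributional, not physical: no pulse-level
  program-and-verify, endurance, read noise, or temperature dependence;
  its parameters are qualitative calibrations.
* The generator reproduces two marginal statistics, not the joint law of
  the real registry; concordance values on synthetic cohorts should not
  be read as predictions for the real data.
* Crossbar non-idealities beyond conductance variability (IR drop, sneak
  currents, finite converter resolution) are deliberately excluded.
* Mode powers in milliwatts depend on the trained weight histogram and
  the read voltage; only their ordering and ratios are meaningful here.
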