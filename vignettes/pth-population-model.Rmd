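---
title: "A multi-population model of acute PTH secretion dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-population model of acute PTH secretion dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(pthpop)
```

## The model

Acute serum parathyroid hormone (PTH) dynamics show two features that a
single steady-state dose–response curve cannot produce: hysteresis (the
PTH value at a given serum ionized calcium depends on the recent calcium
trajectory) and phase-dependent asymmetry between hypocalcemic and
hypercalcemic challenges. `pthpop` models both with two mechanistic
assumptions and nothing else:

1. **Secretion is a calcium-gated fraction of an intracellular store.**
   Each cell subpopulation $i$ holds a vesicular PTH pool $V_i$ fed at a
   constant synthesis rate $k_{v,i}$ and drained by first-order
   degradation ($k_{deg} = 0.02\,\mathrm{min}^{-1}$, i.e. ~70% of an
   isolated pool decays in 60 min) plus secretion. The per-minute
   secreted fraction is a decreasing sigmoid of ionized calcium $c$,

   $$f_i(c) = \gamma_{c,i} + \frac{\beta_i - \gamma_{c,i}}
     {1 + (c/k_{d,i})^{m_i}},$$

   with maximum $\beta_i$ (at low calcium), a never-zero floor
   $\gamma_{c,i}$ (secretion is never fully suppressed), half-inhibition
   at the set point $k_{d,i}$ (mmol/L) and steepness $m_i$. $m$ is an
   empirical "augmentation factor" summarizing the signalling cascade
   downstream of the calcium-sensing receptor — it is not a Hill
   coefficient, and calibrated values are in the hundreds. The store
   obeys $\dot V_i = k_{v,i} - (k_{deg} + f_i(c))\,V_i$.

2. **The gland is a population of heterogeneous subpopulations.** A
   virtual gland holds 20 *sensitive* populations (low set point,
   $k_{d1} \approx 1.13$ mmol/L: silenced at normocalcemia because even
   normal calcium exceeds their set point, hence holding large stores)
   and 20 *insensitive* populations ($k_{d2} \approx 1.27$: secreting at
   normocalcemia). Parameters are drawn independently per population from
   class-level distributions; the 50–50 split and the pair count are
   structural defaults the output is insensitive to (fewer pairs give a
   jagged response, more a smoother one).

Secreted hormone enters a serum compartment (3 L) that exchanges with an
interstitial compartment (11 L) at half the concentration difference per
minute (referenced to the serum volume; the output is insensitive to
this convention, which is exposed through
`physio_constants(exchange_fraction=)`). Clearance is renal plus hepatic
flow times extraction,
$k_{cl} = 0.625 \times 0.34 + 1.02 \times 0.44 = 0.6613$ L/min. Serum
calcium is an independent forcing input — there is no feedback from PTH
to calcium — supplied as a clamp profile.

Hysteresis falls out of the store dynamics: a silenced sensitive
population accumulates a store near $k_v/(k_{deg}+\gamma_c)$, roughly
forty times its active level. When calcium first drops below its set
point the population releases this surplus as a transient burst; the
subsequent plateau reflects the much smaller re-equilibrated store. No
rate-sensing by the receptor is needed.

```{r hysteresis, fig.alt = "Serum PTH transient under the training clamp"}
gland <- sample_gland(table1_spec(), seed = 1)
sim <- simulate_gland(gland, clamp_protocol("A"), dt = 0.5)
plot(sim)
```

## Units

Synthesis rates and stores are carried in an internal "amount unit"
because the published parameter units are not mutually consistent with
pmol/L concentrations; the model is scale-free in that unit. All
shape-based analyses (normalized slope, sigmoid sensitivity, hysteresis
geometry, z-scores against observations expressed in the same unit) are
unaffected. Absolute serum concentrations should be read as relative
values.

## Clamp protocols

Three idealized protocols are built in (`clamp_protocol()`), defined by
plateau offsets from a configurable baseline (default 1.25 mmol/L,
physiologic ionized calcium between the two class set points):

* **A** — hypocalcemia (−0.20 mmol/L) to 75 min, a brief hypercalcemic
  phase (+0.20) whose plateau spans 90–120 min, then re-induced
  hypocalcemia spanning 150–170 min. Used for calibration.
* **B** — hypocalcemia (−0.20) to 100 min, a brief normocalcemic return,
  hypocalcemia again.
* **C** — hypocalcemia (−0.20) to 60 min, then extreme hypocalcemia
  (−0.40).

Exact ramp shapes and brief-phase lengths are not constrained by the
published protocol descriptions; we use 10-min linear ramps positioned
so that every plateau exactly covers the standard sampling windows. All
plateau-window analyses are therefore insulated from the ramp choice.
Arbitrary profiles come from `profile_from_table()` (linear or
monotone-cubic interpolation — the monotone option avoids overshoot,
which matters because predictions are sensitive to the interpolation of
calcium).

## Numerical scheme

Integration is fixed-step classical Runge–Kutta (deSolve, `"rk4"`),
default `dt = 0.1` min; deterministic and refinement-testable (halving
`dt` moves outputs by well under 0.5%). The fastest rate in the system
is $k_{deg}+\beta \lesssim 1\,\mathrm{min}^{-1}$, far inside the RK4
stability region even at `dt = 1`, which the calibration loop uses for
its inner simulations. The sigmoid is evaluated on the log scale
(`exp(min(m·log(c/k_d), 700))`) so $c^m$ cannot overflow at $m \sim
400$, and in the $\gamma_c$-anchored form above, which keeps the value
exactly on its floor without catastrophic cancellation. Simulations
start at the closed-form steady state for the profile's initial calcium
unless an explicit state is given; the steady state itself is
$V_i^* = k_{v,i}/(k_{deg}+f_i)$, $\mathrm{serum}^* = \mathrm{isf}^* =
\sum_i f_i V_i^* / k_{cl}$.

## Parameter distributions and sampling

The calibrated population (`table1_spec()`) is represented by
positivity-truncated normal distributions with the published
post-calibration means and SDs. The calibration itself produced smoothed
kernel densities whose shapes were not published; the truncated-normal
stand-in matches the first two moments only, and downstream statistics
carry that approximation. Two published quirks are preserved
deliberately: the $\gamma_c$ posterior mean (0.0032) lies above its
initial search range ([0.00005, 0.0025]), so posteriors are *not*
clamped to the initial supports; and $\beta$ is additionally truncated
to (0, 1] so drawn fractions stay valid. Draws violating
$\gamma_c < \beta$ are rejected and redrawn jointly.

Sampling is by inverse-CDF transformation of uniform variates
throughout, so every pipeline is bit-reproducible under a seed. Kernel
re-estimation (`fit_kernel()`) uses a Gaussian kernel with Silverman's
rule-of-thumb bandwidth (the smoothing tool is prescribed by the
procedure, the bandwidth rule is ours), truncated and renormalized to
the support, with the CDF accumulated by trapezoid on the density grid
and inverted by monotone linear interpolation — exact round-trip on the
grid knots.

## Calibration

`calibrate()` implements iterative rejection sampling: draw `n_models`
candidate glands from the current distributions, simulate the training
protocol, z-score each candidate at the phase-labelled observation
points (1 baseline, 2 initial-peak, 5 hypocalcemic, 3 hypercalcemic for
protocol A), retain candidates with $\max_j |z_j| \le 1.5$ (inclusive;
outputs treated independently), pool the retained parameter draws and
re-fit kernels, and stop when the retained population's mean outputs
satisfy mean$(z^2) < 0.1$ and $\max|z| < 0.75$. "Mean z-score product"
is read as the mean square; the alternative pairwise-product reading is
available via `rule = "pairwise-product"`. The iteration cap defaults to
20 with a full per-iteration trace.

The procedural default of 2500 candidates per iteration is honoured by
the function default; the package's own test and analysis runs use
60–250 candidates with `dt = 1`, which keeps the recovery experiments
inside a few seconds to a minute while leaving tens of retained models
per iteration for the kernel re-fit.

A structural fact worth knowing: with 20 populations per class, a
gland's class-average parameters concentrate tightly around the
distribution means, so candidate *outputs* cluster. Calibration targets
must be *typical of that cluster* to be reachable at a 1.5 SD gate. In
particular a "mean-parameter" gland is not typical — its 20 sensitive
populations share one set point and burst simultaneously, shifting and
sharpening the hysteretic peak — and targets built from it starve the
gate at the peak phase. Recovery experiments therefore use a fixed truth
gland *sampled* from the priors.

## Synthetic observations

`synthetic_study()`/`generate_observations()` produce
pseudo-experimental observation sets: each of `n_subjects` (default 4)
simulated individuals gets a gland (fresh draw from a spec, or one
shared fixed gland), independent Gaussian noise is added at the sampled
time points, and per-point means/SDs are computed across subjects. The
default noise is 20% of the true value, matching the relative dispersion
of acute-clamp PTH measurements in small groups of healthy adults.
What the generator emulates: the phase layout, between-subject spread
and measurement noise of a small clamp study. What it does not emulate:
within-subject autocorrelated noise, subjects' individually deviating
calcium trajectories, and secondary secretagogues (phosphate,
calcitriol) — so green calibration tests demonstrate algorithmic
correctness and identifiability under the stated noise model, not
clinical fidelity. Degenerate replicate SDs (single subject or zero
noise) are floored at `max(noise_sd, 1)` model units to keep z-scores
defined.

## Steady-state analytics: two curves, two statistics

Two dose–response curves are deliberately distinguished:

* `steady_curve()` re-equilibrates the stores at every calcium level —
  the chronic relationship. Its normalized 10–90% slope
  (`slope_10_90()`) is the statistic compared against clinical
  slope estimates; on ensembles from the calibrated population it
  averages ≈ 340 %/(mmol/L). Normalization is min–max ("range") by
  default: the curve's floor sits near 14% of its maximum (secretion
  never stops), so a percent-of-maximum 10% level would never be
  crossed; the option is exposed as `normalize = "max"` for curves that
  do reach zero. The slope is the level difference (80 percentage
  points) over the calcium distance between the 90% and 10% crossings,
  and is invariant under rescaling of the PTH axis.
* `acute_response_curve()` freezes the stores at their
  baseline-calcium steady state and sweeps calcium — the acute
  dose–response measured on dispersed cells or in short clamp steps,
  where sampling is fast relative to store turnover. Because silenced
  sensitive populations hold large stores, this curve is much steeper.
  It is the appropriate object for fitting the classical four-parameter
  sigmoid $PTH(c) = D + (A-D)/(1+(c/C)^B)$ (`fit_four_param()`), whose
  sensitivity $B$ on the calibrated ensemble is ≈ 31; fitting the same
  sigmoid to the re-equilibrated curve instead yields $B \approx 20$
  (shallower, by a unimodal least-squares optimum), which is why the
  distinction matters when comparing against acute-experiment
  sensitivities.

The four-parameter fit initializes $A, D$ from the curve extremes, $C$
from the half-height crossing and $B$ from a coarse grid, refining each
start by Levenberg–Marquardt and keeping the best RSS; the default grid
covers $B \in [2, 64]$. Degenerate (flat) curves are rejected rather
than returning an indeterminate $B$.

Validation-style analytics mirror the published comparisons:
`ensemble_band()` (pointwise 95% band over 25 freshly sampled glands),
`coverage()` (percent of observed points inside the band),
`direction_score()` (sign agreement of consecutive changes with a
0.5-unit dead band), `brown_prediction()` (the memoryless four-parameter
comparator: exactly zero hysteresis-loop area by construction, checked
via `hysteresis_loop_area()`), and `squared_residuals()`. The
comparisons against the original clinical data points themselves are out
of scope — those values exist only as figure markers — so the package's
tests assert the *properties* (positive loop area for the population
model, zero for the memoryless comparator; presence of the
deep-hypocalcemia secondary peak only under population heterogeneity)
rather than the printed percentages.

## Chosen problem sizes

Defaults follow the study design (25-gland ensembles, 2500 calibration
candidates, `dt = 0.1`). The package's own test suite and the
reproduction script use: 10 × 25 glands for the slope statistic, a
25-gland ensemble for the sensitivity fit, 100 glands for the
steady-state/integration equivalence check (600 min at `dt = 1`, i.e.
>13 of the slowest store time constants), and 60–250 calibration
candidates for 1–2 iterations at `dt = 1`. These sizes were chosen to
keep each check in seconds while leaving the statistics' sampling error
well inside the tolerances asserted.

## Known limitations

* No calcium–PTH feedback loop (calcium is exogenous), hence no lag
  hysteresis from the loop itself.
* Smooth expected-value secretion; pulsatility and population switching
  are not modelled.
* Constant synthesis and degradation: no phosphate, calcitriol or FGF-23
  modulation, no transcriptional delays.
* The truncated-normal representation of the calibrated distributions is
  a two-moment stand-in for unpublished kernel densities; ensemble
  statistics inherit that approximation (the sensitivity fit is the most
  exposed, the normalized slope the least).
* Absolute output units are model units, not pmol/L.
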