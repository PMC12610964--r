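---
title: "Methods: Markov chain modelling of cattle activity budgets"
author: "cattlemc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Markov chain modelling of cattle activity budgets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cattlemc)
```

## The model

`cattlemc` treats a cow's monitored day as a discrete-time, discrete-state
Markov chain. The state space mixes six mutually exclusive behavioural
states — Feeding (F), Moving (M), Lying (L), Standing (S), Rumination
while standing (RS), Rumination while lying (RL) — with three
environmental variables — Temperature (T), Humidity (H) and the
Temperature–Humidity Index (THI) — in the fixed order T, H, THI, F, M, L,
S, RS, RL. Mixing environmental variables into the state space is
unconventional (a cow does not "occupy" the temperature), but it is how
the reference transition matrix bundled with the package is laid out, and
all analysis functions support it; the synthetic generator, by contrast,
draws behaviour from the 6×6 behavioural sub-chain and treats the
environment as parallel continuous series, because a simulated cow must
occupy exactly one behavioural state per step.

The chain is fully described by a row-stochastic transition matrix $P$,
whose entry $(i, j)$ is the probability of moving from state $i$ to state
$j$ in one sampling step. Under irreducibility the chain has a unique
stationary distribution $\pi$ with $\pi P = \pi$: the long-run fraction of
time in each state, i.e. the animal's activity budget. Cumulative sums
$C_1 \le \dots \le C_9 = 1$ of $\pi$ (and of each row of $P$) support
inverse-CDF sampling.

Assumptions worth stating plainly: first-order dependence (the next state
depends only on the current one — duration-in-state and time-of-day
effects are *not* modelled), time homogeneity (one $P$ for the whole
observation window), and a common sampling step within a sequence.

## Reading and validating sensor exports

Activity tables follow the standard aggregated layout (`No, T, H, THI, F,
M, L, S, RS, RL, TOTAL_MIN`; durations in minutes). The validator checks
each row against its *own* `TOTAL_MIN` rather than a fixed 1440: real
exports contain occasional short days (the bundled 30-day table has one
1430-minute day), and these are internally consistent, not errors.
Unrecorded environmental cells (`NA`) pass validation; recorded values
must be finite with humidity in $[0, 100]$. Validation is pure — it
reports, never mutates.

Printed transition matrices rounded to three decimals have row sums around
0.994–0.997, so `load_transition_matrix()` renormalises every row to sum
exactly to 1 and keeps the original sums as a diagnostic attribute.
Renormalisation before analysis is mandatory; all downstream tolerances
assume exactly stochastic rows.

## Time-series features

`compute_features()` summarises one series with eight statistics. The
field uses several inequivalent definitions for half of them, so the
package fixes conventions explicitly (each is configurable where a
parameter exists):

- **sd** is the sample standard deviation ($n-1$); **skewness** and
  **kurtosis** are the bias-corrected sample moments, kurtosis in the
  *excess* convention (a uniform sample sits near $-1.2$, a normal one
  near 0).
- **Shannon entropy** is histogram entropy over `n_bins = 10` equal-width
  bins spanning the observed range, in nats, with $0 \log 0 := 0$. It is
  bounded by $\ln 10 \approx 2.303$ and invariant under positive affine
  maps of the data, since the bins follow the range.
- **trend** is the strength-of-trend statistic
  $\max(0, 1 - \mathrm{Var}(R)/\mathrm{Var}(X))$ from a centred
  moving-average decomposition $X = T + R$ restricted to the interior
  where the full window fits. The default window is
  $\min(7, 2\lfloor n/3 \rfloor + 1)$, forced odd — wide enough to smooth
  daily noise in month-long series, small enough to exist for short ones.
  A noiseless ramp scores 1; added white noise strictly lowers the score.
- **linearity** and **curvature** are the degree-1 and degree-2
  coefficients of an orthogonal-polynomial regression of the trend
  component on time. They are unbounded and signed, which matches how the
  field reports them.

A constant series takes the documented degenerate conventions (sd,
entropy, skewness, kurtosis, trend, linearity, curvature all 0).

## PCA variable selection

`fit_pca()` standardises every column to mean 0, sd 1, then
eigendecomposes the covariance of the standardised data — equivalent to
correlation PCA; the equivalence is stated to fix the convention. The sum
of eigenvalues therefore equals the number of variables. The smallest $k$
with cumulative explained variance $\ge$ `threshold` is selected; the
default threshold is 0.95, with 0.90 a documented alternative for more
aggressive reduction. Eigenvector signs are arbitrary, so each component
is flipped to make its largest-magnitude loading positive. The
per-variable contribution score is the explained-ratio-weighted sum of
absolute loadings over the selected components — a package decision, since
no single formula is standard; ties rank in input order. The matrix
orientation (variables over time, or features over variables) is the
caller's choice; both are meaningful analyses.

Note a consequence of standardisation: a pure-noise variable carries the
same unit variance as any other, so nine standardised variables can
concentrate 95% of variance in three components only when *all nine* load
on the three underlying factors. The test suite constructs its factor
fixtures accordingly.

## Estimating the chain

From a state sequence, `estimate_from_sequence()` is the transition-count
MLE with optional additive smoothing $a$:
$\hat P_{ij} = (n_{ij} + a)/(n_{i\cdot} + k a)$. Smoothing defaults to 0
so the estimator is exact on clean data; a visited state with no outgoing
transition is then an error (the suggestion is to smooth), and a state
never visited at all gets a uniform row so the result is always a valid
stochastic matrix.

From aggregated compositions (no step-level sequence available),
`estimate_from_compositions()` normalises each interval's nine values to
proportions $q(d)$ and row-normalises either $\sum_d q(d) q(d+1)^\top$
(lagged) or $\sum_d q(d) q(d)^\top$ (co-occurrence). Both yield valid
stochastic matrices; neither is a maximum-likelihood chain estimate, and
the package makes no claim that either reproduces a matrix estimated at
step level — the bundled printed matrix is the authoritative input for
budget analysis.

## Stationary distribution: numerical choices

The default solver takes the left eigenvector of eigenvalue 1 (via
`eigen()` on $P^\top$), which handles periodic chains directly. The
alternative power method iterates the damped map
$\pi \leftarrow \pi (P + I)/2$: the damped chain has the same stationary
vector and is aperiodic by construction, so the iteration converges even
on two-cycles where raw power iteration oscillates. (Damping was chosen
over Cesàro averaging of raw iterates for its simpler convergence test;
the two agree at the fixed point.) Both routes must satisfy
$\max_i |(\pi P - \pi)_i| \le 10^{-10}$ or the solve errors out, and they
agree within $10^{-9}$ on random irreducible chains in the test battery.
Irreducibility is checked by boolean reachability (strong connectivity of
the positive-entry digraph); reducible input — e.g. the identity matrix —
is rejected because its stationary distribution is not unique. The
cumulative vector is the running sum of $\pi$ with the last element forced
to exactly 1, so inverse-CDF draws can never fall off the end.

## Simulation

Two samplers are provided because both views of "simulating the chain"
are useful, and they cross-check each other:

- `simulate_direct()` walks the chain: the next state is drawn by
  inverting the current row's cumulative probabilities at a uniform
  variate.
- `simulate_metropolis_hastings()` samples a stationary target directly:
  a uniform proposal over all states (including the current one — a lazy
  but still symmetric proposal), acceptance probability
  $\min(1, \pi_j/\pi_i)$, rejection repeating the current state. All
  target masses must be strictly positive. The realised acceptance rate
  is reported (about 0.84 for the bundled nine-state budget).

Both take a `sim_config`: `n_iterations` retained samples (3000–5000 are
the standard run lengths), `burn_in = 1000` initial discarded steps
(burn-in counts steps, not acceptances), a seed that makes runs
bit-for-bit reproducible, and an initial state (default: the first state
in the space, for reproducibility; `"stationary-draw"` draws it from
$\pi$). For the bundled budget, 5000 retained MH samples land within
about 0.005 AAE of the target, and the two samplers' empirical
distributions agree within 0.01 AAE at $10^5$ samples.

## Evaluation

`error_metrics()` computes AAE ($\frac1N\sum|X_i-\hat X_i|$), AES
($\frac1N\sum(X_i-\hat X_i)^2$) and RMSE ($\sqrt{\mathrm{AES}}$) over
vectors of length $N$ — here usually the 9 states of two activity
budgets. RMSE carries the square root by definition, and the bundled
error table confirms it: $\sqrt{\mathrm{AES}}$ reproduces every printed
RMSE cell to four decimals. `cohort_table()` pools all per-cow error
values in a column into an arithmetic mean and reports
`accuracy = 1 − pooled mean`, rounded *half-up* to two decimals (base R's
banker's rounding would disagree on exact ties). Half-up reproduces the
reference accuracies at 4000 and 5000 iterations; the reference's
3000-iteration cell appears to follow a different (unstated) convention
and is not used as an anchor.

## The synthetic herd generator

`herd_spec()` fixes the study conditions: 5 cows, 30 days, 1-minute
steps, ground truth the bundled nine-state matrix, and a hot-humid-month
climate (T ≈ 31.5 ± 0.95 °C, H ≈ 77.7 ± 4.1 %, day-to-day AR(1)
correlation 0.5) chosen once from the empirical moments of the bundled
30-day table. THI is derived with the standard livestock index
$0.8\,T + (H/100)(T - 14.4) + 46.4$; published tables sometimes use
sensor-specific variants that differ by a few tenths, so generated THI is
never asserted against printed THI columns. The AR(1) structure exists to
exercise the trend/linearity features with minimal machinery.

What the generator emulates: per-interval behavioural durations that sum
to the interval length, seeded per cow, at 1-minute/15-minute/daily
aggregation; correlated environmental series with derived THI. What it
does not emulate: duration-dependent state dwell times, circadian
structure, inter-cow correlation, sensor misclassification noise, or the
proprietary classification firmware itself. Passing the round-trip tests
therefore shows the *pipeline* is self-consistent (generate → aggregate →
estimate → stationary recovers the generating budget within AAE 0.02 over
a 30-day, 1-minute sequence), not that real herds satisfy the first-order
Markov assumption.

## Problem sizes and tolerances in the test battery

The suite runs sequences of $10^3$–$10^5$ steps for estimator-consistency
checks (max-entry recovery error ≤ 0.01 at $10^5$), 20-seed batteries at
3000/4000/5000 iterations for the monotone-accuracy property, $10^6$-step
MH runs against 3-state targets as a sampler-correctness oracle (within
0.005 per state), and 100 random irreducible chains for solver agreement
(within $10^{-9}$) — sizes at which Monte Carlo error sits well below each
asserted tolerance while the whole suite stays fast. Stochastic
assertions use a fixed seed (1, the package default) and tolerances of
roughly two standard errors of the statistic under test, so they are
reproducible rather than flaky.

## Known limitations

- First-order, time-homogeneous chains only; no duration or time-of-day
  covariates, no continuous-time model.
- The composition-based estimator is a heuristic embedding of
  aggregate-only data, not an MLE.
- MH with a uniform independence proposal mixes slowly for very skewed
  targets (acceptance falls with $\max_i \pi_i / \min_i \pi_i$); for the
  nine-state budgets here it is entirely adequate.
- Environmental "states" in the nine-state chain are analysed as given;
  the package takes no position on their causal meaning.
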