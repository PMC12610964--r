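# cattlemc

Markov chain modelling and MCMC simulation of multi-sensor cattle activity
data.

## The problem

Precision livestock farming systems equip dairy cows with neck-mounted
multi-sensor collars (3D accelerometer, pneumatic rumination sensor,
proximity sensor, plus temperature/humidity loggers) and export aggregated
activity tables: minutes per interval spent Feeding (F), Moving (M), Lying
(L), Standing (S), Ruminating while standing (RS) and Ruminating while
lying (RL), alongside ambient Temperature (T), Humidity (H) and the
Temperature–Humidity Index (THI). Farmers and veterinarians care about an
animal's *long-run activity budget* — the typical fraction of time spent in
each state — because deviations from it (less rumination, more lying) are
early signals of lameness, disease or heat stress.

`cattlemc` models these records as a discrete-state Markov chain over the
nine variables and provides the full workflow:

- **I/O and validation** of the aggregated activity tables, labelled
  transition matrices and plain-text state sequences;
- **time-series features** per variable (mean, sd, skewness, excess
  kurtosis, histogram Shannon entropy, strength of trend, linearity,
  curvature) and **PCA variable selection** by explained-variance
  threshold;
- **chain analysis**: transition-matrix estimation from sequences or from
  interval compositions, row renormalisation, stationary distribution
  `πP = π` (eigen or damped power iteration), cumulative probabilities
  `C1..C9` and n-step powers `P^n`;
- **simulation**: direct inverse-CDF chain simulation, and
  Metropolis–Hastings sampling of a stationary target with a uniform
  symmetric proposal, acceptance probability `min(1, π_j / π_i)`, with a
  configurable burn-in (default 1000 discarded steps);
- **evaluation** with the average absolute error, average squared error and
  root mean squared error between observed and predicted probability
  vectors,

  AAE = (1/N) Σ |X_i − X̂_i|, AES = (1/N) Σ (X_i − X̂_i)², RMSE = √AES,

  pooled into a cohort accuracy table (`accuracy = 1 − pooled mean`);
- a **synthetic herd generator** (behavioural sequences from the 6×6
  behavioural sub-chain, AR(1) environmental series with derived THI,
  interval aggregation) so every stage is testable end to end without
  proprietary sensor exports.

Small reference datasets from a monitored Holstein herd (a 30-day daily
activity table, the nine-state transition matrix derived from it, its
stationary distribution and a 5-cow simulation error table) ship in
`inst/extdata/` and are reachable via `cattlemc_example()`.

## Worked example

```r
library(cattlemc)

P  <- load_transition_matrix(cattlemc_example("matrix"))
pi <- stationary_distribution(P)
pi
#> Stationary distribution
#>      T      H    THI      F      M      L      S     RS     RL
#> 0.1085 0.0855 0.0834 0.0881 0.1478 0.2099 0.0849 0.0859 0.1060
#> cumulative:
#>      T      H    THI      F      M      L      S     RS     RL
#> 0.1085 0.1940 0.2774 0.3655 0.5133 0.7232 0.8081 0.8940 1.0000
```

The cow spends about 21% of its time lying — the largest share of the
budget. Sampling that budget with Metropolis–Hastings and scoring the match:

```r
r <- simulate_metropolis_hastings(pi, sim_config(5000, burn_in = 1000, seed = 1))
stationary_similarity(as.numeric(pi), r$empirical)
#> Error report (N = 9 )
#>   AAE  = 0.004925
#>   AES  = 0.000041
#>   RMSE = 0.006396
```

After 5000 retained samples the simulated budget is within half a
percentage point per state of the target. Pooling the bundled per-cow error
table gives the cohort view:

```r
cohort_table(read.csv(cattlemc_example("errors")))
#> Cohort accuracy report
#>   n_iterations pooled_mean accuracy
#> 1         3000    0.034821     0.97
#> 2         4000    0.028423     0.97
#> 3         5000    0.022171     0.98
```

Accuracy improves from ~97% to 98% as the simulation length grows from
3000 to 5000 iterations.

A shell entry point wrapping the same functions (subcommands `fit`,
`simulate`, `evaluate`, `features`, `pca`, `synth`) is installed at
`system.file("cli", "cattlemc.R", package = "cattlemc")`.

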