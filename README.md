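# reverbkit

Tools for simulating and quantifying *reverberating* cortical network
dynamics — population activity poised between the asynchronous-irregular
state and criticality — and for reasoning about how a network tunes its
operating point to task demands.

## The problem

Cortical circuits must sometimes quench their input within milliseconds
and sometimes integrate it over hundreds of milliseconds. Both behaviors
are controlled by a single effective parameter, the **neural efficacy**
`m`: the average number of additional spikes one extra spike triggers in
its postsynaptic targets. Population activity is modeled as a driven
branching process,

    a[t+1] | a[t]  ~  Poisson(m * a[t] + h),

with external drive `h` per bin of width `Δt`. For `m < 1` the process
is stationary with rate `r = h/(1−m)`, lag-`k` autocorrelation `m^k`,
sensitivity `∂r/∂h = (1−m)^−1`, and intrinsic timescale
`τ = −Δt/log(m) ≈ Δt/(1−m)`. All of these diverge at the critical point
`m = 1`, which is what makes the nearby *reverberating regime*
(`0.9 ≤ m < 0.995`, median `m ≈ 0.98` in vivo) such a favorable
operating point: small changes in `m` retune sensitivity, amplification
and integration time over a wide range.

Estimating `m` from recordings is hard because only a tiny fraction of
neurons is observed, which biases the conventional lag-1 regression
slope far downward. The package's core statistic is the
**multistep-regression estimator**: the lag-`k` slopes of a subsampled
trace satisfy `r_k = b · m^k` with a single attenuation factor `b`, so
fitting the geometric decay across lags recovers `m` invariantly under
subsampling — from a few percent of the spikes.

On top of the estimator, the package implements the stability and
adaptation arithmetic for networks near criticality: the
synaptic-fluctuation safety margin `n_σ · c_w · m / √k` (1.5% for
`c_w = 0.5`, `k = 10,000`, `n_σ = 3`, i.e. stable 99.9% of the time)
and the task-optimal efficacy `m* = 1 − (α′β₋/β₊)^(−1/(β₊−β₋))`
maximizing the goal function
`Φ_α(m) = (1−m)^(−β₊) − α′(1−m)^(−β₋)`.

It is written for computational neuroscientists who want a tested
reference implementation of these quantities, a simulator for method
validation, and a subsampling-robust `m̂`/`τ̂` pipeline for binned
population counts.

## Worked example

Simulate a reverberating network, observe only 5% of its spikes, and
compare the naive and multistep estimators:

```r
library(reverbkit)

tr <- simulate_branching(m = 0.98, h = 2, n_bins = 1e5, seed = 1)
tr
#> <activity_trace> 100000 bins, dt = 4 ms, mean count = 99.407

th <- subsample(tr, 0.05, seed = 2)     # binomial thinning to 5%

estimate_m_naive(th)                    # conventional lag-1 slope
#> [1] 0.5543196

estimate_m(th, k_max = 40, n_boot = 200, seed = 3)
#> <mr_fit> multistep-regression estimate
#>   m_hat = 0.9800 [0.9778, 0.9818]   b_hat = 0.5655   tau_hat = 198.3 ms
#>   lags 1..40, dt = 4 ms, converged = TRUE
```

The full trace runs at its theoretical rate `h/(1−m) = 100` spikes/bin.
After thinning, the naive estimator collapses to 0.55 — the subsampling
bias — while the multistep fit recovers `m̂ = 0.980` (bootstrap 95% CI
in brackets) and the intrinsic timescale `τ̂ ≈ 198 ms`; the attenuation
shows up only in `b̂ = 0.57`. Fits are tidyverse-friendly
(`tidy()`, `glance()`, `autoplot()`).

The analytic layer is one call each:

```r
safety_margin(k_synapses = 10000)
#>   sd_mi = 0.005, margin = 0.015 (1.5%), m_safe = 0.985,
#>   stability_prob = 0.9986501, regime = reverberating

optimal_m(alpha_prime = 0.05, beta_plus = 1, beta_minus = 2)
#>   m_star = 0.9, valid = TRUE, is_max = TRUE
```

A command-line front end with `simulate`, `estimate`, `estimate-trials`,
`properties`, `classify`, `margin`, `optimize` and `fixtures`
subcommands ships at `inst/cli/reverbkit.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/reverbkit.R", package="reverbkit"))')" \
  properties --m 0.98 --h 0.2
```

See `vignettes/reverberating-dynamics.Rmd` for the model assumptions,
estimator internals and design choices.

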