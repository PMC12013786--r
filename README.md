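# muflex

Analysis of motor-unit populations decomposed from high-density surface
EMG: latent-manifold dimensionality of smoothed firing rates, recruitment
flexibility statistics, motor-unit action-potential geometry, and a spiking
motor-neuron-pool simulator for testing how the distribution of synaptic
inputs shapes the manifold.

## Who this is for

Researchers working with concurrently recorded motor-unit spike trains
(typically 10-60 units per muscle, 2048 Hz EMG systems) who want to

* estimate how many latent factors underlie a population's smoothed firing
  rates, with a principled stopping rule;
* quantify whether pairs of units ever move *against* each other (flexible
  recruitment) rather than along a single common drive;
* locate units on electrode grids from their action-potential signatures;
* test mechanistic hypotheses in silico with a conductance-based
  leaky-integrate-and-fire (LIF) pool, including Renshaw-cell recurrent
  inhibition.

## The core methods

**Dimensionality.** Binary spike trains are convolved with a 400 ms Hanning
window (unit time-integral, zero phase - a 2.5 Hz low-pass retaining the
force-relevant band), continuity-filtered (no pause > 400 ms), detrended and
concatenated across force plateaus. Maximum-likelihood factor analysis with
promax rotation is fitted for k = 1..kmax; reconstruction accuracy is
R² = 1 − SSE/SST between standardized and reconstructed rates. The selected
dimensionality `k_slope` is where the forward difference of the data R²
curve drops below the fitted straight-line slope of the R² curve of a
*surrogate population* (per-unit inter-spike intervals randomly permuted:
same spike counts, same mean rates, no common slow modulation). Two
alternative criteria (increase < 5%; linear-fit MSE < 1e-3) are reported
alongside.

**Flexibility.** For a unit pair with rates r₁, r₂, displacement is
`max over (t,t') of min(Δr(t,t'), Δr(t',t))` with
`Δr(t,t') = max_i(r_i(t) − r_i(t'))` - the largest opposite-direction
excursion, zero under any shared monotone drive. Dispersion bins timestamps
by the population L1 norm ‖r(t)‖₁ and reports the largest ‖r(t₁) − r(t₂)‖₁
within a bin - zero when the summed rate indexes a unique population state.
Both are minimized over per-unit conduction lags (≤ 25 ms) and normalized by
the summed per-unit maximum rates.

**Simulation.** Pools of 300 conductance-based LIF motor neurons (soma
diameters 50-100 µm, quadratic distribution; rest/reset 0 mV, threshold
10 mV, E_excit +25 mV, E_inhib −15 mV) receive a baseline drive plus 25:75
common:independent conductance fluctuations (0-2.5 Hz common sources, 0-50 Hz
noise, SD 0.03 mS at source level). Seven scenarios vary the number,
polarity, and mixing (homogeneous vs softmax-heterogeneous) of common
sources and add Renshaw-cell recurrent inhibition (homonymous, or
homonymous + heteronymous across three pools with ~0.7-correlated inputs).
The headline result: scenarios with homogeneous distributions or purely
homonymous inhibition yield **one** latent factor; heterogeneous
distributions or heteronymous recurrent inhibition yield **three** - input
*distribution*, not input count, sets the manifold dimensionality.

## Worked example

```r
library(muflex)

# a synthetic 30-unit population driven by 3 heterogeneously mixed latents
lp <- latent_population(n_units = 30, duration = 80, k_true = 3,
                        mixing = "heterogeneous", seed = 103)
rep <- select_dimensionality(lp$pop, kmax = 10, fs_out = 64, seed = 1)
print(rep)
#> <dimensionality_report> 30 units | k_slope = 3, k_5pct = 3, k_mse = 2
#>   R2(data) at k_slope: 0.559 | surrogate line slope: 0.0303

glance(rep)
#>   k_slope k_5pct k_mse r2_at_k_slope surrogate_slope n_units kmax
#> 1       3      3     2     0.5585419      0.03025316      30   10
```

`k_slope = 3` recovers the planted dimensionality: the three heterogeneously
mixed latent signals capture 56% of the smoothed-rate variance (the rest is
the spiking-noise floor of ~1000 spikes per unit), and a fourth factor adds
less than ISI-shuffled noise would. The same call on a homogeneous
single-latent population returns `k_slope = 1`.

Simulating the mechanistic scenarios:

```r
run <- run_scenario("i", seed = 1, duration = 60, dt = 1e-4)
print(run)
#> <scenario_run i> seed 1 | 140 active MNs at 9.63 pps | baseline 0.472 mS
#>   k_slope = 1 (R2 0.800)
```

140 of 300 neurons fire continuously at a physiological 9.6 pps under the
auto-tuned 0.47 mS baseline, and a single common input yields a
one-dimensional manifold capturing 80% of the variance.

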