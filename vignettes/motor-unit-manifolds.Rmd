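---
title: "Motor-unit manifolds, recruitment flexibility and the spiking pool model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor-unit manifolds, recruitment flexibility and the spiking pool model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(muflex)
```

## The scientific problem

When many motor units of one muscle are recorded simultaneously (today
routinely 20-60 units, decomposed from high-density surface EMG), their
smoothed firing rates co-fluctuate: motor neurons of a pool share a large
part of their synaptic input. Linear dimensionality reduction applied to
these rates yields a small number of latent factors spanning a manifold. A
central interpretive question is what the dimensionality of that manifold
means: does a three-dimensional manifold imply three descending commands the
nervous system could exploit for flexible, selective recruitment? `muflex`
implements the computational chain needed to study this question end to end:

1. spike-train preprocessing exactly as used for factor analysis of motor
   units (binarization, 400 ms Hanning smoothing, continuity filtering,
   detrending, concatenation of force plateaus);
2. maximum-likelihood factor analysis with promax rotation and a
   surrogate-based criterion for the number of latent factors;
3. the *displacement* and *dispersion* statistics, which quantify how far a
   pair of units departs from the one-dimensional monotonic behaviour that a
   single common drive imposes;
4. spike-triggered MUAP geometry for locating units on electrode grids;
5. a conductance-based leaky integrate-and-fire (LIF) motor-pool simulator
   with optional Renshaw-cell recurrent inhibition, implementing seven input
   scenarios whose factor structure can be compared with experiments;
6. seeded synthetic generators providing ground truth for every stage.

The simulation scenarios embody the package's headline scientific point:
*how inputs are distributed across a pool - not how many inputs there are -
sets the manifold dimensionality*. Three orthogonal sources delivered
uniformly are indistinguishable from one (weaker) common input; the same
three sources delivered heterogeneously produce a three-dimensional
manifold. Recurrent inhibition behaves the same way: homonymous Renshaw
feedback leaves a one-dimensional manifold (with less variance explained),
whereas topographically organized heteronymous feedback from synergist pools
adds dimensions even under a single descending command.

## Preprocessing

Spike trains are binarized at the acquisition rate (round-half-even sample
assignment) and convolved with a 400 ms Hanning window scaled to unit time
integral, so smoothed values are in pulses per second (pps) and the
time-integral of a row equals the spike count. The 400 ms window acts as a
2.5 Hz low-pass filter: it retains the band relevant to force production and
discards synchronization structure at higher frequencies. The convolution is
zero-phase (kernel centred on the spike sample) with zero padding at the
edges; analyses that need exactness stay a kernel-width inside segment
boundaries.

Only units firing continuously enter the factor analysis: no inter-spike
interval inside the analysis window may exceed 400 ms. The rule is applied
*including* the gaps between the window edges and the first/last spike - a
unit silent for the first second of a plateau is not continuously firing.
Whether the boundary gaps should count is genuinely open; the package makes
the stricter choice and exposes `max_pause` and `window` so the sensitivity
is a one-liner to test.

Smoothed rates may be decimated after convolution (`fs_out`): the signal is
band-limited at 2.5 Hz, so any output rate above ~10 Hz is lossless for the
downstream statistics while cutting factor-analysis cost by an order of
magnitude. The analyses in the test-suite use 64 Hz.

Duplicate units (the same physical unit decomposed from two grids) are
detected by aligning each pair at the best integer-sample lag (conduction
delay) and counting firings shared within 0.5 ms; pairs sharing more than
30% form duplicate groups (transitive closure), and the member with the
lowest inter-spike-interval coefficient of variation is retained. Ties go to
the unit with more spikes, then the lexicographically smallest id, so the
result is deterministic.

## Latent dimensionality

Factor analysis runs on the unit-by-unit *correlation* matrix of the
detrended rates: detrending and the common pps scale make units
exchangeable, and the correlation convention keeps the R-squared curve
invariant to rate rescaling. The maximum-likelihood fit is delegated to
`stats::factanal` (no rotation); the oblique promax rotation (power 4, the
standard default) is applied to the varimax solution afterwards, with the
factor correlation recovered from the rotation matrix, because the rotated
loadings and the rotation matrix must stay mutually consistent for score
computation. Factor scores use the regression (Thomson) estimator. Heywood
cases are handled by the uniqueness floor (0.005) with a warning. When the
likelihood machinery is undefined because there are too few units (the
Ledermann bound falls below one), the package floors the admissible factor
count at one - a single-factor model is the baseline of the whole method -
and falls back to iterated principal-axis factoring for the fit.

Reconstruction accuracy is `R^2 = 1 - SSE/SST` between the standardized
rates and `scores x loadings'`, pooled over units and samples; it is
non-decreasing in the factor count (up to numerical tolerance).

The number of factors is selected by comparing the data R-squared curve with
that of a **surrogate population**: each unit's inter-spike intervals are
randomly permuted and re-accumulated from its first firing time, preserving
spike count, mean rate and ISI distribution exactly while destroying the
common slow modulation. The surrogate curve is summarized by the slope of a
least-squares line (it is near-linear); the data curve, which is strongly
concave, is compared pointwise by its forward difference. Factors keep being
accepted while the forward difference exceeds the surrogate slope; the
selected count is the first k whose difference falls below it (floor one,
cap `kmax - 1`). Reading the data slope as a forward difference rather than
a fitted line is the package's resolution of a genuine ambiguity; the fitted
line variant is available via `slope_method = "linefit"`. One surrogate
realization is used per selection, with its seed recorded in the report.

Two alternative criteria are reported alongside: the smallest k beyond which
the R-squared increase falls below 0.05, and the smallest k at which the
remaining curve is flat (mean squared error of a straight-line fit through
points `k..kmax` below 1e-3).

## Displacement and dispersion

Both statistics operate on smoothed, *non-detrended* rates - their
normalization divides by the summed per-unit maximum rates, which detrending
would distort. For a pair of units, the maximum non-negative rate change
between two timestamps is `dr(t,t') = max_i(r_i(t) - r_i(t'))`; if both
units move together, one direction of every comparison is zero.
*Displacement* is the maximum over timestamp pairs of
`min(dr(t,t'), dr(t',t))` - the largest opposite-direction excursion.
*Dispersion* asks whether the summed rate (L1 norm) indexes a unique
population state: timestamps are binned by norm (bin width 0.5% of the norm
range by default; exact matching is available for analytic cases) and the
statistic is the largest L1 distance between two states sharing a bin.

Conduction-velocity differences shift one unit's surface signature relative
to another's, so both metrics are minimized over per-unit constant integer
lags up to 25 ms. A per-unit *constant* lag is the package's reading of the
lag search - conduction velocity is a fixed property of a neuron - with the
per-timestamp-pair alternative behind `lag_mode = "per_pair"`. The L1 norm
is used for the dispersion difference as well, matching the population-norm
choice; the defining formula leaves the norm unnamed.

The implementation is exact (all timestamp pairs); its cost is quadratic in
series length, so long recordings can be decimated explicitly (`decimate`,
reported via a message). The test-suite verifies exact equality against a
triple-loop brute-force oracle on random ensembles.

## The spiking pool model

Each pool holds 300 conductance-based LIF motor neurons with resting/reset
potential 0 mV, threshold 10 mV, excitatory equilibrium +25 mV and
inhibitory equilibrium -15 mV (equal-magnitude excitatory and inhibitory
effects at the halfway potential). Soma diameters follow
`D = 50 + (i/N)^2 * 50` micrometres, over-representing small neurons. The
membrane equation integrates by forward Euler (default `dt` = 0.05 ms, and
never above 0.1 ms; halving `dt` moves rates by under 2%):

```
C dv/dt = -v/R + max(ge * S * (25 - v) - I_rheo, 0) + gi * S * (-15 - v)
```

with `S = R/R_1` the size-dependent responsiveness (exactly the smallest
neuron has `S = 1`) and a rheobase offset gating the excitatory current.
Printed sign conventions for such equations are easy to garble, so the
implementation fixes them by physical contract - excitation depolarizes
toward +25 mV, inhibition toward -15 mV, leak decays to rest - and the test
suite pins the closed-form constant-input period.

### Size relations and calibration

The mapping from soma diameter to `R`, `C`, `I_rheo` and the refractory
period is not uniquely determined by published constants; the package treats
it as a calibrated construction with the *emergent behaviour* as the
specification: under the default drive, roughly 120-150 of 300 neurons are
continuously active (400 ms pause rule over 60 s) at 8-10.5 pps, and
recruitment order follows soma size (Spearman rho >= 0.95 under a slow
ramp). Concretely: `R` falls as `d^-2.4` of normalized diameter; the
recruitment-threshold conductance over normalized rank `u` rises gently
(`0.40 * exp(0.12 u)` mS) up to a knee at 45% of the pool and then steeply
(wall slope 3), and the rheobase offset is constructed so a steady
conductance at that curve exactly reaches threshold (recruitment order is
then orderly *by construction*); capacitance sets a ~40 ms effective time
constant at the reference drive; the refractory period shrinks as `d^-0.5`
from 25 ms. The knee shape is what makes the continuously active fraction
robust: the sub-knee units hold similar, comfortable voltage margins (few
pauses, little gain diversity - a single exponential instead either starves
the inhibitory-load scenarios of active units or overflows the weakly
fluctuating ones, and the margin diversity it creates can masquerade as a
spurious second factor), while wall units recruit only under much stronger
drive, as high-threshold motor units do. These constants were fixed once
against 60 s calibration runs and are not adjusted per scenario;
per-scenario adaptation happens only through the baseline drive (below).

### Inputs

Per-neuron drive is a baseline plus zero-mean fluctuations: common sources
(Gaussian noise low-pass filtered at 2.5 Hz, standardized, mutually
orthogonalized - or pairwise correlated at ~0.7 across pools in the
three-pool scenario, via a shared component) and independent noise (low-pass
50 Hz). At the source level the common:independent variance split is 25:75
with total SD 0.03 mS. Heterogeneous mixing draws uniform(0,1) weights per
neuron and passes them through a softmax with temperature 0.1 (rows sum to
one, each neuron dominated by one source); homogeneous mixing weights every
source equally, and the averaging of orthogonal sources then attenuates the
*delivered* common variance by `1/k`. That attenuation is deliberately not
re-standardized away: it is the mechanism by which homogeneously distributed
multi-source inputs behave like a single weaker common input (lower variance
explained at one factor), which is the phenomenon the scenarios exist to
show. In the inhibitory scenarios the three common sources ride on a 0.12 mS
inhibitory baseline while the excitatory channel keeps one uniform common
source plus the independent noise.

The baseline excitatory drive is auto-tuned per scenario by bisection on the
mean firing rate, evaluated on short calibration runs that reuse the
scenario's own input realization. The tuning statistic averages over units
above a modest rate floor (4 pps) rather than over pause-rule survivors:
under strong recurrent inhibition the pause rule drops exactly the
inhibited units, and conditioning on the survivors would push the baseline
the wrong way. Targets sit at the centre of the physiological band
(9.25 pps), or its upper half (9.9 pps) for the common-inhibition
scenarios, whose tonic conductance load shrinks voltage margins at any
given rate. Tuned baselines land near 0.47 mS for the purely excitatory scenarios
and higher where inhibition must be compensated; they are reported in every
`scenario_run`.

### Renshaw cells

Renshaw cells are simple integrate-and-fire units (`dv/dt = (I - v)/tau`,
tau = 8 ms, threshold 10 mV, refractory 10 ms) driven by 50 Hz low-pass
noise (SD 3 mV) and by EPSP jumps from delayed motor-neuron spikes; their
spikes deliver a delayed inhibitory conductance increment of 0.002 mS to
target motor neurons; both directions use a 5 ms delay. Two aspects are
calibrations rather than published constants. First, the EPSP amplitude is
per-scenario (3.4 mV homonymous; 1.3 mV in the three-pool circuit), chosen
so Renshaw rates land in the physiological 20-25 pps band given how many
*active* motor neurons actually converge on a cell in each circuit. Second,
the *decay* of the recurrent inhibitory conductance is exponential with
`tau_syn` = 60 ms (20 ms in the three-pool circuit, compensating its larger
EPSP so the loop gain - Renshaw rate x IPSP x decay - stays comparable):
the per-spike amplitude is fixed, so this constant sets the integrated
strength of recurrent inhibition. It was chosen so that recurrent
inhibition is strong enough to require a visibly higher compensatory
baseline and to shape the manifold - the physiological roles attributed to
these circuits - while leaving rates tunable into the physiological band.

Connectivity: the homonymous circuit wires each of 60 cells to a random 17%
of the 300 motor neurons (exact in-degree) and inhibits each motor neuron
from ~40% of the cells (independent Bernoulli draws - read as an expected
density, since an exact out-degree is not implied). The three-pool circuit
uses 50%/60% homonymous densities, no heteronymous excitation of Renshaw
cells, and splits each pool's motor neurons randomly into thirds: two thirds
receive additional inhibition from 60% of one (distinct) heteronymous pool's
cells, the last third none. A random - not rank-ordered - split avoids
confounding the subgroups with recruitment threshold.

### Scenario analyses

`run_scenario()` pipes the first pool's spikes through the identical
experimental chain (continuity filter, smoothing, detrending,
surrogate-slope selection; factor analysis on the first pool only in the
three-pool scenario). The expected outcomes - one factor for scenarios with
homogeneous distributions or homonymous inhibition (i, ii, iv, vi; vi with
lower variance explained than i), three factors for heterogeneous
distributions or heteronymous inhibition (iii, v, vii) - are asserted as the
package's acceptance tests, as the mode over five seeds of 60 s runs.

## Synthetic populations

`latent_population()` draws `k_true` band-limited (<= 2.5 Hz) latent signals,
mixes them homogeneously or heterogeneously (the same softmax construction
as the simulator), adds independent band-limited noise (10% of modulation
variance by default, kept in the same 0-2.5 Hz band so that smoothing cannot
remove it), and generates spikes from an inhomogeneous gamma-renewal process
by time rescaling. The default shape of 16 reproduces the firing regularity
of steadily active motor units (ISI CoV 0.25, inside the physiological
0.1-0.3 range) - far more regular than a Poisson process, which matters both
because the surrogate criterion works on ISI statistics and because
point-process irregularity is the dominant noise floor of the smoothed
rates. Defaults (30 units, 80 s, 12 pps base rate, depth 0.2) match the
scale of a decomposed vastus lateralis sample over four 20 s plateaus. What
the generator does *not* emulate: decomposition errors (missed/false
spikes), rate saturation, recruitment/derecruitment dynamics within a
plateau, and slow fatigue drifts beyond the linear trend - so passing
recovery tests demonstrates correctness of the chain, not robustness to
decomposition artefacts.

The test fixtures (`write_fixtures()`) are fully seeded and byte-stable, and
each carries its ground truth in `manifest.json`.

## Numerical choices and degenerate inputs

* Sample indices use round-half-even; windows are half-open `[start, end)`.
* Zero-phase smoothing zero-pads the edges; spike-count conservation is
  exact to 0.5% away from edges.
* The 3x3 box blur renormalizes its kernel over in-bounds neighbours at map
  edges (zero padding would always bias the argmax inward); the converse
  cost is that a source one electrode away from a grid edge can pull the
  blurred argmax onto the edge channel. Localization is unbiased for
  interior channels.
* The dispersion norm tolerance defaults to 0.5% of the observed norm range;
  exact matching (`norm_tol = 0`) exists for analytic cases but ties are
  measure-zero in floating point.
* Units with fewer than two ISIs have undefined ISI CoV and can never win a
  duplicate group over a well-defined competitor.
* A recruitment threshold is `NA` (excluded downstream) when no three
  firings fall within one second.
* Factor-analysis failures at some k exclude that k and larger from the
  R-squared curves with a warning; selection proceeds on the available
  prefix.
* The integrator aborts with a message naming `dt` if any membrane potential
  exceeds ten times threshold.

## Problem sizes in the shipped tests

The acceptance suite runs every scenario for 60 s at `dt` = 0.1 ms (the
documented convergence margin makes the finer default unnecessary there),
five seeds per scenario with the baseline tuned on the first seed and reused
- the baseline is a property of the scenario, not of the noise realization.
Dimensionality recovery uses twenty 30-unit, 80 s synthetic populations.
Oracle-equivalence checks use 2 x 200 ensembles with lags up to two samples.
These sizes keep the whole suite within minutes on one CPU while
leaving every scientific claim asserted at full population size.

## Known limitations

* The LIF pool has no persistent inward currents, no rate saturation beyond
  the refractory ceiling, and no afferent feedback; its dimensionality
  conclusions concern input *distribution*, not biophysical realism.
* The diameter relations are calibrated constructions, so absolute
  conductance values (e.g. tuned baselines) are comparable only within this
  model.
* Factor-analysis selection assumes enough samples per unit
  (`samples >> units`); with fewer than ~8 units the likelihood machinery
  gives way to principal-axis fitting.
* Displacement/dispersion are exact but quadratic in series length; use
  decimation (explicitly) for recordings beyond a few thousand samples at
  the analysis rate.
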