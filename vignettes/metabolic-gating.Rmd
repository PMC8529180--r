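---
title: "Metabolically gated spiking networks: model, numerics, and design notes"
author: "atpnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolically gated spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atpnet)
```

## The model

`atpnet` simulates an excitatory network of leaky integrate-and-fire (LIF)
neurons whose excitability is gated by an intracellular ATP variable — a
minimal description of cortex under reduced metabolic supply (deep
anesthesia, hypoxia, hypothermia). Each neuron $i$ obeys

$$
c\,\frac{dv_i}{dt} = I_{app,i} + I_{leak,i} + I_{ATP,i}
  + \sum_j C_{ij}\, I_{syn,j\to i},
$$

with a dimensionless voltage running from 0 (reset) to 1 (threshold) and
capacitance $c = 1$. The terms are:

* **Applied current** $I_{app,i} \sim \mathcal N(I_{app0},\sigma_I^2)$ with
  $I_{app0} = 0.03$ and $\sigma_I = 0.006$, redrawn independently per neuron
  and per time step.
* **Leak** $I_{leak} = -v/\tau_{leak}$, $\tau_{leak} = 38.75$ ms.
* **ATP-gated potassium current** $I_{ATP} = -\alpha\, v\, ATP_{max}/ATP$
  with $\alpha = 0.002$: a hyperpolarizing conductance that *strengthens as
  ATP falls*. ATP itself recovers toward $ATP_{max} = 1$ with time constant
  $\tau_{ATP}$ and is decremented by $\varepsilon = 0.005$ at every spike:
  $$\frac{d\,ATP}{dt} = \frac{ATP_{max} - ATP}{\tau_{ATP}}
    - \varepsilon\,\delta(t - t_{spike}).$$
  $\tau_{ATP}$ is the experimental dial: it is the inverse of the ATP
  production rate and stands in for the cerebral metabolic rate. Values of
  4–10 s span the interesting dynamics.
* **Synapse**: an alpha-function EPSC $(t/\lambda)e^{-t/\lambda}$ with
  $\lambda = 2$ ms, realized as a two-stage linear cascade. One spike
  through a unit-strength link injects a voltage integral of
  $\int_0^\infty (t/\lambda)e^{-t/\lambda}dt = \lambda = 2$.

A note on the sign structure of $I_{ATP}$: the current must *weaken* as ATP
accumulates for the model to work at all — during silence ATP recovers
until firing becomes possible again, and an accumulated ATP store produces
an explosive rebound burst. Writing the current as
$-\alpha v\,ATP/ATP_{max}$ instead (proportional rather than inverse) would
make spiking easiest at *low* ATP and the threshold inequality below
unsatisfiable; `atpnet` therefore uses the inverse form throughout. The two
forms coincide at $ATP = ATP_{max}$. A configurable floor
(`atpFloor = 0.01`) keeps the inverse form finite during the deepest
bursts; at every fixed point and limit cycle we have examined, ATP stays
well above it.

### Spike-generation margin

At threshold ($v = 1$) the net current is

$$
m(ATP, f) \;=\; I_{app0} - \frac{1}{\tau_{leak}}
  - \frac{\alpha\,ATP_{max}}{ATP} + 2\,C\,f ,
$$

where $f$ is the locally felt firing rate in spikes/ms and $C$ the summed
incoming strength (0.4). When $m < 0$, a neuron arriving at threshold
cannot cross it: spike generation fails and an OFF period begins. At $f=0$
the margin vanishes at $ATP^\ast = \alpha/(I_{app0} - 1/\tau_{leak})
\approx 0.477$ (`failureMargin()` exposes this algebra). The slow
ATP variable sweeping back and forth across this boundary is the engine of
the ON/OFF alternation.

## The spatial network

5,000 neurons are scattered uniformly on a 20 × 5 mm rectangle (density
50/mm²). Each ordered pair $(j \to i)$ is linked independently with
probability $p_0 \exp(-d_{ij}^2/2\sigma^2)$, $\sigma = 250\,\mu m$; links
are directed and no reciprocity is imposed. Incoming strengths are then
normalized so every innervated neuron receives a total of exactly 0.4.
`rewireLinks()` implements small-world randomization: a fraction $\beta$ of
links have their source replaced by a uniform random neuron (no self-links,
no duplicates), after which the in-strength is re-normalized.

Two calibration choices deserve a note:

* **Kernel peak $p_0$.** Only $\sigma$ and the realized degree statistic
  (10 ± 2.85) are prescribed by the model; the kernel peak must be solved
  for. The interior-neuron integral gives
  $p_0 = k/(\rho\,2\pi\sigma^2) \approx 0.509$ for target degree $k = 10$
  (`calibratePeakProbability()`). On a finite sheet, however, neurons near
  the boundary lose kernel mass, and the *population mean* degree — the
  statistic one actually measures — undershoots the target by about 5 % on
  20 × 5 mm. Since the reference statistic is a realized mean, the builder's
  `"auto"` mode compensates for the boundary truncation (an analytic
  one-dimensional coverage integral per axis), yielding a realized mean
  in-degree of 10.0. The degree correction matters dynamically: the
  collective transitions described below sit close to a threshold in the
  effective recurrent gain, and a 5 % connectivity deficit visibly delays
  them in $\tau_{ATP}$.
* **Degree = in-degree.** The degree statistic is interpreted as the
  in-degree; out-degrees follow the same distribution by symmetry of the
  sampling.

## Numerics

* **Integration**: fixed-step Heun (explicit trapezoid, second order) at
  $dt = 0.5$ ms. Runs last 120 s and the first 20 s are discarded as
  transient. Voltages start uniform in $[0,1)$, ATP at $ATP_{max}$,
  cascades at zero.
* **Noise**: one Gaussian draw per neuron per step, frozen across both RK2
  stages, with no $\sqrt{dt}$ scaling — the applied current is specified as
  a current with an SD, not as a white-noise density, at the fixed
  $dt = 0.5$ ms. This makes the noise bandwidth dt-dependent, which we
  document rather than hide; dynamically the noise is weak (its
  within-cycle average is two orders of magnitude below the margin scale).
* **Spikes**: detected after the full step ($v \ge 1$), reset to 0
  (overshoot discarded), spike time = end of step, ATP decremented then
  floored. Outgoing impulses are delivered to the target cascades at the
  start of the *next* step (explicit ordering; no within-step
  self-excitation).
* **Refractoriness**: the *network* integrator has no refractory period.
  The *mean-field* integrator (below) holds the voltage at reset for
  exactly one step after each spike. This asymmetry is deliberate and
  empirically motivated: the one-step hold reproduces the reference
  steady-state discharge of the mean-field model to all printed digits
  (40.816 Hz at $\tau_{ATP} = 4$ s, across-time SD 0.017 Hz), while in the
  network the hold weakens synchronized volleys enough to suppress the
  global burst-suppression regime that the model is known to exhibit. The
  most economical explanation is that the two reference computations used
  slightly different spike-handling idioms (a scalar `if spike ... else
  integrate` loop versus a vectorized update), and we match each.
* **Determinism**: all integrator randomness flows through an internal
  xoshiro256++ generator seeded explicitly, so a run is bit-reproducible
  from its seed on any platform; R-level subsampling uses `set.seed`.
  Identical seeds give identical rasters; `runExperiment()` writes md5
  checksums of every artifact to make this checkable.

A pure-R mirror of one integration step (`rk2Step()`) is exported; the test
suite drives it in lockstep against the compiled integrator on a
deterministic fixture to guard the C++ implementation.

## The mean-field reduction

`simulateMeanField()` removes all network structure: a single neuron whose
synaptic input is its own Hann-windowed firing rate,

$$
c\,\frac{dv}{dt} = I_{app0} + I_{leak} + I_{ATP}
  + 2\,C_{feedback}\; iFR_{MF}(t),
$$

with $C_{feedback} = 0.4$ and the rate measured over a trailing 200-ms Hann
window, renormalized by the full-window integral $L/2$ (so a lone spike at
the window centre reads $2/L$ = 10 Hz). The factor 2 is the per-spike
voltage integral of a unit-strength synapse, which makes the feedback
commensurate with the network drive and with the threshold inequality
above. Noise is removed ($\sigma_I = 0$); the model is fully deterministic.

Behaviour across $\tau_{ATP}$:

* fast production ($\tau_{ATP} = 4$ s): steady discharge at 40.8 Hz;
* slower production (6.7 s): steady discharge near 25.4 Hz;
* slower still: the fixed point loses stability and the trace alternates
  between bursts and sub-1-Hz silences (`classifyRegime()` labels a trace
  `on_off` when it contains at least two sub-threshold intervals of 200 ms
  or more).

One numerical caveat we document prominently: the Hopf-like boundary of the
mean-field model is extremely sensitive to discrete-time details. With the
one-step hold the oscillation onset falls between $\tau_{ATP}$ = 7.2 and
7.5 s; without it, between 6.6 and 6.7 s; at $dt = 0.1$ ms near 6.3 s. The
reference value for the transition lies between 6.7 and 6.8 s, inside the
interval spanned by these discretizations but not reproduced exactly by
any variant we tried that also reproduces the printed steady rates. The
acceptance suite therefore checks the steady rates tightly and reports the
regime flip honestly (it fails at the 6.7/6.8 boundary under the one-step
hold). The spike-failure algebra — the boundary $ATP^\ast \approx 0.477$ —
is independent of these discretization questions.

## What the simulations show

Sweeping $\tau_{ATP}$ at the default geometry reproduces the canonical
state sequence:

* $\tau_{ATP} = 4$ s — continuous asynchronous firing near the mean-field
  rate; pairwise iFR correlations near zero at every distance.
* 5–7 s — *fragmented slow oscillation*: local populations alternate
  between active and silent phases, coherently within ~1 mm but
  asynchronously across the sheet; the distance-binned correlation is high
  at short range and decays steeply.
* 8–10 s — global burst suppression: population-wide silences longer than
  a second alternate with synchronized rebound bursts; the 50-ms iFR
  correlation stays above 0.8 out to 10 mm, and the ATP–rate phase portrait
  collapses onto a single wide loop touching zero rate.

The mechanism is the margin algebra above: as $\tau_{ATP}$ grows, the
steady-state ATP level sinks toward the failure boundary; local silences
become absorbing (a silent patch cannot re-ignite until ATP recovers), and
a silence that percolates across the sheet acts as a bottleneck that
re-aligns every neuron's rebound — whence global synchrony without any
long-range wiring. Because OFF-length is set by deterministic ATP recovery
and burst size by the ATP accumulated, OFF duration strongly predicts the
next burst's peak rate, while the converse correlation is weak
(`offOnPeakStatistics()`).

## Analysis conventions

* **iFR**: centred rectangular windows, 50 ms by default, stride 10 ms (the
  stride is an artifact choice — dense enough to resolve 1-s cycles, cheap
  to store). Rates are spike count / window length, in Hz.
* **ON/OFF segmentation**: 1-Hz threshold on the population iFR; maximal
  sub-threshold intervals are OFF; segments shorter than 50 ms are merged
  (shortest first) so labels alternate and the intervals tile the epoch
  exactly. The threshold method is appropriate for the model's regular
  cycles; segmentation of noisy experimental point processes is a harder
  problem and out of scope here.
* **Cycle statistics**: each OFF period is paired with the *following* ON
  peak and each ON peak with the *following* OFF duration; the first and
  last intervals are censored by the epoch edges and excluded. Pearson
  coefficients are computed per run and averaged across runs (the
  across-run mean ± SD is the reported statistic).
* **Correlations**: Pearson on the iFR series; zero-variance series are
  excluded with a logged count. Distance-binned averages use 200-µm bins
  and uniform pair subsampling (default cap 2,000 pairs per bin — the bin
  mean has negligible subsampling error at that size, and exhaustive
  enumeration is available and tested on small fixtures).
* **Simulated LFP**: $-\sum_i f(l_i)\,EPSC_i(t)$ with $f$ flat within
  100 µm of the electrode and $l^{-2}$ beyond; the electrode defaults to
  the sheet centre. EPSC means each neuron's total incoming synaptic
  current, evaluated at the postsynaptic soma.
* **Phase portrait**: population-mean ATP against population iFR, both on
  a common 50-ms moving window.

## Problem sizes used by the checks

The test suite validates elementary operations on closed-form oracles and
small fixtures (≤ 400 neurons, seconds of simulated time), and the
collective claims at the full default scale: single 120-s runs for the
distance-correlation and regime checks, five 150-s runs at
$\tau_{ATP} = 7$ s for the cycle statistics, and three seeds per
$\tau_{ATP}$ for the monotonicity checks (the two fastest-regime points
use shorter epochs; all stationary means are well separated). The
acceptance script mirrors these sizes (180-s epochs at
$\tau_{ATP} = 7$ s). The extended epochs are extended stationary sampling — more complete
ON/OFF cycles per replicate for the Pearson statistics — not a change of
any model parameter.

## What the generator does not emulate

The synthetic data are spikes from the model itself; passing checks shows
the implementation reproduces the *model's* documented behaviour, not that
the model captures any particular cortical recording. Known departures
from real tissue, inherited from the model scope: no inhibitory
population, no conduction delays, uniform synaptic strength (no log-normal
tail), no slow receptor kinetics, a hard rectangular boundary rather than
curved cortical geometry, and an open-loop metabolic dial ($\tau_{ATP}$
does not respond to activity). The alpha/beta-band structure of real
anesthesia EEG is absent by construction.

## Worked example

```{r example, eval = FALSE}
net <- buildNetwork(seed = 1)                      # 5000 neurons, 20 x 5 mm
res <- simulateNetwork(net, dynamicsParams(tauATP = 10000), seed = 1)
ifr <- computeIFR(res)                             # 50-ms windows
dc  <- distanceBinnedCorrelation(ifr, net@positions)
seg <- detectOnOff(ifr)
offOnPeakStatistics(seg)
```

On one CPU the full-scale 120-s simulation takes under a minute and the
analysis a further minute or two; all smaller examples in the manual pages
run in seconds.
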