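---
title: "Working memory from bistable dendrites: models, bands, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Working memory from bistable dendrites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dendband)
```

# The models

`dendband` implements three tiers of the same memory mechanism: persistent
neural activity maintained not by finely tuned recurrent feedback but by
the recruitment of bistable (hysteretic) dendritic compartments.

## Spiking autapse

A single integrate-and-fire soma is recurrently connected to itself through
ten conductance-based dendritic compartments.  Each compartment carries a
leak current, an inward-rectifier potassium (Kir) current gated by
$1/(1+e^{0.1(V+100)})$ (half-activated at $-100$ mV, so it stabilizes a
hyperpolarized resting state), an electrical coupling current to the soma,
and AMPA/NMDA synaptic currents driven by somatic spikes; the NMDA current
carries the magnesium-block factor $1/(1+0.15\,e^{-0.08V})$.  The positive
feedback between depolarization and NMDA conductance, opposed by the
hyperpolarization-activated Kir current, makes each compartment bistable: a
down state near $-88$ mV and a plateau near $-5$ mV, each self-sustaining
over a range of input rates.  The per-dendrite maximal NMDA conductance is
$\bar g_{\mathrm{NMDA},i} = 48\,(i+4.5)^{-0.54}\,\mu\mathrm{S/mm^2}$,
decreasing with the dendrite index.  We read the exponent as negative —
dendrites are then recruited in index order, matching both the rate model's
monotone-decreasing weights and the staircase protocol in which each 5 Hz
stimulus increment recruits exactly one further dendrite — and expose its
sign as a configuration option (`nmda_exponent`).

Numerical choices: forward Euler at $dt = 0.01$ ms, all voltages
initialized to $-70$ mV.  Synaptic gates decay exactly
($s \leftarrow s\,e^{-dt/\tau}$) and jump by $0.5\,(1-s)$ on each spike.
Spikes are detected by upward threshold crossing at $-50$ mV at the end of
an Euler step; the soma is then clamped at $30$ mV for 3 ms (somatic
integration suspended, dendrites keep integrating against the clamped
voltage, matching the stereotyped spike shape) and reset to $-80$ mV.  The
tonic current $I_{\mathrm{ton}} = -17.2$ nA/mm$^2$ enters the voltage
equation with a leading minus sign, i.e. it is net depolarizing; together
with the dendro-somatic coupling it places the somatic rest point just
below threshold (about $-50.8$ mV), so that each recruited dendritic
plateau raises the firing rate by a reliable increment.

The hysteresis characterization removes the autaptic feedback (open-loop
mode): the periodic external train drives the dendritic AMPA/NMDA gates
directly, somatic spikes have no synaptic effect, and the electrical
soma-dendrite coupling is kept.  The sweep runs 0 to 70 Hz and back in 1 Hz
steps, 1400 ms per step, averaging dendritic voltages over the last
1000 ms.  Up/down states are classified by comparing the mean voltage with
a separatrix at $-45$ mV; the mean-voltage distribution is strongly bimodal
(modes near $-85$ and $-5$ mV), so any separatrix in the valley gives the
same classification, which the test suite verifies against the histogram
valley.

## Rate autapse and the multistable band

The rate model replaces each dendrite with a binary latch: with weight
$w_i$, the latch flips up when $w_i r \ge T_u$, down when $w_i r \le T_d$,
and contributes $\beta$ while up.  Defaults follow the standard parameter
set $T_u = 9$, $T_d = 2$, $\beta = 1$, $\tau = 50$ ms, $dt = 1$ ms.  Two
conventions had to be fixed where the mathematics is silent:

* **Equality**: activation uses $\ge$, deactivation uses $\le$, and when
  both hold (only possible for $T_u = T_d$) activation wins.  This makes
  thresholds exactly attainable and degrades gracefully to a step
  nonlinearity at $T_u = T_d$.
* **Update ordering**: each Euler step first updates all latches from the
  current rate, then advances the rate with the updated latch outputs.
  This avoids a one-step lag at threshold crossings; the opposite ordering
  is available (`latch_first = FALSE`) for sensitivity checks.

Rates are *not* rectified at zero: the equations are integrated as written,
and under noise the quiescent rates fluctuate about a slightly negative
baseline set by global inhibition.

The summed latch outputs form the multistable band.  The discrete right
edge is $B_u(r) = \beta\,\#\{i : r \ge T_u/w_i\}$ and the left edge
$B_d(r) = \beta\,\#\{i : r > T_d/w_i\}$; in the continuum limit,
$B_u(r) = \beta\,w^{-1}(T_u/r)$ clamped to $[0, \beta N_d]$.  Power-law
$a/(x+b)^p$ and Gaussian profiles invert in closed form, tabulated and
custom profiles by monotone bisection; the staircase converges to the
continuum band within one step height $\beta$ in sup norm, which the test
suite checks at $N_d = 1000$.

## Ring network

$N = 360$ neurons on a ring, each excitatory connection terminating on its
own latch dendrite ($w_{ij} = 18/(d_{ij}+2)^2$ by default, self-connections
included since the formula defines them at $d = 0$), uniform global
inhibition $w_{\mathrm{inh}} = 1/360$, Gaussian stimulus
$I_A e^{-(i-180)^2/(2\cdot 10^2)}$.  Protocols run at $dt = 1$ ms; band
tracing uses $dt = 0.01$ ms.

The latch matrix is stored per presynaptic column as a prefix length over
dendrites sorted by decreasing weight.  This is exact, not an
approximation: all latches in a column see the same presynaptic rate
history, so the up set is always a weight-prefix.  Dendrites whose weight
is too small ever to matter at rates below a bound `r_bound` (default
1000) are pruned; the integrator aborts if any rate magnitude exceeds the
bound, so the pruning can never silently change the dynamics.

Band tracing follows the two protocols: the up edge is swept by the
encoding transient from rest at stimulus amplitude 80, plotting the peak
neuron's total recurrent feedback
$\beta\,(\text{up count}) - w_{\mathrm{inh}}\sum_j r_j$ against its rate;
the down edge by applying a uniform input of $-10$ to a stored memory until
activity returns to zero.  Because every recruitment event on the ring
flips a symmetric $\pm d$ pair of dendrites, the natural resolution of the
simulated band is a step of height $2\beta$ whose edge position shifts by
$O(1)$ rate unit between stimulus amplitudes; the band-overlap tests
therefore compare curves pointwise after allowing edges to slide by at most
one rate unit, and require agreement within $\beta$.

## Analytic band and the linear-design weights

Assuming the network profile keeps the stimulus shape $R(x)$ with peak
amplitude $A$, the dendrite of the peak neuron fed from distance $x$
receives drive $w(x)\,A\,R(x)$, giving the activation measure
$n_u(A) = |\{x : w(x) A R(x) \ge T_u\}|$ and the band edge
$B_u(A) = \beta\,n_u(A) - w_{\mathrm{inh}}\,\kappa\,A$ with
$\kappa = \int R = 10\sqrt{2\pi}$; each feedback step therefore carries
slope $-w_{\mathrm{inh}}\kappa$, and at $w_{\mathrm{inh}} = 0$ the
construction reduces exactly to the autapse continuum band with effective
weight $w(x)R(x)$.  The analytic stimulus-to-memory map integrates the
reduced one-dimensional amplitude dynamics with the latched measure
ratcheting between the activation and deactivation edges — the same
encode/memory fixed-point logic as the autapse.

The *linear-design* inversion asks for the weight profile whose mapping is
$M_A = c\,(I_A - I_{A,\mathrm{th}})$.  With $\nu = 1 + w_{\mathrm{inh}}\kappa$
the closed-form requirement is
$\beta n_u(A) = c\nu(\nu A - I_{A,\mathrm{th}})/(1 + c\nu)$, hence
$w(x) = T_u / (A_{\mathrm{act}}(x) R(x))$ with a linear activation schedule
$A_{\mathrm{act}}(x)$.  Two practical points:

* Past a turning distance the raw inversion rises with $x$, which no
  monotone profile can realize; those dendrites lie outside the design's
  operating amplitudes, and the tail is continued with the bump profile's
  own decay so that tail drives fall off as $R^2$ and stay silent.
* The bump-shape approximation is good during encoding but poor during
  memory (the memory profile is a narrow staircase, so
  $\sum_j r_j \approx \beta U/(1+w_{\mathrm{inh}}N)$, roughly half the
  Gaussian-area estimate), and the discrete recruitment thresholds are
  exquisitely sensitive to these few-percent shape errors.  The closed form
  alone therefore lands the realized mapping visibly off its targets.
  `design_linear_weights(calibrate = TRUE)` (the default) refines the
  closed form by a deterministic fixed-point iteration: noiseless
  simulations of the full ring measure, per dendrite distance, the drive
  available at each stimulus amplitude and the memory plateau levels; each
  recruitment threshold is then moved (damped, multiplicative, anchored at
  the observed thresholds) to the amplitude where the target line crosses
  the midpoint of the adjacent plateaus, which makes the staircase residual
  a symmetric sawtooth around the target line.  The best profile over a
  fixed number of passes is returned.  No randomness is involved, and the
  realized slope and intercept are re-measured from scratch by the
  acceptance script.

# Noise experiments

Noise is spatially and temporally independent Gaussian input to each
neuron's stimulus term, specified by its standard deviation $\sigma$ at the
1 ms reference step.  For $dt \ne 1$ ms the per-step deviation is scaled by
$\sqrt{1\,\mathrm{ms}/dt}$, which preserves the accumulated variance per
millisecond (the per-step value enters the Euler update multiplied by
$dt/\tau$); at $dt = 1$ ms this is identical to drawing $\mathcal N(0,
\sigma^2)$ per step.  All stochastic entry points take explicit seeds;
per-trial seeds are drawn once from the base seed, so ensembles are
reproducible and trials are independent.

The bump amplitude estimator (mean of the 10 highest rates, ties broken by
lowest index) has a noise-driven floor even when nothing is stored: the
upper order statistics of 360 fluctuating rates are positive.  Retention is
therefore classified against that floor, measured by a zero-stimulus
reference run per noise level: a trial retains its memory if its final
baseline-subtracted amplitude is at least 25% of its baseline-subtracted
amplitude 300 ms after stimulus offset.  Without the baseline correction a
complete collapse to the noise floor would be misclassified as retention
whenever the floor exceeds a quarter of the initial amplitude, which it
does at high $\sigma$ for weak stimuli.

Location diffusion uses the shared-initialization protocol: the network is
first run noiselessly with the step-function case $T_u = T_d = 3$ at
stimulus amplitude 15, and the resulting rates and latch states seed every
noisy trial across all bistable-range conditions ($T_u = 3 + 0.2s$,
$T_d = 3 - 0.2s$), keeping the memory amplitude comparable.  Locations are
unwrapped by accumulating minimal circular steps before variances are
computed (valid while successive samples move less than half the ring —
satisfied at the 50 ms sampling stride used), and the first 300 ms are
discarded.

# What the tests do and do not show

All inputs are generated in code: the simulations *are* the data.  The
protocols reproduce the study conditions — printed parameter sets, epoch
durations, stimulus grids — and the test suite runs them at these sizes:
the full hysteresis sweep and staircase protocol for the spiking model; the
36-point linear-design mapping; band traces at stimulus amplitudes 20, 40
and 80; amplitude retention with 10 trials per condition over the full 10 s
memory period; location diffusion across all eleven bistable ranges at 50
trials (reduced from 400; the variance estimates carry the corresponding
sampling error, which the monotonicity check accounts for at two standard
errors); and the 5% asymmetry perturbation at 20 trials.  None of this
emulates biological variability — there is no parameter heterogeneity
across dendrites beyond the weight profile, no spiking noise in the rate
models, and no synaptic dynamics beyond the two gate time constants — so
passing tests certify the computational mechanism, not a fit to
electrophysiology.

Known limitations:

* The collapse of weakly driven memories under strong noise is reproduced
  mechanistically (latch-by-latch deactivation and amplitude erosion), but
  its timescale depends exponentially on the margin between latched drives
  and $T_d$ relative to the noise amplitude.  In this reconstruction the
  margins come out near 2.3 noise standard deviations at $\sigma = 9$ for
  the weakest stimulus, so full collapse takes a few tens of seconds rather
  than completing within the 10 s observation window; the corresponding
  retention check in the acceptance suite documents this as a failing
  expectation rather than adjusting the protocol toward the expected
  outcome.
* The analytic ring band rests on the bump-shape approximation and is
  accurate away from saturation; near the highest sustainable rates the
  bump widens and the approximation degrades, as the band comparisons show.
* Location unwrapping is documented to be unreliable for drifts approaching
  half the ring within one sampling stride; the diffusion conditions stay
  far from that regime.
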