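# dendband

Simulation and analysis of working-memory circuits that store **graded
stimulus amplitude** — and, in a ring architecture, **stimulus location at
the same time** — by recruiting *bistable dendritic compartments* instead of
relying on finely tuned recurrent feedback.

## The scientific problem

Classic attractor models of working memory come in two families.
Location-coding (ring / bump-attractor) models store *where* a stimulus was,
but every memory has the same all-or-none amplitude.  Amplitude-coding (line
attractor) models store *how strong* a stimulus was, but require synaptic
feedback tuned to fractions of a percent, and both families diffuse under
neuronal noise.  If each neuron instead carries many bistable (hysteretic)
dendritic compartments, the recurrent feedback becomes a **multistable
band** rather than a line: dendrite $i$ flips up when its synaptic drive
$w_i r$ reaches an up threshold $T_u$, flips down when the drive falls to
$T_d < T_u$, and contributes $\beta$ to the firing rate while up,

$$\tau \frac{dr}{dt} = -r + \sum_{i=1}^{N_d} D_i(r) + I_{\text{stim}},$$

so stable persistent rates are the intersections of the unity-slope decay
line with the interior of the band spanned by the summed up-threshold curve
$B_u(r)$ and down-threshold curve $B_d(r)$.  The band has finite width
whenever $T_u > T_d$, which is what removes the fine-tuning requirement and
buys noise robustness.

The package implements the three model tiers for this mechanism:

1. **Spiking autapse** (`spiking_params()`, `run_hysteresis_sweep()`,
   `run_graded_storage()`): a conductance-based integrate-and-fire soma with
   ten dendritic compartments whose NMDA and inward-rectifier potassium
   (Kir) conductances generate voltage bistability (forward Euler,
   dt = 0.01 ms).
2. **Rate autapse** (`autapse_model()`, `integrate_autapse()`,
   `discrete_band()`, `continuum_band()`, `autapse_fixed_points()`,
   `stimulus_memory_map()`): hysteretic latch dendrites, the staircase band,
   its continuum limit $B_u(r) = \beta\, w^{-1}(T_u/r)$, and
   stimulus-to-memory mappings for power-law, Gaussian and tabulated weight
   profiles.
3. **Ring network** (`ring_model()`, `simulate_ring()`,
   `run_encode_memory_ring()`, `trace_band_simulated()`,
   `analytic_band_ring()`, `design_linear_weights()`): N = 360 rate neurons
   with one bistable dendrite per excitatory connection
   ($w_{ij} = 18/(d_{ij}+2)^2$ by default), global inhibition
   $w_{\text{inh}} = 1/360$, Gaussian stimuli; simulated and analytic
   multistable bands, and a weight-design procedure that produces a linear
   memory-amplitude-versus-stimulus-amplitude mapping
   $M_A = c\,(I_A - I_{A,\text{th}})$.

Noise experiments (`amplitude_drift_experiment()`,
`location_diffusion_experiment()`) measure amplitude retention and
bump-location diffusion under per-step Gaussian input noise, with the
bump amplitude estimated as the mean of the 10 highest firing rates and the
location as the circular center of mass.

## Worked example

The graded-storage staircase: after a 1200 ms settling period, ten 400 ms
periodic-spike stimuli (20 to 65 Hz in 5 Hz steps) are each followed by an
800 ms memory period.  Every frequency step recruits exactly one more
bistable dendrite, and the somatic memory rate climbs accordingly:

```r
library(dendband)
gs <- run_graded_storage(spiking_params())
gs$staircase
#>    step freq up_count memory_rate memory_rate_isi
#> 1     1   20        1        12.5        12.62626
#> 2     2   25        2        17.5        17.64334
#> 3     3   30        3        20.0        20.83768
#> ...
#> 10   10   65       10        37.5        35.52399
```

`up_count` is the number of dendrites in the depolarized plateau state at
the end of each memory period (one new dendrite per step), and the memory
rate (spike count, and interspike-interval estimate, over the final 400 ms
of each memory period) forms the staircase that stores the stimulus
amplitude.

On the ring, the designed network maps stimulus amplitude linearly into
memory amplitude:

```r
prof <- design_linear_weights(c = 0.5, IA_th = 1.2)
m <- ring_model(profile = prof)
run_encode_memory_ring(m, IA = 20)$amplitude
#> [1] 9.923611        # close to 0.5 * (20 - 1.2) = 9.4, quantized in
                      # steps of one symmetric dendrite pair
```

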