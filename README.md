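# neuroregrow

Simulation of homeostatic structural plasticity and repair after
peripheral lesions in balanced spiking cortical networks.

## What this is for

When a patch of cortex loses its sensory input (a peripheral lesion), the
deprived region — the lesion projection zone (LPZ) — rewires over weeks:
excitatory axons sprout into it from intact cortex, inhibitory axons grow
out of it, and activity gradually returns. `neuroregrow` is for
computational neuroscientists who want to simulate this process and probe
*which activity-dependent growth rules* for axonal and dendritic contact
points (synaptic elements) reproduce it.

The model combines, in one network:

- conductance-based leaky integrate-and-fire neurons (80% excitatory,
  20% inhibitory) on a jittered toroidal sheet, sparsely wired
  (p = 0.02) with distance-dependent kernels, driven by independent
  Poisson input;
- symmetric inhibitory STDP on I→E conductances
  (Δg = η·ḡ·(x_post − α) at pre-spikes, Δg = η·ḡ·x_pre at post-spikes),
  which balances the network into the low-rate asynchronous irregular
  (AI) regime;
- Gaussian growth curves turning each neuron's calcium trace Ca (decay
  τ = 50 s, +0.1 per spike) into element turnover,

  dz/dt = ν ( 2·exp(−((Ca − ξ)/ζ)²) − ω ),   ξ = (η+ε)/2,
  ζ = (ε−η) / (2·√(−ln(ω/2))),

  with zero crossings at η and ε, extrema ν(2−ω) and −νω, and per-neuron
  placement relative to the optimal calcium ψ recorded at balance;
- a structural connectivity update (1 s interval): element-loss-driven
  deletion (uniform for excitatory synapses, weight-dependent
  p_del = exp(−(g/2g_th)²) with an immunity threshold for inhibitory
  ones), harvesting of free elements, distance-kernel synapse formation
  (p_form = p̂·exp(−(d/wμ_dE)²)), and decay of unused free elements.

The membrane-level loop is compiled (Rcpp); everything user-facing takes
and returns tibbles.

## Worked example: growth-curve analytics

```r
library(neuroregrow)
gc <- growth_curve(nu = 1, eta = 5, epsilon = 15, omega = 0.001)
gc
#> <growth_curve> nu = 1  eta = 5  epsilon = 15  omega = 0.001
#>   max dz/dt = 1.999 at Ca = 10 ; asymptotic min = -0.001
```

A curve shifted up by a small ω sprouts fast between its zero crossings
(maximum 1.999 elements per step at the midpoint Ca = 10) and retracts
only very slowly outside them (asymptotic rate −0.001): this is the shape
used for dendritic elements that must grow under deprivation but not
collapse under overexcitation.

## Worked example: single-neuron homeostasis

```r
sn <- run_single_neuron_experiment()
sn
#> <single_neuron_run> psi = 181.1
#>   z_postE / z_postI after grow-in = 4
#>   cor(ca - psi, dg_net) over sinusoid = -0.7377
```

The isolated neuron initialises its dendritic elements at the 4:1
excitatory:inhibitory ratio of a balanced network neuron (exact by
construction, ν_E = 4ν_I under identical growth windows). When its
activity is then modulated sinusoidally, the net input conductance its
elements would deliver (g_net = z_postE·g_EE − z_postI·g_IE) moves
*against* the activity deviation — the correlation of −0.74 is the
homeostatic counteraction: the dendritic growth rules stabilise single
neurons, not just networks.

## Worked example: a desk-scale lesion experiment

```r
fx  <- make_fixture(scale = 0.2, seed = 1, overrides = desk_overrides())
run <- run_lesion_experiment(fx)          # balance, lesion at 80 s, repair
repair_feature_checklist(run)[, 1:2]
#>   feature                    status
#> 1 initial_stability          TRUE
#> 2 lpz_rate_recovery          TRUE
#> 3 outside_rate_normalisation TRUE
#> 4 stable_final_state         TRUE
#> 5 lpz_b_before_lpz_c         TRUE
#> 6 excitatory_ingrowth        TRUE
#> 7 inhibitory_outgrowth       TRUE
#> 8 transient_disinhibition    TRUE
autoplot(run)                              # region rate trajectories
plot_incoming_projections(run, "EE")       # ingrowth into the LPZ centre
```

With the reference growth configuration (regime G2: excitatory axons
sprout above ψ, inhibitory below; dendritic fixed points at ψ), the
0.2-scale network collapses in the LPZ after deafferentation
(4.2 → 0.0 Hz), recovers through excitatory ingrowth (EE projections
from outside into the LPZ centre: 384 → 2570 in the run above), shows
transient dis-inhibition of the LPZ centre (317 → 265 → 644 inhibitory
inputs) and outgrowth of inhibitory projections from the LPZ, with the
LPZ border reactivating before the centre. Toggling the mechanisms
(`fx$cfg$toggles`) dissects them: iSTDP alone leaves the LPZ silent;
structural plasticity alone restores activity but never settles at the
balanced level.

A thin command-line front end over these functions is installed at
`inst/cli/neuroregrow` (`balance`, `lesion`, `single-neuron`, `regimes`,
`metrics` subcommands; plain-text gdf/CSV/JSON outputs).

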