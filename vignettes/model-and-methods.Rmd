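---
title: "Homeostatic structural plasticity after peripheral lesions: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homeostatic structural plasticity after peripheral lesions: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(neuroregrow)
```

# The scientific problem

After a peripheral lesion — loss of sensory input to a patch of cortex —
the deprived region (the lesion projection zone, LPZ) rewires: excitatory
axons grow into it from the surrounding intact cortex, inhibitory axons
grow out of it, dendritic spines are gained and inhibitory shaft synapses
lost, and activity gradually returns. `neuroregrow` simulates this process
in a balanced spiking cortical network in which every neuron grows and
retracts *synaptic elements* (abstract axonal and dendritic contact
points) as a function of its own activity, while inhibitory
spike-timing-dependent plasticity (iSTDP) continuously tunes
inhibitory-to-excitatory conductances. The package asks, and lets you ask:
**which activity-dependent growth rules for each element type reproduce
the experimentally observed course of repair?**

# The model

## Neurons and synapses

Neurons are conductance-based leaky integrate-and-fire point neurons with
exponential synapses:

$$C \frac{dV}{dt} = -g_L (V - E_L) - g_{exc}(V - E_{exc})
  - g_{inh}(V - E_{inh}) + I_e,$$

with the standard cortical constants (200 pF, 10 nS leak at −60 mV,
threshold −50 mV, reset −60 mV, 5 ms refractory period, 5/10 ms
excitatory/inhibitory conductance decay; see `neuron_params()`). 80% of
neurons are excitatory (E), 20% inhibitory (I). Each neuron receives an
independent 10 Hz Poisson external drive through a static excitatory
conductance. EE, EI and II conductances are static; IE conductances are
plastic under the symmetric iSTDP rule: at a presynaptic (inhibitory)
spike $\Delta g = \eta \bar g (x_{post} - \alpha)$, at a postsynaptic
spike $\Delta g = \eta \bar g\, x_{pre}$, where $x$ are per-neuron spike
traces with a 20 ms time constant and $\alpha = 0.12$ sets the target
activity ($\alpha / 2\tau_{STDP}$ = 3 Hz). This rule grows inhibition
from zero until excitatory firing settles at a low rate, producing the
asynchronous irregular (AI) regime. The membrane loop is compiled (Rcpp)
with forward-Euler voltage integration at 0.1 ms and exact exponential
conductance decay; spikes are delivered with a one-step transmission
delay (the source text specifies no delays; the step is a configurable
engine property).

## Activity readout and growth curves

Each neuron's activity is summarised by a calcium trace: exponential
decay with $\tau_{Ca} = 50$ s and an increment $\beta = 0.1$ per spike,
so that under steady firing at rate $r$ the trace averages
$\beta r \tau_{Ca}$. The turnover rate of each class of synaptic element
is a Gaussian function of this trace:

$$\frac{dz}{dt} = \nu\left(2 e^{-\left(\frac{Ca - \xi}{\zeta}\right)^2}
  - \omega\right), \qquad
  \xi = \frac{\eta + \epsilon}{2}, \quad
  \zeta = \frac{\epsilon - \eta}{2\sqrt{-\ln(\omega/2)}},$$

positive between the zero crossings $\eta$ and $\epsilon$, negative
outside, with analytic extrema $\nu(2-\omega)$ (at the midpoint) and
$-\nu\omega$ (asymptotically). The vertical shift $\omega$ decouples the
speeds of sprouting and retraction. Each neuron has three element pools:
axonal (excitatory axons on E neurons, inhibitory on I — a neuron never
bears the opposite polarity), post-synaptic excitatory, and post-synaptic
inhibitory. Curves are positioned relative to each neuron's *optimal
calcium* $\psi$, recorded at the moment the balanced state is declared;
because the AI state leaves similar but not identical activities, $\psi$
is per-neuron. A neuron at $\psi$ turns over no elements.

The reference configuration (regime **G2** plus the reference dendritic
placement) is: excitatory dendritic elements with stable fixed point
$\epsilon = \psi$ (sprout when deprived), inhibitory dendritic elements
with $\eta = \psi$ (sprout when overexcited), excitatory axons sprouting
above $\psi$, inhibitory axons sprouting below $\psi$. The full axonal
battery G0, G0', G1–G5 is available through `make_regime_curves()`, as is
the dendritic battery (placements $\epsilon=\psi$, $\eta<\psi<\epsilon$,
$\eta=\psi$ per pool).

## Element bookkeeping and the connectivity update

The continuous count $z$ per pool is integrated at the growth step
(0.1 s) inside the engine and clamped at zero from below (element counts
are physical). Once per structural interval (1 s) the connectivity
update runs, in a fixed order chosen so the update is idempotent at
steady state:

1. **Deletion**: each pool with $z$ below its connected count sheds
   $z_{loss} = \lfloor z_{conn} - z\rfloor$ synapses. Losses of
   excitatory elements pick candidates uniformly; losses of inhibitory
   elements (IE/II) use weight-dependent deletion
   $p_{del} = e^{-(g/2g_{th})^2}$ with synapses at or above the immunity
   threshold $g_{th}$ excluded outright. $g_{th}$ is recorded once, at
   balance, as the mean learned IE conductance — the only
   simulation-derived inhibitory conductance scale the model defines.
   A consequence worth knowing: II conductances ($10\bar g$) sit far
   above this threshold, so in practice II synapses are immune and IE
   synapses carry the weight-based competition.
2. **Harvest**: free counts $z_{free} = \lfloor\max(z - z_{conn},
   0)\rfloor$.
3. **Formation**: neurons with free axonal elements are visited in random
   order; every neuron with a complementary free dendritic element is a
   candidate partner, accepted with the spatial kernel
   $p_{form} = \hat p\, e^{-(d/w\mu_{dE})^2}$ (narrow for excitatory
   axons, $w_E = 8$; broad for inhibitory, $w_I = 24$) until either
   side's free supply runs out. Autapses are forbidden; multiple parallel
   synapses between a pair are allowed (the element bookkeeping
   naturally permits them). New EE/EI conductances draw from
   $N(\bar g, 0.1)$, II from $N(10\bar g, 0.1)$, and new IE synapses
   start near the mean learned IE conductance so they are neither
   instantly re-deleted nor invisible to STDP.
4. **Decay**: unused free elements decay by $\tau_{free} = 0.01$ per
   update (floored), and $z$ is reduced by the decayed amount so decayed
   elements are not resurrected at the next harvest.

Deletions are computed from the state at the start of the update and
processed pool by pool; when two pools claim the same synapse the second
claim silently finds it gone and the next update corrects the residual —
the per-update error is at most one synapse per neuron and conservation
(per class, $\sum z_{conn}^{pre} = \sum z_{conn}^{post} =$ synapse count)
holds exactly after every update, which the test suite asserts.

## Spatial layout and the lesion

Excitatory neurons sit on a jittered rectangular lattice (spacing 150 µm,
jitter SD 15 µm), inhibitory neurons interleaved at twice the spacing,
and the sheet wraps into a torus (no edge effects). Regions are assigned
by ranking each population by distance from the sheet centre: 2.5% LPZ
centre, 2.5% LPZ border, 5% peri-LPZ, 90% other — rank-based assignment
hits the printed fractions exactly and keeps the E:I ratio uniform across
regions. Initial wiring gives every neuron exactly
$n_{out} = \mathrm{round}(p(N-1))$ targets ($p = 0.02$), sampled without
replacement with the same class-specific spatial kernel used for synapse
formation (the source describes only "a distance dependent manner"; using
one kernel family throughout is this package's choice). The lesion
(`deafferent()`) permanently disconnects the external Poisson drive from
every neuron, E and I, in the LPZ centre and border.

## Experiment protocol

Every experiment runs in two phases (`run_balance_phase()`,
`run_lesion_experiment()`): iSTDP-only balancing to the AI state until
$t_1$; recording of $\psi$, the IE mean and $g_{th}$ at $t_1$; both
mechanisms until the lesion at $t_2$ (verifying the network stays
balanced — total synapse count varies by well under 5%); then repair
until $t_{end}$ under the configured mechanism toggles and growth
regime. The AI criterion is the standard one: mean ISI CV > 1 and
population-rate SD < 5 Hz, with mean pairwise cross-correlation (5 ms
bins, sampling rule: all neurons up to 800, else max(800, 10%)) below 0.1
as the asynchrony convention. The population-rate estimator is the
population spike histogram at the correlation bin width (5 ms), in Hz per
neuron — one binning convention across all metrics. Runs whose mean rate
exceeds 10× the balanced mean for 10 s are stopped and flagged as
runaway; that outcome is itself informative (structural-only repair).

# Desk-scale conditions

The full-scale model (8000 E + 2000 I, 18,000 s) is a cluster-budget
computation. The package's standard test conditions use a 0.2-scale
fixture (1600 E + 400 I on a 6 × 6 mm torus) with a canonical set of
desk overrides (`desk_overrides()`), chosen once and frozen:

- **Recurrent unit conductance 1.25 nS** (full scale 0.5 nS). A 0.2-scale
  neuron has a fifth of the recurrent synapses; without compensation the
  drive-balance structure degenerates (excitatory rates sit below the
  iSTDP target and inhibition never grows). 1.25 nS restores enough
  recurrent coupling for genuine inhibitory balancing while keeping
  single EPSPs small enough that recurrent input alone cannot reignite a
  deafferented zone — the property behind the iSTDP-only control.
- **External conductances 16/24 nS** (full scale 8/12). Keeps the
  external share of each neuron's drive — the share the lesion removes —
  dominant, as it is at full scale; this sets the depth of the LPZ
  collapse (to ~5% of the pre-lesion rate at desk scale).
- **Kernel widths 3.6/10.8** (full scale 8/24), i.e. scaled by
  $\sqrt{0.2}$. Keeps the reach of excitatory and inhibitory projections
  proportional to the LPZ radius; without this the broad inhibitory
  kernel spans the whole miniature sheet and the post-lesion peri-LPZ
  disinhibition effect inverts.
- **iSTDP learning rate ×10**, so balancing completes within a 60 s
  $t_1$.
- **Growth scaling factors per pool** (E axonal 0.3, E postE 0.6, E postI
  1.0, I axonal 5, I postE 0.6, I postI 0.15 elements/s): the biological
  repair takes months, the full-scale model compresses it to hours, and
  the desk schedule compresses it to a 300 s repair window. Acceleration
  is deliberately non-uniform — the dendritic pools, four orders of
  magnitude slower than axonal ones at full scale, are accelerated more,
  so that the repair completes without a synapse-count explosion from
  the already-fast inhibitory axonal pool. Window positions (as
  multiples of $\psi$), $\omega$ values and every other parameter keep
  their full-scale defaults.
- **Schedule** $t_1 = 60$ s, $t_2 = 80$ s, $t_{end} = 380$ s.

What desk-scale passing shows — and what it does not. The desk fixture
reproduces, with the reference G2 configuration: balancing into the AI
state; LPZ collapse and ingrowth-driven recovery; the transient peri-LPZ
rate increase (a few percent at this scale versus ~8%/~19% reported at
full scale); LPZ-B reactivating before LPZ-C; excitatory ingrowth into
the LPZ centre; inhibitory outgrowth from the LPZ; transient
dis-inhibition of the LPZ centre followed by re-inhibition; and the
mechanism dissection (iSTDP-only leaves the LPZ silent; structural-only
recovers activity but never settles at the balanced level). These are
direction-and-ordering reproductions: absolute magnitudes (the 3×10⁴ →
5×10⁴ growth of excitatory inputs to the LPZ centre, the exact percentage
rate changes) belong to the full-scale network and are not desk
quantities. At desk scale the AI criterion's CV margin is also thin
(≈1.02 against the >1 threshold): a 2000-neuron drive-dominated network
is intrinsically closer to Poisson-like firing than the full-scale one.

A further caveat shared with the full-scale model: the synthetic network
is a uniform sheet with one cell type per polarity, a single calcium
compartment per neuron (so a neuron can only grow *or* retract a given
element type at one time), and no axonal/dendritic morphology — passing
desk tests says nothing about morphology-dependent rewiring in real
cortex.

# The single-neuron experiment

`run_single_neuron_experiment()` isolates the dendritic growth rules. A
neuron driven by constant current defines $\psi$; a sub-optimal drive
phase grows both dendritic pools under identical windows with
$\nu_E = 4\nu_I$, initialising the element counts at the 4:1 ratio of a
balanced network neuron (the ratio is exact by construction — both pools
integrate the same curve shape scaled by 4, and the shared decay
preserves the ratio); the reference curves are then restored (zero
turnover at $\psi$) and the current modulated sinusoidally. The readout
is $g_{net} = z_{postE}\, g_{EE} - z_{postI}\, g_{IE}$ as a deviation
from baseline. Because the isolated neuron's elements have no partners,
they are free elements and decay at $\tau_{free}$ per interval (applied
continuously here — there is no connected/free partition to floor
against). That leak is what makes the element counts *track* the
activity deviation instead of integrating it: the counts behave as a
low-pass filter of $-(Ca - \psi)$ with a ~100 s time constant, giving a
clearly negative correlation (≈ −0.7 at the default 600 s period)
between $Ca - \psi$ and $\Delta g_{net}$ — the counteracting, homeostatic
response. The experiment is open loop: the sinusoidal current is the only
driver, and $g_{net}$ is a readout.

# Numerical choices and degenerate inputs

- Curves with $\omega \ge 2$ (no zero crossings) or $\eta \ge \epsilon$
  are rejected at construction.
- $\psi$ is floored at 0.05 calcium units when recorded, so neurons that
  happen to be silent at $t_1$ still get well-defined (narrow, low)
  growth windows rather than degenerate ones.
- Membrane integration is forward Euler at 0.1 ms with exact exponential
  conductance decay; non-finite voltages abort with diagnostics.
- Five RNG streams (placement, wiring, drive, plasticity, metric
  sampling) are kept independent by saving and swapping R's RNG state,
  so switching one mechanism off does not perturb the random numbers
  another consumes — toggle comparisons share an identical balanced
  prefix.
- The growth integration step (0.1 s) and the membrane step (0.1 ms) are
  separate configuration knobs; scaling factors $\nu$ are stored per
  second (printed per-step values divided by the 0.1 s growth step).
- `structural_update()` recomputes connected counts from the synapse
  table itself, so bookkeeping cannot drift; conservation is asserted in
  the tests after every update of a lesion run.

# Problem sizes used by the tests

The suite balances one 0.2-scale fixture (60 s + 20 s verification,
reused across the acceptance tests), runs the three mechanism-toggle
lesion experiments at 300 s repair each, one 0.05-scale conservation run,
the single-neuron experiment (~1550 s of one-neuron simulation), and the
full-scale (10,000-neuron) construction checks. These sizes were chosen
so a complete check of the model's claims runs on one CPU in well under
half an hour.
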