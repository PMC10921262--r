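---
title: "The prebotc model: biophysics, protocols and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The prebotc model: biophysics, protocols and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`prebotc` simulates random conductance-based models of the preBötzinger
complex (preBötC), the brainstem kernel of the inspiratory rhythm, and
measures how simulated opioids degrade and eventually shut down the
population rhythm. This vignette is the package's account of the model, the
experiment protocols, and the numerical and design choices behind them.

## The single-neuron model

Each of the $N$ neurons follows a persistent-sodium (Butera-type) membrane
model with a fast spiking sodium current, a delayed-rectifier potassium
current, a potassium-dominated leak, and the slowly inactivating persistent
sodium current $I_{\mathrm{NaP}}$ that enables intrinsic bursting:

$$-C_m \frac{dV}{dt} = I_{\mathrm{Na}} + I_{\mathrm{NaP}} + I_{\mathrm{leak}}
 + I_K + I_{\mathrm{syn,exc}} + I_{\mathrm{syn,inh}} + I_{\mathrm{syn,op}}
 + I_{\mathrm{hyp,op}}$$

with (outward-positive, nS·mV = pA)

* $I_{\mathrm{Na}} = g_{\mathrm{Na}}\, m_\infty^3 (1-n)(V - E_{\mathrm{Na}})$
* $I_{\mathrm{NaP}} = g_{\mathrm{NaP}}\, D_{\mathrm{NaP}}(t)\,
  m_{\mathrm{NaP},\infty}\, h\, (V - E_{\mathrm{Na}})$
* $I_{\mathrm{leak}} = g_{\mathrm{leak}}\, D_{\mathrm{leak}}(t)\,
  (V - E_{\mathrm{leak}})$
* $I_K = g_K n^4 (V - E_K)$
* $I_{\mathrm{syn,exc}} = g_{\mathrm{exc}} (V - E_{\mathrm{exc}})$,
  $I_{\mathrm{syn,inh}} = g_{\mathrm{inh}} (V - E_{\mathrm{inh}})$,
  $I_{\mathrm{syn,op}} = g_{\mathrm{op}}(t) (V - E_{\mathrm{exc}})$
* $I_{\mathrm{hyp,op}} = D_{\mathrm{op}} \, I_{\mathrm{hyp,op}}(t)$, applied
  only to neurons carrying the µ-opioid receptor flag $D_{\mathrm{op}} = 1$.

The gates relax as $dn/dt = (n_\infty - n)/\tau_n$ and
$dh/dt = (h_\infty - h)/\tau_h$, with logistic steady states
$x_\infty = (1 + \exp((V - E_x)/\sigma_x))^{-1}$ and
$\tau = \tau_b / \cosh((V - E)/2\sigma)$. Every directed synapse carries a
first-order gate $ds/dt = ((1-s)\,m_{\mathrm{syn},\infty} - s)/\tau_{\rm syn}$
driven by the presynaptic voltage through
$m_{\mathrm{syn},\infty} = (1+\exp((V_{\rm pre} - E_s)/\sigma_{\rm syn}))^{-1}$;
the conductance a neuron receives is the sum of $g_{\rm syn,max} \cdot s$
over incoming edges, routed into $g_{\rm exc}$, $g_{\rm inh}$ or
$g_{\rm op}$ by the presynaptic class (excitatory MOR−, inhibitory,
excitatory MOR+).

`global_params()` returns the shared constants (units mV, ms, nS, pF, pA;
`tau_hb` is stored as 10,000 ms). The two heterogeneous conductances are
per-neuron: `g_leak` from a three-component Gaussian mixture (weights 0.35 /
0.1 / 0.55, means 0.5 / 0.7 / 1.2 nS, sd 0.05 nS) and `g_NaP` from a
Gaussian (0.8 ± 0.05 nS). Together they place each neuron in one of three
intrinsic regimes — quiescent, bursting, or tonic spiking — visible in
`phase_diagram()`.

## Opioid mechanisms and what is modulated

Simulated opioid acts through two pathways, both restricted to the MOR+
subpopulation (`D_op = 1`; half of the excitatory neurons, never inhibitory
ones):

1. a hyperpolarizing current `I_hyp_op` (pA), and
2. presynaptic depression: the maximum conductance of MOR+ neurons'
   outgoing excitatory synapses is scaled by $g_{\rm syn,op}(t)$ relative to
   its control value.

The population-wide drug factors `D_NaP` and `D_leak` multiply every
neuron's `g_NaP` and `g_leak`; they implement pharmacological rescue
(e.g. raising `D_NaP` to 1.3 or lowering `D_leak` to 0.5).

## Network construction

`build_network()` draws a directed Erdős–Rényi graph on `N = 300` neurons
(240 excitatory, 60 inhibitory) with per-ordered-pair connection probability
$(d_{\rm avg}/2)/(N-1)$; the default average total degree 6 gives ~1%
density. No self-edges, at most one edge per ordered pair. MOR+ identity is
assigned to exactly half of the excitatory neurons: uniformly at random, or
to the below-/above-median `g_leak` halves (`low_gleak` / `high_gleak`
policies; ties broken by stable sort on (g_leak, index), so the split is
always exactly 120/120). Four RNG streams (topology, conductances,
population identity, initial state) are derived independently from one
master seed so that, e.g., MOR policies can be compared on otherwise
identical networks. `scale_density()` rebuilds the topology at a multiple of
the density while dividing every synaptic conductance by the same factor,
keeping the expected total synaptic strength constant.

**Baseline synaptic strength (calibrated).** The per-synapse maximum
conductance is the one structural quantity with no principled prior value,
and the emergent network rhythm is extremely sensitive to it: below ~2 nS a
default network produces no population bursts at all (neurons fire
asynchronously), while far above ~5 nS bursts fuse toward continuous
synchronized activity. We calibrated it once, before measuring any
opioid-response quantity, to the smallest value at which all six calibration
networks (seeds 1–6) produce at least five control bursts in 80 s:
`g_syn_max = 3` nS, which yields median burst amplitudes of 17–25 Hz/cell —
comfortably spanning the 10–15 Hz/cell amplitude thresholds the shutdown
analysis depends on. It is exposed in `build_network()` and
`experiment_config()`. The opioid ramp's printed conductance course (1.0 → 0
"nS") is therefore interpreted fractionally: MOR+ synapses run at
`g_syn_max * g_syn_op(t) / g_syn_op_control`, i.e. from their full baseline
down to zero in the same 0.5% steps.

## Numerical integration

The network is advanced with a fixed-step **exponential midpoint** scheme
(second-order exponential Runge–Kutta): the membrane equation is written as
$dV/dt = -(G_{\rm tot} V - B)/C_m$, a half step of exponential Euler
predicts the midpoint state, and the full step reuses the exact exponential
update with all coefficients (steady states, conductances, relaxation
rates) evaluated at the midpoint. Gates update the same way; because every
update is a convex combination of the current value and a steady state in
(0, 1), the gates provably remain in [0, 1] at any step size. The
voltage-dependent functions are tabulated on a 0.02 mV grid (interpolation
error ~1e−9) for speed.

Plain (first-order) exponential Euler was evaluated first and rejected: at
`dt = 0.05` ms it loses roughly a fifth of the spikes of a near-boundary
burster relative to a high-order reference, and converges only near
`dt = 0.005` ms. The midpoint scheme reproduces the reference spike count at
`dt = 0.05` ms and shows clean second-order spike-time convergence; the test
suite verifies it against an independent classical RK4 integrator (no
tables, direct evaluation of all gating functions, `integrate_neuron_reference()`)
at one tenth of the step, and against an exact exponential-relaxation
solution to 1e−6 relative accuracy. Default `dt = 0.05` ms (configurable up
to 0.1 ms, where burst-level statistics are still converged).

Initial conditions are not part of the model's definition; we draw
$V_0 \sim U(-65, -55)$ mV per neuron (desynchronized start), set
$n = n_\infty(V_0)$, $h = h_\infty(V_0)$, and all synapse gates to 0. Spikes
are upward crossings of −20 mV with a 2 ms lockout; action potentials
overshoot this threshold by a wide margin, and the choice is insensitive
over roughly [−30, −10] mV (both are configurable).

## Protocols

* `make_ramp_schedule()` — the gradual opioid ramp: `I_hyp_op` climbs 0 → 8
  pA and `g_syn_op` falls 1 → 0 (of control) in 0.5% steps every 3 s; 200
  steps, 600 s total.
* `make_perturbation_schedule()` — the timed all-or-nothing protocol: 200 s
  split into 10 s transients alternating with 30 s analysis segments
  (control / opioid / wash / drug / opioid + drug), with opioid at
  `I_hyp_op = 4` pA and `g_syn_op = 0.5`, and the drug scaling `g_NaP`
  (110/130/150%) or `g_leak` (90/70/50%). Transient segments are flagged and
  excluded from analysis.
* `constant_schedule(..., synaptic_block = TRUE)` — synaptic block for
  intrinsic classification: all synaptic conductances are forced to zero
  (the synapse gates are frozen; they are irrelevant while blocked), so
  every neuron expresses its intrinsic activity.

## Rhythm analysis

`population_rate()` bins all spikes (10 ms bins), normalizes to Hz per cell
(rate / N), and smooths with a Gaussian kernel (σ = 25 ms) whose mass is
renormalized per bin so the integral of the trace is conserved exactly. The
bin and kernel widths resolve the ~300–600 ms network bursts while keeping
peak heights in the 10–30 Hz/cell working range; both are configurable, and
the acceptance tolerances absorb the residual estimator sensitivity.

`detect_bursts()` finds local maxima with height ≥ 4 Hz/cell and topographic
prominence ≥ 10 Hz/cell (prominence to the higher of the two flanking
minima, each flank extending to the nearest sample exceeding the peak or the
trace edge; between equal peaks the earlier one takes the full prominence).
An independent brute-force prominence oracle in the test suite checks the
implementation on random traces.

`shutdown_dose()` measures opioid sensitivity: for each amplitude threshold
in {10, …, 15} Hz/cell, find the last burst at or above it and read
`I_hyp_op` at its peak time off the ramp; the dose is the mean over reached
thresholds (unreached ones are dropped with a warning; if none is reached
the dose is undefined and an error is raised rather than a made-up value).

## Intrinsic classification

The label rule under synaptic block (window 60 s after a discarded 10 s
transient): **silent** with fewer than 3 spikes; otherwise **bursting** if
the inter-spike intervals are grouped (max ISI > 5× median ISI and at least
two groups separated by gaps > 1 s); otherwise **tonic**. The thresholds
match the canonical appearance of persistent-sodium bursting here —
intra-burst ISIs of tens of ms against inter-burst intervals of seconds
(the slow inactivation time constant is 10 s) — and are all configurable.
The 60 s window covers at least three cycles of the slowest plausible burst
period; a stability test checks that ≥ 98% of labels are unchanged when the
window doubles.

**Composition percentages are reported over the excitatory population.**
Only excitatory neurons can be MOR+, so it is the MOR-eligible population
whose composition opioid can move; inhibitory neurons draw their
conductances from the same distributions and so have the same expected
composition, which makes control-condition percentages equal under either
denominator. For opioid conditions the two denominators differ mechanically
(MOR+ is 50% of excitatory neurons but only 40% of all neurons), and only
the excitatory denominator can express near-complete silencing under
targeted MOR assignment. `intrinsic_composition(..., over = "all")` gives
the whole-network version.

## Topology analysis

`subgroup_connection_counts()` tabulates directed edges between groups under
three partitions (E/I; MOR+/MOR−/I; tonic/bursting/silent × MOR±, plus I),
and `connectivity_dose_correlation()` correlates each count with per-network
shutdown dose (Pearson r, two-tailed p on n − 2 df). Intrinsic labels for
the partition default to control-condition classification. No
multiple-testing correction is applied across the grid of cells; the output
is per-cell and flagged as such.

## Experiments and problem sizes

`run_experiment()` orchestrates the batch designs (ramp batches, the
high/low sensitivity split, density sweeps, topology correlations, MOR
policies, the g_NaP/g_leak rescue protocols, and phase diagrams) from an
`experiment_config()`; `scripts/run_experiment.R` is the command-line
wrapper. Full-length study batches (40 networks × 600 s ramps) are hours of
CPU; the package's own test suite therefore runs scaled-down versions —
single-network live ramps, 10-network precomputed dose batches
(`tools/precompute_batches.R`, tables shipped as CSV with their seeds), and
15–60 s classification windows for orchestration tests — sizes chosen so the
distributional claims remain testable while a routine check stays fast.

## What the generator emulates, and limitations

The network builder is the data generator for the whole pipeline: it
reproduces the study's stated composition (300 neurons, 240/60 E/I, 120
MOR+), connectivity (directed Erdős–Rényi at ~1% density) and conductance
heterogeneity (the mixture above). It does not emulate spatial structure,
distance-dependent or small-world connectivity, synaptic plasticity or
depression, channel noise, calcium dynamics, or sensory/state-dependent
drive — so passing tests show that the *model* behaves as specified, not
that real preBötC slices do.

Two caveats deserve emphasis. First, with the shared parameter table as
printed, the tonic/silent boundary at g_NaP ≈ 0.8 nS sits near g_leak ≈
1.05–1.1 nS, which places more of the high-leak mixture component in the
silent regime than the in-vitro-motivated design intends; the control
tonic/silent split is correspondingly tilted toward silent (the bursting
fraction, 5–10%, is unaffected). Second, emergent network quantities
(shutdown doses in particular) depend on the calibrated baseline synaptic
strength; they are reproducible given the package defaults but should be
read as model-internal measurements, not slice predictions.
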