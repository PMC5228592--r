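---
title: "Model and methods: a spiking basal-ganglia network for action selection and dopamine-depleted dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`bgnet` is a clock-driven spiking model of the rodent basal ganglia (BG):
the two striatal projection-neuron populations (MSN D1, MSN D2), striatal
fast-spiking interneurons (FSN), the subthalamic nucleus (STN), the two
external-pallidum subtypes (arkypallidal GPe TA and prototypical GPe TI) and
the output nucleus (SNr). It is built to study two linked phenomena: how
tonic dopamine loss (a 6-OHDA lesion model of parkinsonism) reshapes
population synchrony, beta-band (15--25 Hz) oscillations and their phase
structure across the STN--GPe network, and how well the circuit transfers
cortical "action" commands to its output under normal and depleted
conditions.

# Neuron models

Two hybrid point-neuron families are used, each with one fast voltage
variable and one slow recovery/adaptation current.

**Striatal neurons** (MSN D1, MSN D2, FSN) follow the quadratic
integrate-and-fire model with adaptation,

$$C\dot V = k(V-v_r)(V-v_{th}) - u + I,\qquad
\dot u = a\,[\,b\,(V-v_r) - u\,],$$

with reset $V \leftarrow c$, $u \leftarrow u + d$ when $V$ crosses
$v_{peak}$. The FSN variant replaces the recovery law by a cubic below a
kink voltage $v_b$ ($\dot u = a[b(V-v_b)^3-u]$ for $V \le v_b$, otherwise
$\dot u = -a u$), which gives the characteristic type-2, abrupt onset of
fast spiking. The printed unit of the rate constant `a` ("s") is read as a
rate in 1/ms (0.2 and 0.01), the canonical values for these published
parameter sets; with a literal reading the models lose their signature
dynamics. The D2-type cell is slightly more excitable (smaller
capacitance-effective surface, larger spike-triggered increment
$d = 91$ pA vs 66.9 pA).

**Pallidal, nigral and subthalamic neurons** follow the adaptive
exponential integrate-and-fire model,

$$C\dot V = -g_L(V-E_L) + g_L\Delta_T e^{(V-V_T)/\Delta_T} - w + I,\qquad
\tau_w\dot w = a(V-E_L) - w,$$

with reset $V \leftarrow V_r$, $w \leftarrow w + b$. GPe TA cells are the
TI set with $C$, $\Delta_T$ and $b$ at 150%, flattening their f--I curve;
the bias currents $I_e$ = 1 and 12 pA calibrate the in-vitro rates of 8 and
18 Hz. Two subtleties we found while validating:

* The TA model is *bistable* at its bias current: started from rest it
  settles on a silent fixed point, while from the post-spike state it
  pacemakes at 8 Hz. `fi_curve()` therefore starts from the post-spike
  state by default, measuring sustained firing.
* The STN adaptation conductance acts only below a $-70$ mV gate, and the
  rebound-burst reset ($V \leftarrow V_r + \max(w-15, 20)$ when $w<0$ at
  spike time) fires only after hyperpolarisation below $E_L = -80.2$ mV,
  where $w$ can become negative. Because the depolarised reset constant
  dominates ($w<0$ makes the max always 20), the expression is implemented
  literally, with a `rule = "min"` hook for the alternative reading. The
  burst is validated in the 100 ms following the *first* post-release
  spike: the first spike itself arrives about 124 ms after release (the
  model crawls slowly through its quasi-threshold region at $I_e$), so a
  window anchored at release would see no spikes under either reset rule.

Heterogeneity: capacitance is sampled per cell with a 10% coefficient of
variation (resampled if non-positive) and spike thresholds with a 1-mV
standard deviation.

# Synapses

Static synapses are conductance-based with exponential decay; each
presynaptic spike adds $g_0$ after the axonal delay, and
$I = g(E_{rev}-V)$. NMDA receptors are additionally gated by the standard
magnesium block $B(V) = [1 + ([\mathrm{Mg}]/3.57)\,e^{-0.062 V}]^{-1}$ with
$V$ in mV. At $-80$ mV and 1 mM magnesium only ~2.4% of the NMDA
conductance is unblocked; this canonical form is essential — treating the
voltage constant as "per volt" leaves NMDA unblocked at rest and drives
the D1 cells an order of magnitude above their in-vivo range. Magnesium
concentration (not stated in the source tables) defaults to the standard
physiological 1 mM and is configurable.

Short-term plasticity uses the Tsodyks--Markram three-pool formalism
(recovered $x$, active $y$, inactive $z$; utilisation $u$ incremented by
$U(1-u)$ at each spike *before* release $r = u\,x$, so a first spike from
rest releases exactly $U$). The postsynaptic conductance is $g_0\,y$,
exactly as the model equations state; we evaluated and rejected the
alternative utilisation-normalised convention ($A = g_0/U$), which
collapses the output nucleus to ~2 Hz through the very strong pallido-nigral
synapse. $\tau_{fac} = 0$ rows mean no facilitation ($u$ returns to $U$ at
every spike). Between events all synapse states relax by exact closed-form
exponentials, evaluated lazily at event times — there is no per-step
synapse integration error.

# Dopamine

Tonic dopamine is a receptor-occupancy scalar $\alpha \in [0,1]$ with
reference $\alpha_0 = 0.8$; every modulated parameter scales as
$p \leftarrow p\,[1 + \beta(\alpha - \alpha_0)]$. The catalogue of $\beta$
coefficients covers synaptic and drive conductances, two striatal fan-ins
(MSN collaterals, FSN onto D2 cells) and five neuron parameters. Each
$\beta$ is re-derivable from its experimental constraint with
`solve_beta_from_ratio()` / `solve_beta_from_shift()`; the catalogue keeps
the printed value where the printed constraint is inconsistent with it
(cortex to STN), and notes the one row whose printed label duplicates
another (the arkypallidal synapse onto D2 cells). Fan-ins are rounded
half-up with floor 0 after scaling. `apply_depletion()` is pure
(returns a modified copy) and supports one-parameter *restoration*, the
basis of the restoration sweeps.

# Network construction

Population sizes are fixed proportions of the requested total, anchored at
the 80,000-neuron census. Connectivity is specified as exact in-degrees
(fan-ins); every postsynaptic cell draws its presynaptic partners uniformly
without replacement. Striatal collaterals and FSN feed-forward inhibition
are restricted to index-ring neighbourhoods of 2800 and 540 cells (the
source material specifies neighbourhood cardinality only, not geometry,
so a 1-D ring is used). Scaled-down networks keep *absolute* fan-ins, so
per-neuron input counts match the full model; when a pool is smaller than
a fan-in the build caps it with a loud warning rather than resampling
silently. One in ten prototypical cells projects back to striatal
interneurons. Action channels are embedded by partitioning the output
nucleus (and, with the indirect pathway, the prototypical cells) into
per-action blocks and restricting the pathway connections so Go pools
reach their own action's output pool and NoGo pools reach their action's
pallidal pool.

# Extrinsic drives and protocols

Each population receives an independent Poisson drive per neuron at the
catalogued rate, entering through one static synapse (AMPA, plus NMDA for
cortical drives to MSN and STN). Square-wave rate modulation
($v(1\pm a)$ every half cycle) implements the slow-wave (1 Hz, both
dopamine conditions) and beta (20 Hz, depleted condition only) cortical
regimes. Because a time-shifted Poisson process is statistically
identical, the axonal delay of a generated drive is unobservable and is
dropped; the delay *sweeps* are implemented as modulation phase lags,
which is the only observable consequence of a cortical delay here.

Selection trials are 100-ms bursts (multiplicative factors 1--3 on the
channelised striatal drives) followed by 900-ms rests; an action counts as
selected when its SNr pool rate during the burst falls below 50% of the
control model's baseline. The protocol bursts the Go pool of the commanded
action and the NoGo pool of the competing action. The interneuron co-burst
is off by default: with the catalogued depressing feed-forward synapses it
acts mostly as a global brake on D2 cells, disinhibiting both pallidal
pools and masking the channel contrast; the hyperdirect (STN) burst is its
own arm (`stn_stop_pulse()`), matching how the source treats it.

# Numerics

The engine advances all neurons with forward Euler at a fixed step
(default 0.1 ms); spikes are detected at step end and delivered through
per-connection ring buffers after delays rounded to the step grid (all
catalogued delays are representable). Exponential overflow in the adaptive
exponential model is clamped by declaring a spike. Conductance decay is
exact per step. Random streams (drive realisations, initial-state jitter)
are split deterministically from the master seed, so adding probes never
perturbs dynamics and identical seeds give bit-identical records. Initial
voltages are jittered ±5 mV to break startup synchrony. Halving the step
to 0.05 ms changes population rates of a ~3000-neuron striatal module by
under 2%.

# Analysis

Spike trains are binned at 256 Hz (1000/256 ms bins). Synchrony is the
population Fano factor (variance over mean of the summed count per bin,
population form). The oscillation index is the 15--25 Hz share of spectral
power, from Welch-averaged Hanning periodograms of per-neuron,
mean-subtracted binned trains averaged over neurons; window lengths of 256
and 2048 samples give the 1-Hz and 0.125-Hz resolutions appropriate for
beta and slow-wave work (the printed "128 and 2048 ms" conflicts with the
stated resolutions; the resolutions win). Coherence uses disjoint Hanning
segments with the $1-(1-p)^{1/(L-1)}$ significance level for $L$ segments;
network-level checks read the coherence at the 20-Hz bin of the most
active unit pairs, since a band-maximum statistic is biased upward under
the null. Phase relations band-pass the binned trains with a zero-phase
Butterworth filter (0.5--1.5 or 15--25 Hz), take instantaneous phases from
the analytic signal, and histogram the pointwise difference in 100 bins
over $[-\pi,\pi)$; circular means near 0 / $\pm\pi$ are read as in-phase /
antiphase with $\pi/2$ as the dichotomy boundary.

# Study conditions and scale

The experiment drivers default to desk-scale networks that keep the full
fan-in structure: dynamics validation at $N = 10{,}000$, striatal
inhibition studies at $N \approx 3160$ (the smallest module holding the
collateral connection statistics, ~3000 projection neurons), selection
experiments at $N = 10{,}000$, and sweeps at $N = 6000$; runs of 3--9
simulated seconds with a 0.5--1 s discarded transient. These sizes are the
package's validated operating points; population-level beta structure,
phase relations and selection orderings are stable there, while
quantities that need long single-unit spike counts (unit-pair coherence of
sparse populations) are noisier than in the 80,000-neuron original.

# What the synthetic conditions do and do not show

All inputs are parameter tables plus seeded Poisson drives; there is no
recorded data in the loop. The drives emulate mean cortical/thalamic rates
and their square-wave modulation but not correlated cortical ensembles,
so single-unit spiking is more regular (lower ISI CV) than in vivo;
consequences are documented where they matter (unit-level oscillation
indices of regular pacemakers understate entrainment that is clearly
present at the population level). Passing tests demonstrate internal
consistency of the model and reproduction of the qualitative network
phenomena — depletion-induced beta coherence and its phase structure, the
inhibition hierarchy in striatum, selection contrast and its failure
modes — not quantitative agreement with any particular recording.

# Known limitations

* The FSN population runs near 100 Hz under the catalogued activation
  drive; the printed drive/synapse combination delivers several times the
  current the model needs for its stated 10--20 Hz range, and no
  catalogued inhibition can close the gap. The model is kept faithful to
  its tables, and the discrepancy is asserted openly in the tests.
* GPe TI collapses to ~2 Hz in the fully depleted state at desk scale;
  rate *orderings* (TI below TA when depleted, above when intact) still
  hold.
* Learning of corticostriatal weights, thalamo-cortical feedback and
  phasic dopamine signalling are out of scope.
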