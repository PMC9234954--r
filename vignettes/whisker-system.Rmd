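---
title: "Model and methods: the whiskersim closed-loop simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: the whiskersim closed-loop simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`whiskersim` simulates the peripheral rodent whisker system — trigeminal
ganglion (TG) afferents, trigeminal nuclei (TN), facial nuclei (FN) and a
central pattern generator (CPG) — in closed loop with a simple whisker
plant, and couples it to an adaptive cerebellar microcircuit that learns a
GO/NOGO object-localization task. This vignette documents the model, the
parameters that matter, the numerical choices, and the design decisions
taken where the architecture left them open.

## 1. Neuron and synapse model

All simulated cells are leaky integrate-and-fire point neurons with exact
exponential integration at a fixed 0.1 ms step:

$$V(t+\Delta t) = V_\infty + (V(t) - V_\infty)\,e^{-\Delta t/\tau_m},$$

where $V_\infty$ is the resting potential plus any tonic bias. Synapses are
delta-current kicks: a presynaptic spike deflects the target membrane by the
synaptic weight (in mV), after the projection delay; inhibitory weights are
negative. Defaults: $\tau_m = 10$ ms, $V_\text{rest} = V_\text{reset} =
-70$ mV, threshold $-55$ mV, refractory period 2 ms (inputs arriving during
refractoriness are discarded; the earliest next spike is one step after the
refractory period). Spikes are evaluated after input application in each
step; simultaneous spikes across neurons are allowed. These parameter values
are not constrained by the modelled system; they are standard point-neuron
settings, and every behavioural result below is produced by weight
calibration on top of them rather than by tuning them. The engine refuses
non-finite membrane potentials, delays shorter than the step, and thresholds
at or below reset.

Some populations are *generators*: they do not integrate, and their spikes
are produced by the sensory encoders or protocol code and injected into the
network (TG cells, TN phase cells, CPG, inferior olive).

## 2. Whisker plant

The four whiskers (L0/R0: 50 cm, 11° roll; L1/R1: 25 cm, 22° roll; 1 cm
diameter) are modelled as independent 1-DOF torque-driven rotational joints,

$$I\ddot\theta = \tau - c\dot\theta - k(\theta - \theta_\text{rest}),$$

integrated semi-implicitly at 0.1 ms. Defaults $I = 8\times10^{-5}$ kg m²,
$c = 2.5\times10^{-3}$ N m s/rad, $k = 2\times10^{-2}$ N m/rad were
calibrated once so that the default motor drive produces a clear 4 Hz
protraction–retraction cycle with a free amplitude of roughly 20°; the
amplitude itself is an emergent quantity and not a validated target.

A vertical bar is a hard angular stop at a configured protraction angle
(default 15°) on one side. Impacts faster than `stick_velocity` bounce with
restitution 0.4; slower ones stick. Two kinds of contact signal are
produced, reflecting the two kinds of mechanoreceptive afferent:

* **micro-impact events** — every free→clamped transition at the stop.
  These drive the rapidly adapting contact cells, and through them the
  trigeminal reflex; a bouncing whisker generates a stream of them, which is
  exactly the noisy contact signal the reflex is there to debounce.
* **the debounced `in_contact` flag** — engaged at the first clamp and
  released only when the whisker retreats more than `release_margin`
  (default 4°) below the stop, a stand-in for tip compliance. Pressure
  cells, detach cells and the contact-distance report follow this flag.

The contact distance is the bar's radial placement (default 10 cm, constant
during a contact): the plant has no force variable, so proximity is the
only spatial quantity a contact carries.

## 3. Sensory encoders

Per whisker, 100 TG cells in five classes of 20 (sampling at 1 ms):

| class | code | default |
|---|---|---|
| contact | 1 spike/cell per micro-impact, ≤ 1 ms jitter | — |
| detach | 1 spike/cell per debounced offset, ≤ 1 ms jitter | — |
| pressure | Poisson-like tonic while in contact | 27 Hz |
| high-threshold | fixed-rate iff contact distance < 2 cm (strict) | 50 Hz |
| whisking | inhomogeneous Poisson, Gaussian tuning over angle | peak 30 Hz |

The whisking grid spans rest − 5° to rest + 30° (the calibrated motion
range) with tuning width equal to the grid spacing; the peak rate was set
once so that the trial-mean whisking rate lands near 4 Hz. Because contact
in the plant is binary, the pressure response is a fixed rate rather than
force-dependent; 27 Hz was chosen to sit in the middle of the plausible
tonic range. At the default bar distance the high-threshold cells never
fire; placing the bar closer than 2 cm activates them.

The TN phase decoder is implemented as a deterministic gating transfer
function rather than as synapses: phase cell *i* copies whisking cell *i*'s
spikes whenever the same whisker's pressure population fired within the
trailing 10 ms (matching the system-wide 10 ms binning). Gating can only
delete spikes, so the phase output is always a subset of the whisking
spike set.

## 4. Motor pathway and reflex

The CPG emits strictly periodic spikes at 4 Hz (first spike at one period).
CPG→FN weights are suprathreshold, so each CPG spike elicits exactly one
spike in every protractor (1 ms delay) and every retractor (50 ms delay):
the free-whisking FN mean rate equals the CPG rate by construction, and the
49 ms volley lag produces protraction followed by retraction. Rates are
decoded into torques per whisker with the printed gains
($1.5\times10^{-3}$ / $1.0\times10^{-3}$ N m/Hz) on 10 ms bins with
zero-order hold — torque follows spikes with a bin of latency, as in any
rate-decoded interface.

Each whisker's 20 contact cells converge on one TN contact relay neuron,
which excites that whisker's 20 protractors at 7.5 ms and inhibits its
side's 20 retractors. In closed loop this yields a self-sustaining hold:
impact → TN volley → protraction push → re-impact, while retraction is
suppressed — the whisker stays pressed against the bar and the debounced
contact flag stays contiguous (the suite checks ≤ 2 flag transitions per
protraction cycle with the reflex, and strictly more when the reflex
projections are ablated).

## 5. Cerebellar module

Populations: 100 MF, 2,000 GrC, 72 PC, 72 IO, 36 DCN. Projections (exact
synapse counts under the defaults): pressure→MF 80 and phase→MF 80 (seeded
injective one-to-one maps; with 160 sources into 100 targets at least 60
MFs receive both), MF→GrC 8,000 (convergence 4), PF→PC 115,200
(convergence 1,600, plastic), IO→PC 72 one-to-one *teaching* (no current —
verified by the suite: ablating them changes no membrane trajectory),
MF→DCN 3,600, PC→DCN 72 (each PC inhibits exactly one DCN, each DCN gets
two PCs). Sampling is without replacement per target with at most one
synapse per cell pair.

Calibration choices, each exposed in `cerebellum_spec()`:

* **MF relay** (20 mV): one afferent spike, one MF spike.
* **MF→GrC** (8.5 mV): a granule cell needs two near-coincident active
  mossy inputs to fire, giving sparse combinatorial recoding (with one
  whisker's pressure cells active, the active GrC fraction stays below the
  active MF fraction).
* **PC tonic bias** (~50 Hz simple-spike rate): the plasticity rule is
  evaluated at PC spikes, and PF→PC weights start fully depressed, so
  without background Purkinje activity no synapse could ever change. Tonic
  simple-spike firing is a basic Purkinje property; the bias also makes the
  PC population a graded readout of PF drive.
* **MF→DCN** (2.6 mV) and **PC→DCN** (−10 mV): set so that with naive
  (zero) PF→PC weights any sustained contact drives the DCN population
  above the 80 Hz response threshold despite baseline Purkinje inhibition,
  while the Purkinje rate increase produced by potentiated parallel fibers
  is sufficient to hold it below threshold.

A response is latched at most once per trial, at the first 10 ms bin whose
DCN population rate strictly exceeds 80 Hz.

## 6. Plasticity

The PF→PC rule is event-based, evaluated at every PC spike $t$:

* if an IO spike for that cell lies within the coincidence window —
  $\Delta w_i = \text{LTD}\cdot\sum_{s \in \text{PF}_i,\; t-W \le s \le t}
  K(t-s)$ (depression weighted by the eligibility kernel);
* otherwise — $\Delta w_i = \text{LTP}$ for every PF active within the
  coincidence window of $t$.

Constants: LTP 0.01 (0.001 under the L7-PP2B genotype), LTD −0.03, bounds
[0, 1], integration window $W = 300$ ms. The kernel is the single
non-negative lobe of $e^{-u/\tau_K}\sin(\pi u/L)^{20}$, shifted and scaled
numerically (0.01 ms grid) so its argmax sits exactly $t_0 = 100$ ms before
the evaluation time with maximum 1. As written, the unshifted expression
vanishes at its own nominal peak, so the normalization treats the described
behaviour — maximal depression of inputs 100 ms in the past — as the
contract and the formula as the lobe shape. Lobe width $L$ defaults to
100 ms and decay $\tau_K$ to 50 ms.

Two rule-level decisions required deviation from the minimal reading:

* **Coincidence window 5 ms** (not one step). With a strict equality
  $t = t_\text{IO}$ the depression branch essentially never fires for a
  tonic Purkinje cell, leaving the rule potentiation-only.
* **Reward as an IO burst** (default 60 spikes at 5 ms spacing) rather
  than a single spike. With the LTP/LTD constants fixed, a single IO spike
  per rewarded trial produces an order of magnitude less total depression
  than the potentiation accumulated over one second of contact — the
  rewarded pathway would potentiate almost as fast as the unrewarded one
  and GO responses would eventually be suppressed. The burst (a stand-in
  for climbing-fiber complex-spike volleys and sustained IO reward
  signalling) makes total per-trial depression commensurate with per-trial
  potentiation; burst size and spacing are configuration values.

The event-driven engine implementation is checked to $10^{-12}$ against a
dense-time reference that recomputes the LTD integral from the full spike
trains, and against the exported R rule (`on_pc_spike()`) replayed on the
engine's own rasters.

## 7. Task, learning dynamics, and what the tests show

Trials last 2 s with the bar present for the first second (left for GO,
right for NOGO); the response window spans the whole trial, since no
narrower start is defined for it. Sessions hold 5 GO and 5 NOGO trials in a
seeded random order; the full protocol is 27 sessions (270 trials). Between
trials the plant and all membrane states are reset but synaptic weights
persist; nothing is reset between sessions. The master seed fans out to
separate substreams for wiring, per-trial encoder sampling and schedules,
so identical seeds give bit-identical runs and paired genotype comparisons
differ only in the LTP constant.

The learning logic is side-separation: left and right contacts activate
largely disjoint mossy-fiber and granule ensembles. NOGO (right) synapses
receive only potentiation, eventually raising Purkinje firing during right
contacts enough to silence the DCN — false alarms fall. GO (left) synapses
receive the same potentiation but also reward-gated depression, which pins
them low — hits persist. The knock-out potentiates ten times slower and
cannot reach suppression within the scaled protocol.

The test suite runs this experiment at a reduced size — 10 sessions × 10
trials × 5 paired seeds per genotype — and asserts the qualitative
contract: both genotypes start ≥ 80% on hits *and* false alarms, the
control's late-session false alarms are lower than its early ones and lower
than the knock-out's, and hits stay ≥ 80% throughout for both. The full
27-session protocol is available through `make_protocol()` /
`compare_genotypes()` defaults.

What passing these tests does *not* show: the plant is a linear joint with
a hard stop, so no whisker bending, resonance, texture or force coding; the
pressure "force" response is a constant rate; exact published learning-curve
values are not targets (they depend on platform physics and
figure-resolution data); and peak FN bin rates here reach the 100 Hz
quantization ceiling because the single-spike-per-cycle calibration makes
FN volleys synchronous, rather than the sub-ceiling peaks a jittered
implementation would show.

## 8. Numerical and bookkeeping details

* Rates are spike counts per 10 ms bin normalized by population size; with
  20 cells the quantum is 5 Hz (0–100 Hz for one-spike-per-cell bins).
* Encoder sampling runs at 1 ms (rates are far below 1 kHz, so thinning
  bias is negligible); contact/detach bursts use the plant's exact event
  times; the engine runs at 0.1 ms.
* Projection delays are rounded to whole steps and must be ≥ one step.
* Purkinje membrane phases are randomized per trial (uniform between reset
  and threshold) to desynchronize the tonic population.
* Rasters are two-column text (`gid time_ms`) with a JSON population map;
  kinematics, torques, rate traces and session metrics are CSV; the
  resolved configuration of any run can be written as a YAML manifest.
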