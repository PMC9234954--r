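# whiskersim

A closed-loop spiking neural network simulator of the rodent whisker
sensorimotor system with an adaptive cerebellar controller.

Rodents localize objects by rhythmically sweeping their whiskers
(protraction–retraction "whisking") and reading out when and where a whisker
touches something. `whiskersim` implements the peripheral circuits of that
system as populations of leaky integrate-and-fire (LIF) neurons in a
clock-driven engine (0.1 ms steps), couples them to a lightweight
torque-driven whisker plant, and wires the sensory stream into a cerebellar
microcircuit whose parallel fiber → Purkinje cell (PF→PC) synapses learn
under a supervised spike-timing rule. The package is aimed at computational
neuroscientists who want an in-process, scriptable stand-in for a
robotics-platform implementation of the same architecture: every population,
projection, weight and protocol parameter is exposed in one configuration
list, and all simulation outputs are plain-text rasters and CSV tables.

## The model in brief

**Motor pathway.** A single central pattern generator (CPG) neuron fires at
4 Hz and drives 80 facial-nucleus protractors (1 ms delay) and 40 retractors
(50 ms delay), one spike per cell per cycle. Population rates `FR` (spikes
per 10 ms bin, normalized by population size) are decoded into joint torques

```
torque(t) = α_pro · FR_pro(t) − α_ret · FR_ret(t)
```

with α_pro = 1.5·10⁻³ N·m/Hz and α_ret = 1.0·10⁻³ N·m/Hz.

**Sensory pathway.** Each of the four whiskers (L0, L1, R0, R1) is
innervated by 100 trigeminal-ganglion (TG) cells in five labeled-line
classes of 20: contact (burst at contact onset), detach (burst at offset),
pressure (tonic ~27 Hz during contact), high-threshold (active only for
contacts < 2 cm from the snout) and whisking cells (Gaussian angular tuning,
mean rate ~4 Hz). Trigeminal-nucleus (TN) contact neurons (one per whisker)
relay contact volleys back onto the facial nuclei — excitation of
protractors at 7.5 ms, inhibition of retractors — a reflex that presses a
colliding whisker against the object and debounces the contact signal. A TN
phase decoder gates each whisking cell with the same whisker's pressure
activity (logical AND), yielding a labeled-line code of the contact phase.

**Cerebellum.** TG pressure and TN phase cells map one-to-one onto 100
mossy fibers; 2,000 granule cells recode them sparsely (convergence 4);
72 Purkinje cells each sample 1,600 parallel fibers (115,200 plastic
synapses); 36 deep-cerebellar-nuclei (DCN) neurons integrate mossy-fiber
excitation against Purkinje inhibition. A behavioural response is detected
when the DCN population rate exceeds 80 Hz. Rewarded responses trigger an
inferior-olive burst; at every Purkinje spike coincident with an IO spike,
each PF synapse is depressed by `LTD · Σ K(t − t_PF)` where the eligibility
kernel K peaks 100 ms in the past, and otherwise every recently active PF is
potentiated by a fixed step (`LTP = 0.01`, `LTD = −0.03`). The L7-PP2B
knock-out genotype reduces LTP tenfold (0.001).

**Task.** GO/NOGO object localization: a vertical bar appears for 1 s in
the left (GO) or right (NOGO) whisker field during 2 s trials; sessions
hold 5 GO + 5 NOGO trials in random order. Hit rate and false-alarm rate
are recorded per session.

## Worked example

```r
library(whiskersim)

# 10 s of free whisking
sys <- build_whisker_system(default_config(), seed = 1)
fw  <- run_free_whisking(sys, duration = 10000, seed = 1)
nrow(spikes_of(fw$spikes, sys$motor$cpg)) / 10   # CPG rate (Hz)
#> [1] 4

# a scaled learning experiment: 10 sessions x 10 trials, control genotype
m <- run_experiment(make_protocol(10, 10, "control", seed = 1))
m$false_alarm_rate
#> [1] 100  60  20  20   0   0   0   0   0   0
m$hit_rate
#> [1] 100 100 100 100 100 100 100 100 100 100
```

The false-alarm trajectory shows the cerebellar learning: a naive network
responds to every bar contact (session 1: hits and false alarms both 100%),
then potentiation of the parallel fibers carrying the unrewarded (right
side) contact pattern raises Purkinje firing during NOGO trials, silencing
the DCN and suppressing the response, while the rewarded GO pathway is held
down by IO-gated depression — hits stay at 100%. Running the same protocol
with `"l7pp2b"` leaves false alarms near 100% across these sessions: with
LTP at a tenth, the impaired genotype cannot build up the NOGO-side
suppression in this many trials.

A command-line front end wrapping these calls lives at
`inst/cli/whiskersim.R` (`build-check`, `free-whisk`, `run-trial`,
`run-experiment`, `compare`).

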