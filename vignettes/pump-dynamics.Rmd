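---
title: "A sodium-pump motoneuron model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A sodium-pump motoneuron model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`pumpneuron` simulates a single-compartment, conductance-based model of a
*Drosophila* larval motoneuron whose distinguishing feature is an
electrogenic Na/K-ATPase pump coupled to a dynamic intracellular sodium
concentration and, optionally, a dynamic sodium reversal potential. The
membrane potential obeys

$$C\,\frac{dV}{dt} = -\bigl(I_{NaT} + I_{NaP} + I_{Naleak} + I_{Kf} +
I_{Ks} + I_{Kleak} + I_{pump} - I_{inj}\bigr),$$

with a transient sodium current $I_{NaT} = g_{NaT} m_{NaT}^3 h_{NaT}
(V - E_{Na})$, a persistent sodium current $I_{NaP} = g_{NaP} m_{NaP}
(V - E_{Na})$, sodium and potassium leaks, a fast potassium current with
two inactivation components ($I_{Kf} = g_{Kf} m_{Kf}^4 (0.95 h_{Kf1} +
0.05 h_{Kf2})(V - E_K)$), and a slow potassium current $I_{Ks} = g_{Ks}
n_{Ks}^4 (V - E_K)$. Every gating variable relaxes to a Boltzmann steady
state with a sigmoid voltage-dependent time constant
(`gating_kinetics()`); two time constants are fixed (1 ms for $m_{NaP}$,
116 ms for $h_{Kf2}$).

The pump current is an instantaneous sigmoid function of intracellular
sodium,

$$I_{pump} = \frac{I_{pumpmax}}{1 + \exp\bigl((NaH - [Na^+]_i)/NaS\bigr)},$$

with defaults $I_{pumpmax} = 75$ pA, $NaH = 40$ mM, $NaS = 10$ mM: at the
resting concentration of 40.08 mM the pump sits almost exactly at half
activation (37.65 pA). Sodium in a thin shell under the membrane
(volume 0.549 pL) evolves as

$$\frac{d[Na^+]_i}{dt} = -\frac{I_{NaT} + I_{NaP} + I_{Naleak} +
3 I_{pump}}{F \cdot Vol},$$

the factor 3 reflecting three sodium ions extruded per elementary charge
of net pump current. The sodium reversal potential follows the Nernst
equation at 25 °C, $E_{Na} = (RT/F)\ln([Na^+]_o/[Na^+]_i)$ with
$[Na^+]_o = 135$ mM fixed.

Two switches define three variants (`variant_preset()`): **ConCon**
(concentration and reversal both frozen at their resting values 40.08 mM
and 31.2 mV), **DynCon** (dynamic concentration, frozen reversal) and
**DynDyn** (both dynamic). The fourth combination — a dynamic reversal
with a frozen concentration — is physically meaningless and the
constructor rejects it. All three variants share the same resting state
by construction: the frozen values are the values the DynDyn variant
relaxes to, which is why their responses only diverge after a
perturbation.

### Units and numerical constants

All computation uses (mV, ms, nS, pA, pF, mM, pL). In this system
nS·mV = pA and pA/pF = mV/ms hold identically, so the voltage equation
needs no conversion factor; the sodium balance uses the single constant
$1/(F \cdot Vol) \approx 1.888\times 10^{-5}$ mM/(pA·ms). The thermal
voltage is taken as $RT/F = 25.693$ mV at $T = 298.15$ K with the natural
logarithm — this choice is validated by an internal consistency check:
the Nernst potential of the resting concentration (40.08 mM) must equal
the frozen resting reversal (31.2 mV) to within 0.05 mV, and
`sodium_environment()` enforces it at construction.

### A note on the conductance of the fast potassium current

In the source description of this model the fast-K current is written
with the slow-K conductance symbol while a separate fast-K conductance
(15.1 nS) is defined but then never used. We treat this as a typo and use
the fast-K conductance for $I_{Kf}$; the alternative would leave a
defined parameter dead and make two distinct currents share one
conductance. We verified numerically that the choice barely affects any
reported quantity: $m_{Kf}$ activates only near spike peaks, so
$I_{Kf}$ contributes a brief repolarizing pulse whose exact amplitude has
little influence on rates, sodium loading, or AHPs.

## Integration

The reference integrator is `deSolve`'s `lsoda` — adaptive-step and
stiffness-switching — with absolute tolerance 1.49012e-8 and relative
tolerance 1e-10 (note the absolute tolerance is the larger of the two;
the defaults keep that assignment deliberately). The right-hand side is
compiled C for speed; an identical pure-R implementation
(`state_derivative()`) is exported and the two are cross-checked on
random states in the test suite. A fixed-step classical Runge-Kutta
integrator over the same compiled right-hand side (`method = "rk4"`,
default step 1 µs over short windows) serves as an independent
cross-validation oracle: adaptive and fixed-step solutions of a spiking
2-second response agree to better than 0.1 mV everywhere except within
1 ms of spike peaks, where infinitesimal spike-time shifts dominate the
pointwise difference.

Stimulus discontinuities (step onsets/offsets, ramp turning points, the
zap midpoint) are solver breakpoints: the integrator is restarted at each
one, so edges are never smeared by interpolation. Stimulus windows are
half-open $[t_{on}, t_{off})$ — the sample at the offset carries 0 pA —
which makes charge accounting unambiguous. The internal step is capped at
1 ms so the adaptive solver cannot step across a narrow spike; the output
grid (default 0.05 ms) only samples the solution and demonstrably does
not influence it.

### Rest-state determination

`find_rest()` relaxes the model for 200 simulated seconds with no
stimulus from a cold start (gating at steady state for −60 mV, sodium at
its reference 40.08 mM), then polishes the endpoint with damped Newton
iterations on the full right-hand side, and verifies that every state
derivative is below 1e-7 in natural units. Relaxation-then-polish was
chosen over root finding alone because some pump parameter regimes are
multistable or endogenously oscillatory; a root finder can converge to an
unstable fixed point that the physical system never visits. When the
relaxation tail still shows voltage excursions above 1 mV the function
reports *no stable rest* (`converged = FALSE`) instead of returning a
spurious fixed point — this is the expected outcome for endogenous
bursters, not an error.

## Stimulus protocols

* **Step**: rectangular pulse, the work-horse for FI curves, adaptation
  and AHP measurements (default 5 s duration).
* **Ramp**: bidirectional piecewise-linear 0 → peak → 0 (default peak
  70 pA), at total durations of 2, 10 and 40 s; slower ramps give the
  pump more time to integrate sodium load, which is what the rate
  hysteresis measures.
* **Zap**: a sinusoidal current whose frequency sweeps exponentially
  from 0.1 Hz to 5 Hz over 20 s and back. The printed closed form of the
  sweep frequency is typographically ambiguous; we read it as
  $f_{zap}(t) = f_0\,(e^{\lambda t}-1)/(\lambda t)$, the unique reading
  for which $2\pi f_{zap} t$ is the integrated phase of the instantaneous
  exponential sweep $f_0 e^{\lambda t}$, which reaches exactly
  $f_{max}$ at $\tau_{half}$ given $\lambda = \ln(f_{max}/f_0)/\tau_{half}$.
  The deceleration half is implemented as the exact time mirror of the
  acceleration current waveform, so $I(t) = I(2\tau_{half} - t)$ to
  machine precision — the response-symmetry analyses rely on this.
* **Memory protocol**: a 22 pA/200 ms test pulse, a gap, a 50 pA/5 s
  main stimulus, a configurable delay, and the identical test pulse
  again. The pre-stimulus pulse is placed 5 s before the main onset; the
  baseline response is insensitive to this placement because the model is
  at rest (verified by the isolated-pulse control, which reproduces the
  baseline response exactly).

## Analysis measures

Spike times are linearly interpolated upward crossings of −20 mV with a
2 ms refractory merge. Model spikes overshoot around 0 mV while
subthreshold dynamics stay below about −40 mV, so counts are insensitive
to the threshold over a wide band; the suite checks −20 vs −5 mV. (The
second spike of a strong step response, fired during the initial rapid
adaptation, can peak slightly below 0 mV, which is why the insensitivity
band is not extended all the way to 0.)

The instantaneous firing rate (IFR) is the inverse of each inter-spike
interval, timestamped at the later spike of the pair. The adaptation
slope `s_adapt` takes the last 19 IFR values, drops the very last (its
closing spike may be truncated by the stimulus offset), splits the
remaining 18 into two consecutive groups of 9, and divides the difference
of the group means by the time between the middle (5th) spikes of each
group — the grouped form is robust to the discreteness of late, slow
IFR values. It requires at least 20 spikes and reports *undefined*
otherwise.

The AHP amplitude is the post-stimulus voltage minimum minus the
pre-injection baseline; the half duration $T_{1/2}$ is the time from
stimulus offset to the first post-trough recovery to half amplitude.
Deflections shallower than 0.05 mV are reported as *no AHP*. Because
AHPs here last tens of seconds, step experiments simulate a 60 s
post-stimulus tail by default.

Bursts are segmented at inter-spike intervals exceeding 5× the median
ISI after discarding the first 20% of the record as transient. The 5×
criterion cleanly separates the model's regimes (within-burst ISIs of
tens of ms versus inter-burst gaps of seconds); the suite verifies that
the segmentation is insensitive to this factor over 3–8×. Period is the
mean inter-burst-onset interval, duration the mean first-to-last-spike
span of complete bursts, and the duty cycle their ratio. Fewer than three
burst onsets, or no qualifying gaps, report *not bursting*.

Classification of step responses: *subthreshold* (no spikes),
*depolarization block* (voltage above −30 mV without spiking for more
than 200 contiguous ms during the injection), *premature termination*
(gap from last spike to stimulus offset exceeding max(500 ms, 3× the
last ISI)), else *sustained*. The block thresholds are package choices —
the phenomenon is only used to delimit FI-curve plots — and the
premature-termination margin is deliberately generous so that slow late
firing near 20 Hz is not misclassified.

## The experiment drivers and problem sizes

Each driver in `R/experiments.R` is a pure function of its configuration
(no hidden randomness anywhere in the package; identical inputs give
bit-identical tables). The default problem sizes are the study
conditions themselves: 5 s steps with 60 s tails, integer-pA scans of
20–50 pA for the sustained-spiking thresholds, ramps of 2/10/40 s, 40 s
zaps, memory delays up to 52 s with 200 ms probes, and 50–100 s records
for the bursting survey (100 s for the endogenous burster, whose period
approaches 15 s). The test suite exercises the same drivers at these
sizes.

## What the synthetic fixtures emulate

`synthetic_spike_train()` and `synthetic_ahp_trace()` generate spike
trains (constant-rate, linearly decaying IFR, bursting) and voltage
traces (rest + stylised spikes + exponential AHP) whose descriptors are
known in closed form; every analysis function is validated by
round-tripping these fixtures. They emulate the *geometry* of the
quantities being measured — ISI sequences, trough depth, recovery
times — not the biophysics: passing fixture tests shows the measures are
computed correctly, not that the model is right; the model itself is
validated separately against its own invariants (rest-state balance,
conservation under frozen sodium, gating bounds, solver cross-checks).

## Reproduction notes and known limitations

The implementation reproduces the printed model description exactly, and
the description is strikingly self-consistent at rest: relaxing the
equations yields V = −59.93 mV and $[Na^+]_i$ = 40.082 mM against the
stated −60 mV and 40.08 mM, the sodium-flux balance at rest pins the
pump stoichiometry factor to 3.0006, and the subthreshold zap response
reproduces the reported first-cycle peak to 0.1 mV. All qualitative and
ordinal findings reproduce as well: the AHP ordering (absent in ConCon,
deeper in DynDyn than DynCon despite a *smaller* peak pump current and a
smaller sodium rise), the premature-termination regime below a
sustained-spiking threshold with final rates clustering near 20 Hz, rate
hysteresis that grows with ramp duration and is absent in ConCon,
history-dependent asymmetry of near-threshold zap responses, and the
silent/tonic/bursting/endogenous-bursting regimes of the pump-parameter
space.

Quantities that depend on the cumulative sodium load of prolonged
spiking, however, come out 15–25% stronger here than the published
values (deeper AHPs, steeper late adaptation, sustained-spiking
thresholds about 2 pA higher, burst periods about 15% shorter). We probed
every typographically ambiguous reading of the gating equations
one-at-a-time and found none that reconciles these quantities jointly
while preserving the (exactly matching) resting state; the differences
are also far outside the integrator's error (adaptive vs fixed-step
solutions agree to sub-ms spike times). We therefore publish the
equations as printed rather than tune any parameter toward the reported
numbers, and flag the affected acceptance checks rather than weaken
them.

Out of scope by design: potassium or extracellular concentration
dynamics, pump voltage dependence, temperature dependence beyond the
fixed 25 °C, channel noise, synaptic/conductance stimuli,
frequency-domain impedance analysis, and multi-compartment geometry.
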