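---
title: "Model and methods: phase-targeted stimulation of ING gamma networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: phase-targeted stimulation of ING gamma networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ctcstim)
```

`ctcstim` simulates cortical columns that generate gamma oscillations
through an interneuron-gamma (ING) mechanism, measures how much of a
time-varying input signal survives into their spiking output, and uses
single precisely timed current pulses — delivered closed-loop, guided by
the column's phase-response curve — to hold a network of such columns in a
desired synchronization or signal-routing state. This vignette documents
the model, every analysis choice that required a decision, and what the
package's synthetic benchmarks do and do not establish.

## The column model

A column has 800 excitatory and 200 inhibitory conductance-based quadratic
integrate-and-fire neurons. Each membrane potential obeys

$$C_m \dot V = p_2 V^2 + p_1 V + p_0 + I_\mathrm{syn} + \sigma_n\,\eta(t) + I_\mathrm{pulse},$$

with a spike registered when $V$ crosses $V_\mathrm{thresh} = -56.23$ mV
and $V$ reset to $-67$ mV (no refractory period beyond the reset). The
quadratic leak has stable root $\approx -64.7$ mV, the quiescent resting
potential; the unstable root at $\approx -55.7$ mV gives the model its
spike-initiation nonlinearity. Membrane capacitance is
$C_m = 1\,\mu\mathrm{F/cm^2} \times A$ with areas
$A_e = 2.88\times10^{-4}$, $A_i = 1.2\times10^{-4}\ \mathrm{cm^2}$
($C_e \approx 0.288$ nF, $C_i \approx 0.12$ nF), the standard specific
capacitance — with it, a 4 nA, 1 ms pulse depolarizes an excitatory cell
by about 14 mV, more than the full reset-to-threshold range, which is what
makes the strongest pulses full phase resets.

Synaptic interactions follow exponential kernels: an excitatory event adds
$\omega_e = 0.4$ nA decaying with $\tau_e = 3$ ms; an inhibitory event adds
a fast/slow mixture ($\chi_1 = 0.9$ at $\tau_{i1} = 1.2$ ms,
$\chi_2 = 0.1$ at $\tau_{i2} = 8$ ms) of total weight $\omega_i = 1.2$ nA.
Kernel state $g(t)$ is converted to membrane current as

$$I_\mathrm{chan} = g(t)\,(V_\mathrm{rev} - V)\cdot(1\,\mathrm{V})^{-1},$$

i.e. the conductance-times-driving-force product read literally in SI
units (`syn_norm = "volt"`, the default). This choice deserves emphasis,
because it fixes the *relative* scale between synaptic currents, the
internal noise, and the stimulation pulses. With it, synaptic currents sit
at the few-hundred-pA scale, so noise magnitudes of 0.075–0.15 nA visibly
degrade the rhythm and pulses of 0.25–4 nA span the range from weak
biphasic phase shifts to complete resets — the documented operating
regime. Two alternative normalizations are retained for comparison:
`"common"` (both kernels scaled by $1/|V_e - V_\mathrm{reset}|$, so an
event delivers its nominal weight in amperes near rest) makes recurrent
currents an order of magnitude stronger relative to $\sigma_n$ and
$\delta I$, leaving the rhythm essentially impervious to the stated noise
levels; `"per_reversal"` (each kernel scaled by its own
$|V_\mathrm{rev} - V_\mathrm{reset}|$) additionally overweights inhibition
roughly eightfold, and the slow IPSC tail then pins the rhythm near 40 Hz
regardless of drive.

Local wiring is purely inhibitory: I→I and I→E projections with
probability 0.5 and 5 ms conduction delay (no local E→E or E→I). The
delayed mutual inhibition is the ING generator: each synchronized
inhibitory volley silences the network, and the next volley can only occur
once the IPSC has decayed, setting a gamma-period rhythm that the
excitatory pool inherits.

Integration is forward Euler at $dt = 0.1$ ms. Because the synaptic term
is linear in $V$, its stiffness during synchronized volleys is handled by
an exponential-Euler update of the linearized part (exact for frozen
conductance); below stiffness the update reduces to plain forward Euler.
Delays are rounded to integer multiples of $dt$ (5 ms = 50 steps exactly),
and spikes are delivered to every postsynaptic target exactly one delay
later. Divergence ($V > 0$ V or $V < -1$ V, or non-finite) aborts with the
neuron and time named.

## Stochastic inputs

*Pink noise.* Each neuron receives its own unit-variance 1/f current
trace, scaled by $\sigma_n$. The generator streams white noise through a
bank of six one-pole filters plus direct terms (a classic audio-domain
1/f approximation accurate from about $10^{-4}$ of the sampling rate to
Nyquist); the filter's stationary standard deviation is computed in closed
form so the process has exactly unit scale, and `generate_pink_noise()`
traces are additionally normalized to unit sample standard deviation. The
streaming form matters: storing explicit noise traces for 3,000 neurons
over tens of seconds would take gigabytes.

*Flicker.* The information-carrying input is a piecewise-constant
Uniform$[-1,1]$ amplitude modulation holding each value for 10 ms
(emulating a 100 frames/s luminance flicker), applied to the afferent
drive as $S(t) = S_0(1 + \sigma_F F(t))$ with $\sigma_F = 0.1$. One
flicker signal per column modulates both pool drives.

*Afferent drive.* Each neuron of a driven pool receives an independent
inhomogeneous Poisson event train (event count per $dt$ bin drawn as
Poisson$(S(t)\,dt)$, the exact realization of the process at piecewise
constant rate), feeding the excitatory kernel at zero delay.

All randomness derives from one master seed by fixed sub-seeding
(connectivity, per-neuron noise, per-neuron Poisson, per-column flicker
are independent streams), so any component is reproducible in isolation;
structural and realization seeds are separate, letting one connectivity be
re-simulated under many noise realizations.

## Calibration

Noise raises firing rates, and the recurrent coupling amplifies any rate
change, so every noise level is calibrated: afferent base rates $S_e, S_i$
are scaled by signed-error proportional updates (2 % per Hz of error,
capped at 20 % per iteration) until the excitatory pool averages 15 Hz and
the inhibitory pool 60 Hz over a 3 s probe (0.5 s transient discarded),
tolerances 1 and 3 Hz. The proportional-in-squared-error magnitude of the
original description cannot carry the sign of the update, so the signed
form is used; the cap recovers bounded steps for large errors. In the
three-column network the same loop first calibrates the X/Y drives
in-network (mean error over both columns, identical update to both,
preserving symmetry), then scales the feedforward connection probabilities
$p_{Ze}, p_{Zi}$ (clipped to $[0,1]$) until Z shows the same rates.
Package defaults store converged values per noise level, so calibration
from defaults typically verifies in one iteration; the loop always
re-measures before accepting. One observed deviation from the idealized
expectation: while the excitatory drive decreases with $\sigma_n$ as
expected, the calibrated inhibitory drive is not perfectly monotone across
the lowest noise levels (noise both excites neurons and disrupts the
synchrony that makes inhibition effective, and the two effects do not
cancel identically in both pools).

With the defaults the calibrated column oscillates at 64 Hz at zero noise,
rising monotonically to about 78 Hz at $\sigma_n = 0.15$ nA. The reference
range for this phenomenon is 60–75 Hz: the package's rhythm runs a
systematic ~4 Hz fast across the range. We attribute this to the synaptic
normalization convention (the only free scale in the model once Table-level
parameters, wiring and rate targets are fixed) and report it as a known
limitation rather than adjusting any parameter to compensate.

## Phase measurement

The default analysis signal is the 1 kHz excitatory-pool rate, smoothed
with a 3 ms boxcar; per-source synaptic currents into each excitatory pool
are recorded as alternatives (the routing-state analysis uses the currents
into Z). Offline phase: z-score, zero any artifact windows, zero-phase FIR
bandpass, Hilbert transform, phase = argument of the analytic signal. The
band is found per condition from a time-averaged Morlet spectrum
(center-frequency parameter 6): peak within 20–120 Hz after 3-bin
smoothing, band edges at the half-power points. The FIR has order
$3 f_s / f_{lo}$ (rounded even, Hamming window); it is applied as two
passes of the symmetric filter via FFT with the total group delay (an
integer number of samples) removed exactly, which is identical to
forward-backward filtering away from the edges. Samples within 30 ms
(about two gamma cycles) of trace edges or artifact windows are masked
invalid; masked samples are never consumed by controller logic.

Real-time phase may only use the past. An AR model (order
$f_s/f_\mathrm{peak} \approx 15$, one cycle at 1 kHz) is fitted to 10 s of
unperturbed activity with the Burg lattice method (`stats::ar.burg`) and
forecasts the signal 100 ms beyond "now"; the offline pipeline then runs
on the extended signal and the phase is read at the last observed sample,
now 100 ms from the forecast edge so Hilbert edge distortion cannot reach
it. Two practical details: (1) when reading the phase *at a pulse onset*,
the last 2 ms of history are dropped and the phase is read 2 samples into
the forecast, because the centered 3 ms smoothing would otherwise leak the
pulse response into the "pre-pulse" history; (2) in closed loop, the
11 ms window following each fired pulse is zeroed in the history, mirroring
the offline artifact treatment.

## Signal content: wavelet spectral coherence

The coherence between input flicker and population output is

$$C_{xy}(f,\tau) = \frac{\left|\sum_i W_x^*(f,t_i)\,W_y(f,t_i+\tau)\right|}
 {\sqrt{\sum_i |W_x(f,t_i)|^2\,\sum_i |W_y(f,t_i)|^2}},$$

computed per frequency over all lags at once by FFT cross-correlation.
The denominator uses root-sum-square normalization so that self-coherence
is exactly 1 — the product-of-summed-moduli variant (available as
`normalization = "printed"`) cannot reach 1 even for identical signals.
Scores are pooled over a cone of interest: frequencies 4–45 Hz, lags
within $\pm 7/(6f)$ of the central lag $\tau_{xy}$, estimated as the
squared-coherence-weighted mean lag within 25 ms of the band-averaged
peak. The pooled score $\overline{SC}$ is an unweighted mean over in-cone
grid cells. Chance levels pair the output with independently drawn
surrogate flickers (default 100) and report the 95th percentile.
Coherence is biased by sample size, so comparisons are only made between
equal-duration signals; the API refuses anything else. State-conditioned
routing scores (`routing_scores()`) zero the out-of-state samples of both
input and output under a common mask, so the per-state scores of a run
share one effective duration.

## Stochastic phase-response curves

Single pulses (1 ms squares into every neuron of a column) are
characterized by batches of 1 s runs: pulsed runs with onset at
0.5 s plus a Uniform(0, 0.1 s) per-run jitter, and an equally sized
amplitude-0 control group. The jitter matters because all runs start from
identical initial conditions; a deterministic onset time would sample only
a narrow range of oscillation phases, whereas jitter over ~6 gamma cycles
makes the onset phase approximately uniform. Onset phases are estimated by
the AR-forecast method from pre-pulse data only. Pulsed trials are matched
greedily, without replacement and in trial order, to the control trial
with the nearest onset phase (for the three-column network, additionally
requiring both routing-state phase differences to match within 0.2 rad);
the shift at delay $\tau$ is the circular difference of the two trials'
phases at their own onset times plus $\tau$. Shifts are binned on a
36×36 onset-phase × shift grid (plain histogram, no smoothing), and each
occupied onset bin is condensed into a circular mean, resultant and
circular quartiles; bins with fewer than 10 samples or resultant below 0.1
are flagged undefined, never interpolated. For PRC reads the artifact
guard is the zeroed pulse window itself (pulse + 10 ms, with a 2 ms margin)
rather than the 30 ms analysis guard — the immediate portion of the
response at $\tau < 30$ ms is part of what the PRC measures.

The settling delay is the smallest $\tau$ on a 5 ms grid after which
consecutive mean-PRC curves differ by less than 0.15 rad on average; the
calibrated column at $\delta I = 2$ nA settles around 25–30 ms (2–3
cycles). Switch probabilities reduce state-difference shift distributions
to $p_{sw} = 1 - \int_{-\pi/2}^{\pi/2}\rho(\Delta\Phi)\,d\Delta\Phi$, with
the passive baseline from control-vs-control pairings at the same delay.

## The routing network and its state

Three columns: X and Y receive independent flicker-modulated drives and
are coupled laterally ($X_e \to Y_i$, $Y_e \to X_i$, probability 0.02,
delay 5 ms), which locks them in anti-phase. Both project onto Z
($p_{Ze}, p_{Zi}$ calibrated, delay 5 ms, a choice — every other delay in
the model is 5 ms); Z sends nothing back and receives no afferent drive of
its own, so its rhythm must be entrained by one of its inputs. The
competition makes the network bistable: in state Tr$^X$ the X volleys
arrive at Z's excitability peaks and the X input signal propagates while
Y's is suppressed, and symmetrically for Tr$^Y$.

The state is read from the phases of the $X_e$-, $Y_e$- and $Z_i$-origin
currents into $Z_e$: $\Phi_{ZX} = \phi_{X_e} - \phi_{Z_i}$, and Tr$^X$
is declared when $\Phi_{ZX} \in (0, 0.5\pi)$ — a quarter of all phases, so
the chance level of being in a given state is exactly 0.25. Because the
phase zero of a band-passed current depends on its waveform, the measured
attractor does not sit at a universal angle; `estimate_state_offset()`
locates the attractor axis of the passive phase-difference distribution
(angle doubling collapses the two π-separated modes), identifies the
X-favorable mode as the one where Z spiking correlates with the
$X_e$ current, and rotates it to the window center. The offset is
estimated once per condition from an unperturbed training run. In finite
realizations the quenched connectivity breaks the X/Y symmetry noticeably
— one state can be occupied 2–3× more than the other at intermediate noise
— so controller evaluations target the *less* occupied state by default,
where there is headroom to demonstrate control.

## Controllers

Both controllers tick at 1 ms (the analysis rate), recompute real-time
phases from history only, fire single 1 ms pulses, and enforce a 100 ms
refractory period after every pulse — long enough for the network to
settle into its post-pulse state. Firing is edge-triggered: the pulse is
issued in the tick where the wrapped live phase crosses the target onset
phase.

*Synchronization.* Two uncoupled columns drift apart as a random walk in
$\Phi_{XY}$. When $|\Phi_{XY}| > \pi/4$ (an eighth of a cycle) and the
refractory time has passed, the controller inverts the tabulated mean PRC:
it picks the onset phase whose expected shift is circularly closest to the
required correction $-\Phi_{XY}$ (ties toward the smaller shift) and
pulses X when its phase crosses that onset. If no PRC bin is defined (high
noise destroys phase-response reliability), the controller degrades to
pulsing whenever outside the window, which still biases the system away
from forbidden states; the fallback is flagged in the log.

*Routing.* The switch controller fires iff (1) the refractory period has
elapsed, (2) the classified state differs from the target (unknown states
hold fire), and (3) the pulsed column's phase crosses the onset with the
highest measured switch-probability gain. No hysteresis is applied beyond
the refractory period; the strict interval rule alone defines the state.

## Scales used by the shipped benchmarks

The package's own test suite and the acceptance script run at "desk"
scale, chosen so the full pipeline stays interactive on one core: PRC
batches of 110–300 runs per group (the experiment drivers default to 300,
with the original 2,500 reachable via `n_runs`), routing comparisons over
8 passive 8 s runs, controller evaluations of 6–10 s, and chance levels
from 100 surrogates. At these sizes the qualitative phenomena —
biphasic-to-reset PRC transition, anti-phase locking, bistable routing,
above-baseline controller performance — are stable across seeds, while
per-bin PRC statistics remain visibly noisier than at full scale.

## What the synthetic benchmarks do not show

Everything here is measured on the model's own synthetic data: the flicker
is the only "signal", noise is stationary 1/f, oscillations are sustained
rather than burst-like, and the stimulation couples identically to every
neuron of a column. Conclusions therefore concern the method — that
real-time AR phase tracking is accurate enough to place single pulses, and
that PRC/switch-map inversion suffices to hold a bistable CTC network in a
chosen routing state up to a critical noise level — not any particular
biological cortex. Known quantitative limitations: the ~4 Hz fast offset
of the oscillation frequency under the default normalization; the weak
non-monotonicity of the calibrated inhibitory drive at low noise; and the
realization-dependent asymmetry of the bistable states, which full-scale
averaging over connectivity seeds would remove.
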