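---
title: "A conductance-based model and virtual electrophysiology of calretinin-positive periglomerular cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A conductance-based model and virtual electrophysiology of calretinin-positive periglomerular cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crpg)
```

## The cell and the model

Calretinin-positive periglomerular (CR+ PG) cells are among the smallest
interneurons of the mouse olfactory bulb: about 4 pF of membrane capacitance
and an input resistance near 1.9 GΩ. Their voltage-gated repertoire is
unusual — a fast transient sodium current, a large A-type potassium current
(and *no* delayed rectifier), a small persistent L-type calcium current, and
a slow hyperpolarization-activated cationic h-current. Because both of the
excitability-carrying currents (Na and A) inactivate completely, and nothing
replaces them, these cells fire exactly one action potential in response to
a sustained input and then become ohmic, unexcitable elements until the Na
conductance de-inactivates — a process that takes on the order of 80 ms at
−70 mV.

`crpg` packages this biophysics as a single-compartment Hodgkin–Huxley
model,

$$ C_m \frac{dV}{dt} = I_{inj} - g_{leak}(V - E_{leak})
   - \sum_c g_{max,c}\,\Big(\prod_g x_g^{p_g}\Big)(V - E_c), $$

with each gating variable relaxing as
$\dot x = (x_\infty(V) - x)/\tau_x(V)$. Units are fixed package-wide to
{mV, ms, pA, nS, pF}, under which the membrane equation needs no conversion
factors. Depolarization is positive; currents are positive outward.

Steady states are Boltzmann curves parameterized by a half-point voltage and
a steepness given either as a slope factor $k$ (mV) or an equivalent gating
valence $z$, tied by $k\,z = kT/e = 25.69$ mV (25 °C — the temperature at
which this value reproduces the Nernst sodium potential computed from the
recording solutions). Activation variables whose curve was obtained by
taking the cube root of a fitted conductance–voltage relation are
represented *as* that cube root (`root = 3` in `gate_spec()`), which makes
the identity $g_{max}\,a_\infty^3(V) \equiv g(V)$ exact at every voltage;
the analysis round trips in this package rely on that identity.

### Time constants and voltage-stitching

The kinetics of inactivation were measured in two disjoint voltage ranges:
development of inactivation at depolarized potentials and removal of
inactivation (recovery) at hyperpolarized ones. The model keeps each fitted
law on its measured range and joins them with a straight line across the
unmeasured gap (A-current: −70…−30 mV; Na h gate: −70…−50 mV). This adds no
invented dynamics inside any measured range and keeps τ(V) continuous;
`tau_stitched()` implements it generically. Every τ law carries a positive
floor so integration never divides by a vanishing time constant.

The h-current τ(V) is implemented as
$\tau(V) = 5908\,e^{V/51.82} - 677.48$ ms with a 30 ms floor. The fitted
exponential-plus-offset expression is used in the orientation in which the
current activates faster with hyperpolarization, which is the behavior the
recordings show; as printed, the signs of the published expression would
make τ vanish everywhere, which we treat as a typographical slip.

### The reference parameterization

`reference_cr_cell()` assembles the printed values: $C_m = 4.07$ pF,
$R_{in} = 1877.7$ MΩ (leak 0.533 nS, reversal −70 mV, the holding level of
the functional recordings); I_A with $g_{max} = 8.08$ nS, $E_K = −101$ mV,
cubic activation (base half-point −12.3 mV, $z = 3.8$) and single-gate
inactivation (−52.7 mV, 7.59 mV); I_Na with $g_{max} = 12.7$ nS,
$E_{Na} = +61.4$ mV, cubic activation (−34.6 mV, $z = 4.3$) and inactivation
(−70.0 mV, 9.4 mV); I_h activating below −100 mV (slope 9.02 mV); and a
persistent L-type calcium conductance.

Three components are conventions rather than measurements, and are flagged
as such in the documentation:

* **L-type gating.** Only the ~0.6 nS maximal open-channel conductance was
  measured (with Na and K currents blocked). The default activation curve
  (−20 mV half-point, 6 mV slope, τ = 1 ms, no inactivation) is a standard
  L-type convention. For the *integrated* cell the default weight is 0.2 nS:
  with a persistent 0.6 nS inward conductance the steady-state I(V) of a
  0.53 nS-leak cell becomes N-shaped and the model latches at a depolarized
  plateau after every spike, which the recorded cells demonstrably do not do
  (they return to rest and recover their excitability). The isolated-current
  pipeline (`analyze_ca_current()`) uses the measured 0.6 nS.
* **h-current weight.** The h-current kinetics were characterized in a
  high-potassium bath chosen to enhance the current; under standard bath
  conditions the recorded sag only becomes evident below about −90 mV. The
  default $g_h = 0.3$ nS is set from that observation (1 nS would produce an
  obvious sag already at −88 mV). The tail-current analysis normalizes
  amplitudes, so the recovered activation curve is independent of this
  choice.
* **Reversals** $E_h = −35$ mV and $E_{Ca} = +65$ mV are conventions,
  configurable.

### Activation order: 3 vs 4

The A-current rise is described as a third-order exponential and its
steady-state activation was extracted as a cube root, so the model uses
$p = 3$. The time-to-peak inversion (`tau_m_from_ttp()`), however, defaults
to $p = 4$, the kinetic order assumed where that inversion was introduced.
Both orders are ordinary arguments; nothing is hard-coded.

## The protocol engine

`simulate()` integrates the model under arbitrary segment-based stimulus
programs. Gates advance by the exponential-Euler closed form
$x \leftarrow x_\infty - (x_\infty - x)\,e^{-\Delta t/\tau}$ evaluated at the
instantaneous potential — exact for piecewise-constant V (all of voltage
clamp) and unconditionally stable in current clamp — while V advances by
forward Euler. The default step is 0.01 ms; the multi-second h-current
protocols use 0.05 ms, where the slowest gate (τ ≥ 30 ms) makes the coarser
step immaterial. A convergence test (halving dt) is part of the suite.

The voltage clamp is ideal: no series resistance and no capacitive
transient, so the command is met exactly at every sample and the recorded
current is the algebraic membrane current. All analyses start at or after
twice the time-to-peak, so the absent capacitive transient would not be
sampled anyway. The initial state of every simulation is the steady state at
the first segment's level, eliminating settling artifacts; current-clamp
protocols that need a −70 mV baseline ride on the holding current returned
by `holding_current()`, mirroring the recording practice (the model's
zero-current rest sits near −59 mV because of the Na/Ca/h window currents
implied by the printed curves).

## The measurement procedures

Each pipeline simulates the original protocol on a channel-isolated model
(`isolate_channels()`, the in-silico analogue of TTX/4-AP/Cd²⁺/ion
substitution; the leak is also zeroed in voltage-clamp isolations, i.e.
ideal offline leak subtraction) and then measures the traces exactly as the
recordings were measured:

* **Zero-time extrapolation.** The decay of a transient current is fitted
  with $A e^{-t/\tau} + C$ over [2·ttp, step end], t measured from the step
  onset, and extrapolated to t = 0. This removes the inactivation that
  developed during the pulse and returns the open-channel current.
* **Conductance conversion and Boltzmann fit.** $g(V) = I_0(V)/(V - E)$,
  then a least-squares fit of
  $g = g_{max}\,[1 + e^{z e (V_0 - V)/kT}]^{-1}$.
  The sodium conversion uses the $E_{Na} = +63$ mV convention of the
  original conductance analysis, and the pipeline's Na model is built with
  the same reversal so the transform is exact; mixing +61.4 mV dynamics with
  a +63 mV conversion would bias the fitted $g_{max}$ by several percent,
  more than the parameter-recovery tolerance.
* **Availability correction.** Zero-time extrapolation cannot correct for
  the *steady-state* inactivation remaining at the conditioning level
  (0.960 for Na at −100 mV, 0.998 for the A-current). The pipelines divide
  the conductance curve by the availability at the conditioning potential
  read off the inactivation curve fitted in the same session — the same
  curve the recordings measured. Without this the recovered
  $g_{Na,max}$ is 4% low.
* **Steady-state inactivation.** Long prepulses, peak test currents
  normalized to their maximum, falling Boltzmann with a free amplitude (so
  the normalization convention cannot bias the midpoint). For sodium the
  peaks are replaced by zero-time amplitudes: activation at the test
  potential is so fast (τ_m ≈ 0.1 ms) that the inactivation decaying before
  the peak otherwise compresses the fitted slope by ~4%.
* **Recovery from inactivation.** Double pulses; the peak test current vs.
  gap is fitted with $A - B e^{-gap/\tau}$. The free pre-factor absorbs the
  incomplete inactivation at gap zero (the A-current availability at −70 mV
  is 0.91, not 0).
* **h-current tails.** $I_{inst}$ is averaged over 5–15 ms after the step
  onset and $I_{ss}$ over the last 10% of the step; the activation curve
  comes from tail currents at a common post-step potential,
  back-extrapolated to the transition time by a single-exponential fit and
  fitted with a falling Boltzmann carrying a free additive offset — the
  tail's leak component is identical across sweeps and the offset absorbs
  it exactly.
* **Time-to-peak inversion.** $ttp = \tau_m \ln(1 + p\,\tau_h/\tau_m)$ is
  solved for $\tau_m$ by safeguarded Newton iteration; the bracketing grows
  the upper bound because the root exceeds the time-to-peak whenever the
  logarithm is below one.

All fits are deterministic: exponentials are seeded by log-linear
regression after offset removal, Boltzmanns by the half-maximum crossing and
the 25–75% width. The optimizer is Levenberg–Marquardt on the residual
function directly (`minpack.lm::nls.lm`), which is robust on the
zero-residual data that round-trip tests produce. Non-convergence and
degenerate inputs are flagged in the result objects, never silent.

## Synthetic data

`generate_recording_set()` adds white Gaussian noise to the recorded channel
(current in voltage clamp, voltage in current clamp), with byte-identical
output under a fixed seed. `sample_population()` draws cell populations
around the reference model: truncated-Gaussian coefficients of variation on
capacitance and conductances (default 10%, ±3 sd), ±2 mV jitter on
half-point voltages, 5% on slope factors. What the generator deliberately
omits — 1/f and line noise, seal leak drift, series-resistance and
space-clamp errors, synaptic background — bounds what passing tests show:
they demonstrate that the *procedures* recover the generating parameters
under realistic white noise and cell-to-cell spread, not that they are
robust to every artifact of real recordings.

## Excitability battery

The functional battery (`excitability_battery()`) holds the full cell at
−70 mV and measures: rheobase; the single-spike response to a sustained
1.5× rheobase step; spike half-width with and without the A-conductance
(its suppression broadens the spike, the 4-AP result); the late-phase
current–voltage relation (mean V over the last 50 ms of 300 ms steps,
−15…+45 pA); and paired 10-ms pulses at 15–310 ms intervals. The pulse
amplitude is 1.1× the smallest amplitude whose spike *peaks within the
pulse* — near absolute rheobase this GΩ cell fires with tens of
milliseconds of latency, which would make attribution of a spike to a
particular pulse ill-posed, whereas the published traces show the spike
riding the pulse. The second-pulse response is quantified as the peak
depolarization relative to the potential at that pulse's onset (a graded
response on a moving baseline); a baseline-referenced peak would be
dominated by the first spike's repolarization tail at the short intervals.
A variant scales only the removal-of-inactivation branch of the Na h gate
by 0.1 (`modify_channel(..., tau_branches = 1)`), which restores the
second spike at the 50-ms interval.

One battery property deserves honesty: perfect linearity of the late-phase
I–V is not attainable under the printed kinetics. The overlap of the Na
activation and inactivation curves leaves a window current of roughly
−14 pA near −40 mV, and the h-current activates at the most hyperpolarized
step — both bend the relation. The reproduction report
(`reproduce_all()`) computes the resulting r² alongside the slope, which
does land within 15% of the printed input resistance; the r² row documents
the shortfall rather than hiding it.

## Problem sizes and runtime

Defaults were chosen so the whole reproduction — every pipeline plus the
battery — completes in well under a minute on one core: voltage-clamp
families of 9–13 sweeps at dt = 0.01 ms, 500 ms prepulses (≥5× the slowest
gate τ over the prepulse range, enforced with a warning), ten recovery gaps
up to 250 ms, and eight 5-s h-current sweeps at dt = 0.05 ms. The compiled
integrator makes per-sweep cost negligible; the fits dominate.

## Known limitations

* The published pooled activation midpoints (means of per-cell fits) are
  not exactly reproducible from the single printed conductance fit; the
  cube-root activation-curve checks therefore compare against analytic
  oracles computed from the printed conductance parameters, not against the
  pooled values.
* The "no current after −50 mV preconditioning" observation is not
  consistent with the printed availability curve (41% available at −50 mV);
  the tests assert the suppression that curve actually dictates.
* L-type calcium gating and the h/Ca reversals are conventions (above);
  conclusions that depend on them (plateau behavior, exact rheobase) are
  model conventions, not measurements.
* No temperature scaling, stochastic gating, or multi-compartment
  structure.
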