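---
title: "Methods: simulating and analyzing Cav1.3 whole-cell gating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing Cav1.3 whole-cell gating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavclamp)
```

## Purpose and scope

`cavclamp` implements the standard whole-cell voltage-clamp analysis of
Cav1.3 L-type calcium channel gating — Boltzmann activation and
availability curves, window current, exponential inactivation kinetics,
recovery from inactivation, tail-current deactivation, and
run-down-corrected concentration–inhibition curves — together with a
biophysical current generator that stands in for raw patch-clamp
recordings. The generator exists so that every analysis stage can be
tested by *parameter recovery*: simulate currents from a known gating
parameterization, run the same pipeline an experimenter would, and check
that the fitted parameters return the generating ones. The shipped presets
encode published steady-state and kinetic parameters for wild-type and
F747S-mutant channels co-expressed with β3 or β2a subunits.

## The gating model

The empirical curve fits used in whole-cell work do not commit to a
mechanistic model, so the simulator adopts the smallest gate structure
whose outputs the analysis pipeline can invert: independent
Hodgkin–Huxley-type gates, one for activation (`m`) and two for
inactivation (`h_fast`, `h_slow`) with fixed fractional amplitudes and a
non-inactivating plateau,

$$ I(t) = G_\max C\,(V - V_\mathrm{rev})\; m(t)\,
   \big[I_\mathrm{ni} + A_f h_f(t) + A_s h_s(t)\big] + g_\mathrm{leak} V
   + \varepsilon(t). $$

Assumptions worth stating explicitly:

* **Linear ohmic driving force** `(V − Vrev)`, matching the I–V equation
  the analysis fits. No Goldman–Hodgkin–Katz rectification.
* **Independent first-order gates.** Within a constant-voltage segment
  every gate relaxes exponentially toward its steady state, so
  trajectories are evaluated in closed form at each sample — there is no
  ODE solver, no step-size error, and simulation of a full
  steady-state-inactivation family takes well under a second. (An
  independent `deSolve` integration is used as a cross-check in the test
  suite.)
* **Voltage-independent amplitude weights** `A_f + A_s + I_ni = 1`,
  enforced to 1e-9 on the simulator side. Fitted amplitudes are *not*
  constrained this way.
* **Additive white current noise**; capacitive transients are not
  modelled, so P/4 subtraction removes the linear leak essentially
  exactly (a convenient test fixture, not a realism claim).

### Time constants

The printed gating tables report inactivation and recovery time constants
but no activation kinetics, so the activation time constant is a modelling
choice: bell-shaped (Gaussian in voltage) with default peak 2 ms at
−20 mV, width 20 mV and floor 0.3 ms, blending logistically (midpoint
−40 mV, 4 mV width) into a deactivation branch
`τ_deact(V) = τ_deact,ref · exp((V + 69)/35)` on the hyperpolarized side.
`τ_deact,ref` is the deactivation time constant at −69 mV (0.8 ms for WT
presets, 3.5 ms for F747S, chosen so the mutant's ~4-fold increase in
normalized tail-current charge at −49 mV is reproduced). With a 2–3 ms
peak the 25-ms I–V pulse is quasi-steady, which is what makes the
activation round-trip accurate to well under 1 mV; a much slower assumed
τ_act would degrade that recovery, and this dependence is inherent, not
resolved, because the source data contain no activation kinetics.

Inactivation-gate time constants interpolate logistically (midpoint
−50 mV, 5 mV width) between the recovery values measured at the holding
potential and the decay values measured at depolarized potentials; the two
regimes are measured by different protocols and nothing constrains the
transition voltage range, so the interpolation is a declared convention.

### The F747S amplitude problem

The mutant inactivates mono-exponentially during a 5-s depolarization but
recovers bi-exponentially. One amplitude split cannot satisfy both tables
in a two-gate model. The F747S presets therefore give the two gates a
*single shared depolarized time constant* (the published mono-exponential
τ), making the simulated 5-s decay exactly mono-exponential with amplitude
`A_f + A_s`, while keeping the two distinct published recovery time
constants with weights in the published recovery-amplitude proportion.
WT presets split `1 − I_ni` in the published decay-amplitude proportion.
`I_ni` itself is taken from the steady-state-inactivation table (the
quantity the SSI protocol measures), and the 5-s-decay parameter rows are
shipped verbatim as separate closed-form fixture sets (`preset_decay()`),
because the two measurements differ by design (a 5-s pulse truncates slow
inactivation).

### Optional tail "hook"

A delayed tail-current peak is modelled, disabled by default, as a
blocked-open pool: during depolarization a fraction of open channels
occupies a non-conducting state (`b∞ = blocked_frac · m∞`, τ = 0.3 ms
default), and on repolarization the pool re-enters the open state faster
than deactivation empties it, producing a rising-then-falling tail. The
mechanism of the real phenomenon is unresolved; this is a phenomenological
stand-in with the right signature (peak delayed by more than 2 samples at
50 kHz).

## Protocols and conventions

All six protocol families are built as square-segment command waveforms
snapped to the sampling grid: 25-ms I–V steps in 5-mV increments from a
holding potential of −89 mV; two-pulse steady-state inactivation with 5-s
conditioning in 10-mV increments and 30 s between sweep starts; 5-s
depolarizations for kinetics; two-pulse recovery with a 2-s prepulse and
15 logarithmically spaced gaps over 0.001–20 s at 10 kHz; 10-ms steps to
the reversal potential followed by 20-ms repolarizations for tails; and
100-ms pulses at 0.1 Hz for pharmacology. Defaults the source protocol
descriptions leave open were fixed once: the I–V ladder spans −84…+61 mV
(covering both variants' activation ranges and reversal approach), the
SSI conditioning ladder spans −89…+21 mV (sampling the availability
plateau), and non-stated inter-sweep intervals default to 5 s.

Voltages are liquid-junction-potential corrected (−9.3 mV); protocols
carry a `jp_corrected` flag and `junction_correct()` refuses to correct
twice. Inward currents are negative throughout and percentages are
computed on magnitudes.

## Measurement choices that matter

Three analysis conventions deserve justification because they visibly
affect parameter recovery:

* **I–V peaks are signed absolute extrema.** Above the reversal potential
  the current is outward; taking the inward minimum there would clip the
  positive limb to zero and corrupt the fitted `Vrev` (and through it
  `V0.5` and `k`). `peak_current()` still defaults to the classical
  inward-minimum read-out for single-sweep use.
* **SSI ratios are isochronal.** After a depolarized conditioning step the
  activation gate is still open when the test pulse begins, so an
  onset-peak ratio overstates availability by up to ~9%. The pipeline
  instead averages the final 5 ms of both the control and the test pulse,
  which cancels the activation-gate state exactly; the onset-peak mode
  remains available (`measure = "peak"`).
* **Family-level leak estimation.** Offline linear subtraction with a
  baseline window at a single holding voltage cannot identify the leak
  conductance (the fallback subtracts the mean and warns). The SSI
  pipeline therefore pools holding and conditioning samples of the
  channel-free hyperpolarized sweeps (conditioning ≤ −69 mV), where two
  command voltages make `I = a + gV` identifiable, and applies that line
  to the whole family. The dose–response pipeline quantifies block on
  relative peak amplitudes and is run leak-compensated.

## Numerical choices

All curve fits use bounded Levenberg–Marquardt (minpack.lm) with tight
tolerances (`ftol = ptol = 1e-15`, up to 1000 iterations) so noise-free
closed-form fixtures are recovered to machine precision; when the final
`nls`-object construction rejects a rank-deficient gradient (which happens
at exact zero-residual solutions), the raw LM optimizer result is used
instead. Initialization follows the conventional recipes: midpoints from
interpolated half-maximum crossings, `k = 6` mV, `Vrev` from the
interpolated zero crossing beyond the peak, decay τ from a log-linear
regression. Bounds: `k ∈ (0.5, 30)` mV (a fit pinned at a bound is
flagged), τ ∈ (1, 60000) ms, amplitudes non-negative.

Decay model selection (`model = "auto"`) prefers the mono-exponential
unless the extra sum-of-squares F test favours the bi-exponential at
α = 0.05; a bi-exponential whose time constants collapse
(`τ_fast/τ_slow > 0.8`), fails to improve on the mono fit, or an
effectively exact mono trace (relative residual < 1e-12) all fall back to
mono. The recovery fit uses a free instantaneous offset bounded to
[0, 0.3] by default; the bound is raised to just above the shortest-gap
fraction when the data floor exceeds it, which happens whenever the
conditioning prepulse is short relative to a slow inactivation time
constant (the simulated F747S two-pulse experiment starts near 0.49).
Degenerate inputs fail loudly: all-zero I–V densities, constant SSI
ratios (I_ni indeterminate), inhibition data pinned at an asymptote, and
sub-noise tail currents are errors, not silent misfits.

Remaining-current fractions are measured from the current peak; the
5000-ms point is clipped to the last in-pulse sample when peak latency
pushes it past the 5-s pulse end (an overshoot of a few ms against time
constants of hundreds to thousands of ms).

## What the generator does and does not emulate

It emulates: voltage-dependent sigmoidal activation, bi/mono-exponential
inactivation with a non-inactivating fraction, deactivation tails with
optional hook, double-exponential recovery, linear sweep-to-sweep
run-down (percent of initial peak per minute, applied multiplicatively),
Hill-type (slope 1) concentration-dependent block with first-order
equilibration, ohmic leak, and additive Gaussian noise.

It does not emulate: Ca²⁺-dependent inactivation, GHK permeation,
single-channel stochasticity, capacitive transients, series-resistance
error, temperature effects, or cell-to-cell parameter variability. Passing
round-trip tests therefore demonstrate that the *analysis pipeline* is
correct and well-conditioned under realistic gating, run-down and noise
structure — not that the model captures every feature of real recordings.
Two measurement artefacts the simulator does reproduce faithfully — the
slight availability overshoot after 5-s conditioning (incomplete
equilibration of slow gates) and the nonzero availability floor at Vmax
(shallow-slope combinations) — are visible as the small, systematic
differences between fitted and generating parameters in the round-trip
tests, and real experiments share them.

## Problem sizes

The test suite and the acceptance script run the full study at the
protocol sizes above: 30-sweep I–V families at 50 kHz, 12-sweep SSI
families with 5-s conditioning, 15-gap recovery ladders at 10 kHz, 5-s
decay traces (thinned to ≤ 2500 points for fitting), and 30–50-sweep
pharmacology trains; the complete suite takes tens of seconds on one CPU.

## Known limitations

* Recovery and decay amplitudes measured from finite prepulses are
  attenuated relative to the generating weights (slow gates do not fully
  inactivate in 2 s); recovered *time constants* are accurate, and the
  amplitude attenuation is predictable in closed form.
* The β2a presets reuse the β3 recovery time constants of the matching
  variant, as recovery was characterized with β3 only.
* The fitted SSI plateau contains the incomplete-equilibration excess of
  the 5-s protocol (≈ 2 percentage points for β3 presets, more for the
  slower β2a combinations); this mirrors the real protocol rather than a
  fixable bias.
* IC50 estimates assume the block equilibrates within the sweeps averaged
  for steady state; the default schedule (12 sweeps per concentration at
  0.1 Hz, equilibration τ = 8 s) satisfies this comfortably.
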