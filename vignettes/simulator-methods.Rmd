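---
title: "Model and methods behind the aortasim waveform simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind the aortasim waveform simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortasim)
```

## What the package models

`aortasim` is an in-silico twin of a bench cardiovascular simulator: a
piston ventricular pump ejecting distilled water through a one-way aortic
valve into a 1:1-scale silicone aorta, terminated by peripheral-resistance
ball valves and a pressurised reservoir, with the vessel sealed inside an
air compliance chamber that controls the extravascular pressure. The
central aortic blood-pressure waveform in such a system — as in the human
body — is the superposition of the forward pressure wave launched by
ejection and the wave reflected at the aortic bifurcation, so reproducing
it faithfully requires the right geometry (path lengths), the right wall
mechanics (wave speed), and the right terminal load (reflection magnitude
and diastolic run-off).

The package generates these waveforms, extracts the standard pulse-wave
indices (SBP, DBP, PP, MAP, AP, AIx, foot-to-foot PTT/PWV), and replays
the device's parameter sweeps over heart rate, stroke volume, peripheral
resistance, and chamber pressures.

## Wave speed and wall mechanics

Pressure waves travel at the Moens–Korteweg speed of a thin-walled elastic
tube with incompressible, effectively inviscid fluid (inertia dominates
viscosity in a 2–3 cm lumen):

$$\mathrm{PWV} = \sqrt{\frac{E\,h}{\rho_f\,D\,(1-\nu^2)}}$$

with wall modulus $E$, thickness $h = 2$ mm, fluid density $\rho_f =
1000$ kg/m³ (water), inner diameter $D$, and Poisson ratio $\nu = 0.5$
(incompressible elastomer; not a measured value, a standard default
exposed in every signature). The aorta tapers from 28 to 16 mm, but the
relation takes one diameter; the package uses a single pulse-averaged
effective diameter $D_\mathrm{eff} = 21.8$ mm, chosen inside the taper
range so that inverting the relation at the 6.54 m/s design wave speed
returns the 350 kPa design modulus. `effective_diameter()` computes the
length-weighted mean over any path interval (22.6 mm for the root-to-
bifurcation path) for users who prefer a geometric value; $D_\mathrm{eff}$
is configurable.

The silicone wall is strain-softening. At zero transmural pressure
(TP = IVP − EVP = 0, maintained by the compliance chamber) the wall stays
at zero strain and keeps its zero-strain modulus of 346 kPa. Under
positive TP the default material interpolates measured (TP, E) knots —
(0, 346), (10, 248), (20, 80) kPa — with a monotone (Hyman) cubic,
clamped beyond the last knot. The knots are treated as measured truth
rather than re-derived, because they are not jointly consistent with the
wave-speed relation at a fixed diameter (the diameter in the expanded
state is unknown). For materials without tabulated data a thin-wall
Laplace closure is provided: hoop stress $\sigma = \mathrm{TP}\cdot r/h$,
strain $\epsilon = \sigma/E$, and $E = \mathrm{curve}(\epsilon)$ solved by
damped fixed-point iteration (damping 0.5, tolerance $10^{-8}$ on strain,
at most 100 iterations; non-convergence is an error, not a warning).

Negative TP (chamber over-pressurisation) is outside the modelled range
and rejected.

## The ventricular drive

The pump ejects `sv` millilitres per beat over a systolic fraction of
0.35 of the beat period (0.28 s at 75 BPM). Two templates are available;
both are non-negative (the valve prevents backflow) and integrate exactly
to `sv`:

* `early_peak` (default): $Q(u) = 12\,\mathrm{sv}/t_s\; u(1-u)^2$ on the
  ejection phase $u \in [0,1]$ — a rapid upstroke peaking at one third of
  ejection, the shape of human aortic flow. This shape matters: with the
  reflected wave returning $\approx 0.2$ s after the onset of ejection,
  an early forward peak is what lets the reflection augment *late
  systole* and produce the middle-aged waveform morphology (shoulder
  followed by an augmented region) whose AP/PP ratio sits near 13 %.
* `half_sine`: symmetric, peak flow $\pi\,\mathrm{sv}/(2 t_s)$
  (392.7 mL/s at the standard drive). Kept for its closed forms and as a
  simple reference template; with it the simulated waveform is
  younger-looking (reflection arrives after the peak).

Two choices here were genuinely open and are worth recording. First, the
ejection duration scales with the beat (fixed fraction) rather than being
fixed in seconds. At constant cardiac output this keeps the peak flow —
and with it the systolic peak — essentially constant while diastolic
truncation raises DBP, which is exactly the observed bench behaviour of
that sweep; a fixed-seconds ejection makes peak flow collapse with the
shrinking stroke volume and drags SBP down with it. Second, the piston's
diastolic refill is routed through the reservoir and never appears as
aortic flow: the valve isolates the aorta in diastole.

## The wave engine

The aorta is a single effective conduit from the valve outlet to the
bifurcation at path length $L = 669$ mm (half-circle arch of 50 mm radius,
arc length $\pi \cdot 50 \approx 157$ mm, plus the 512 mm abdominal
segment; the 74 mm femoral remainder is lumped into the terminal load).
It is a linear, lossless delay line at speed $c$ from the Moens relation
evaluated at the current effective modulus, so raising TP softens the
wall and slows every wave.

At the root, the forward wave is the pulsatile component of ejection
scaled by the characteristic impedance,
$w_s\, Z_c\, (Q(t) - \mathrm{CO})$ with
$Z_c = \rho c / A(D_\mathrm{eff})$, riding on a lumped Windkessel
relaxation $x(t)$ toward the reservoir pressure. The steady
(cardiac-output) component of flow deliberately does *not* travel as a
wave: its pressure is the Windkessel's mean $R\cdot\mathrm{CO}$. Putting
the full $Z_c Q$ on the line double-counts the DC pressure drop, inflates
the mean pressure, and forces any calibration to compensate with an
unphysically small $R$.

The Windkessel is a resistance–compliance pair with a series inertance on
the outflow branch:

$$C\,\dot x = Q - q, \qquad L_i\,\dot q = x - R\,q .$$

$L_i = 0.025$ mmHg·s²/mL is a frozen structural constant of the order of
$\rho\,\ell/A$ for the half-metre column of 14 mm line between the
bifurcation and the reservoir. Its role is qualitative but essential: the
outflowing column's momentum lets the end-diastolic pressure undershoot
the reservoir level slightly. Because the model is amplitude-linear, the
sign of (DBP − reservoir level) is the sign of the DBP-versus-SV slope;
only with this small undershoot does DBP *fall* as stroke volume rises,
as observed on the bench. A pure two-element Windkessel cannot reproduce
that direction. The discrete update is the exact matrix exponential of
the two-state system per sample, run as a second-order recursive filter.

The bifurcation reflects with $\Gamma = (R_T - Z_c)/(R_T + Z_c)$ against
a wave-termination resistance $R_T$, distinct from the total resistance
$R$ (a local orifice property versus a DC property). The reflection
passes through a first-order lag of 45 ms: a compliant termination
reflects low-pass, not instantaneously. Without this smoothing the
lossless line produces a sharp echo comb whose phase relative to the beat
makes waveform features wobble by ±1 mmHg at particular heart rates.
Both resistances follow the orifice law
$R(o) = R_\mathrm{ref}\,(0.85/(1-o))^2$ anchored at the 15 % standard
occlusion.

The closed valve re-reflects returning waves with coefficient 0.8 during
diastole and 0 during ejection (the open valve faces the low-impedance
ventricle). The forward-wave recursion retains **all** reflections
exactly (it is a feedback delay line, not a truncated sum); the
`n_reflections` setting only feeds the stability diagnostic
$|\Gamma\,\Gamma_\mathrm{root}|^{n}$, which is $\approx 10^{-7}$ at the
shipped constants. Configurations with $|\Gamma\,\Gamma_\mathrm{root}|
\ge 1$ are rejected.

Pressure at a sensor at path position $s$ is

$$p(s,t) = \mathrm{IVP} + f_0(t - s/c) + \Gamma\,\tilde f_0(t-(2L-s)/c),$$

where $f_0$ is the emitted forward wave and $\tilde f_0$ its smoothed
reflection. Because everything dynamic rides the wave, equal changes of
IVP and EVP (TP = 0) shift every waveform rigidly — the simulated
counterpart of the compliance-chamber experiment — and the package
verifies this to machine precision.

## Calibration

Four lumped constants cannot be derived from the geometry: the total
resistance $R$ at 15 % occlusion, the compliance $C$, the termination
resistance $R_T$ at 15 %, and the forward amplitude scale $w_s$ (which
absorbs the difference between the idealised line and the real launch).
They are fixed by one deterministic Nelder–Mead least-squares fit in
log-space against the human-standard anchors at the standard
configuration — SBP 120 mmHg, DBP 80 mmHg, AIx 13.3 % — with a weak
quadratic pull toward the physical starting values to pin the direction
the three anchors leave free. The fitted values ship frozen in
`aortasim_defaults()`; `calibrate_simulator()` reproduces them. The
foot-to-foot wave speed is not an active anchor: it is fixed by material
and geometry alone (346 kPa, 2 mm, 21.8 mm, water give 6.506 m/s, within
the 0.05 m/s band around the 6.54 m/s target).

The reservoir pressurisation level (`ivp_offset`, 83 mmHg) is a
structural default, set just above the diastolic level the reservoir is
raised to in operation; the calibrated end-diastolic undershoot of about
3 mmHg then lands DBP at 80.

## Pulse-wave analysis

Preprocessing mirrors the acquisition chain: a 4th-order Butterworth
low-pass at 30 Hz applied forward and backward (`signal::filtfilt`), so
the DC gain is exactly one and no group delay shifts feet or peaks. The
signal is mirror-padded and mean-restored, so a constant input passes
through unchanged.

Beats are segmented by detected feet. Peak candidates are strict local
maxima above 40 % of the signal range; the beat period is estimated by
autocorrelation and only the highest candidate per 0.55 period survives —
necessary because a pronounced dicrotic hump can rival the systolic peak.
The foot is the per-beat lowest point preceding the upstroke (the
definition used for transit-time readings on the bench); an
intersecting-tangent alternative is available but off by default.
Transit time pairs each foot in the upstream record with the first later
foot in the downstream record within half a beat and averages over beats;
a non-positive delay (e.g. identical records) is an error. On simulated
records the measured PTT agrees with the analytic $L/c$ to well under one
sample.

Per beat, SBP/DBP are the extremum values, `map_integral` the true time
average, and `map_formula` the clinical $(\mathrm{SBP} +
2\,\mathrm{DBP})/3$ — the variant the device reports and the one the
sweep trends assert. AP is geometric: the pressure difference between the
systolic shoulder and the systolic peak, the shoulder being the
second-derivative zero crossing (5-point stencils on the filtered signal)
adjacent to the peak — the last crossing before it when one exists,
otherwise the first after it. A shoulder is only accepted if the waveform
shows a reflected wave at all: either a pre-peak inflection or a
post-peak re-rise of pressure within systole. With a matched termination
($\Gamma = 0$) the post-peak decay is monotone and AP is reported as
missing (`NA`), never as zero. AIx is $100\,\mathrm{AP}/\mathrm{PP}$
(the numeric convention matching the reported 5.3/40 = 13.3 %).

## Numerical choices

* **Sample rate** 4 kHz by default (8 kHz available). The limiting
  quantity is foot timing: the AA–AB transit is only 84.7 ms, so a 1 ms
  grid quantises PWV by ±0.08 m/s, comparable to the 0.05 m/s band of
  interest; at 4 kHz quantisation is ±0.02 m/s. All delays are
  implemented fractionally (linear interpolation), so the line length is
  not rounded to samples.
* **Beats** 10 per run with the first 7 discarded. Transients decay on
  two scales — the Windkessel (τ ≈ 0.25 s) and the reflection cavity
  (e-fold ≈ 0.14 s) — so 5.6 s of burn-in leaves the retained beats
  periodic to ~10⁻⁵ mmHg when the beat is a whole number of samples.
  When it is not (e.g. 70 BPM at 4 kHz), consecutive beats are sampled at
  slightly different phases and agree only to ~1 mmHg near the sharp
  valve transition; beat-averaged features are insensitive to this.
* **Valve switching** is classified with a quarter-sample guard so the
  boundary sample falls on the same side in every beat (naive `t %% T`
  flips by one ulp across beats).
* **Problem sizes.** The shipped test-and-sweep workload — the full
  grids: HR 60–100 by 10, SV 60–80 by 5, constant CO at 3.6 L/min,
  occlusion 5–25 % by 5 %, levels 40–120 by 20, TP 0–20 by 10 — is about
  30 ten-beat simulations and runs in well under a minute; a single
  standard run with feature extraction takes ~0.3 s.
* **Degenerate inputs** are errors with messages, not silent defaults:
  non-positive physical quantities, ν ≥ 1, occlusion = 1 (unbounded
  resistance), cutoff at or above Nyquist, negative TP, unstable
  reflection products, non-finite samples, records without one complete
  beat.

## The TP sweep and held MAP

Raising TP softens the wall, slows the waves (PTT 0.085 → 0.100 →
0.176 s over TP 0/10/20 mmHg) and pushes the reflected return out of
systole, deflating PP. The bench holds MAP at 93 mmHg during this sweep
without stating the control; the package models it as rescaling the
reservoir level after the softening is applied — for this model an exact
affine shift, applied in `run_sweep(kind = "tp")`. The TP = 10 transit
time (0.100 s) is the one place the simulation visibly departs from the
measured table value (0.108 s): it follows from the interpolated modulus
knot, which is itself not consistent with the wave-speed relation at a
fixed diameter (see above). TP = 0 and TP = 20 agree closely.

## What the tests do and do not show

All waveforms here are generated by the model itself; the test suite and
the sweep trends demonstrate internal consistency (oracle equivalences,
conservation, invariances) and that the calibrated model reproduces the
device's operating point and the *directions* of its parameter responses.
They do not validate magnitudes of the sweep responses (the bench
magnitudes depend on hardware details the lumped model does not carry),
and nothing here substitutes for measured pressure data: real recordings
have sensor noise, baseline drift and beat-to-beat variability that the
deterministic engine only mimics through the optional seeded noise
injection in `generate_fixture()`. The feature extractor is exercised on
such synthetic noise, but its robustness envelope on clinical-grade
signals is untested.

## Known limitations

* One effective conduit: the taper enters only through $D_\mathrm{eff}$
  and the simplified side branches are omitted entirely; intermediate
  sensors see the correct timing and qualitative PP amplification, but
  no local impedance steps.
* No viscous or viscoelastic wave damping; echo decay comes entirely from
  the terminal and root reflections and the termination lag.
* The ventricular pressure itself is not modelled (the drive is a flow
  source); ventricular diagnostics would be derived, not simulated.
* Strain-softening is quasi-static (pulse-averaged TP); within-beat
  modulus modulation is not modelled, consistent with using
  pulse-averaged quantities throughout.
* The brachial/radial periphery is out of scope; `cfpwv_to_apwv()` is a
  fixed 0.87 ratio, not a propagation model.
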