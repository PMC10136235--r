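---
title: "Modelling stenotic aortic valve hemodynamics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stenotic aortic valve hemodynamics: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`stenosim` couples three components through the cardiac cycle:

1. **A time-varying elastance left ventricle.** Ventricular pressure is
   generated by a prescribed periodic elastance acting on the volume above
   the dead volume, `P_LV(t) = E(t) (V(t) - Vd)`, with
   `E(t) = (Ees - Eed) E_N(t) + Eed`. `Ees` (mmHg/mL) is the contractility
   index (slope of the end-systolic pressure-volume relation), `Eed` the
   diastolic stiffness. `E_N` is a normalized curve with `E_N(0) = 0` and a
   maximum of 1 at the time of peak elastance `t_max`.
2. **A dynamic stenotic aortic valve.** The instantaneous transvalvular
   pressure gradient (TPG) is an inertial plus a turbulent term,
   `dP = L dQ/dt + beta Q |Q|`, with `L = rho l_eff / A_eff` and
   `beta = Kt (rho/2) (1/A_eff - 1/A_o)^2`. The effective orifice is
   `A_eff = A_mes * zeta(t)`; the valve state `zeta` in [0, 1] opens at rate
   `(1 - zeta) Kvo dP` for a non-negative gradient and closes at rate
   `zeta Kvc dP` otherwise. The solver advances `Q` from the gradient
   (rather than differentiating a measured flow) and enforces a diode rule:
   a closed valve facing a negative gradient carries no flow, so the model
   describes stenosis without regurgitation.
3. **A 1D arterial tree.** Each segment solves the cross-sectionally
   averaged continuity and momentum equations with an arctangent
   pressure-area wall law (maximal distensibility at the inflection
   pressure `P0`, width `P1`, asymptotic area `Amax`), a velocity-profile
   friction term `f = -2 (gamma_v + 2) pi mu Q / (rho A)` and an optional
   Kelvin-Voigt viscoelastic pressure term (default off: elastic walls).
   Branch points conserve flow exactly and keep total pressure
   (static + dynamic) continuous; terminal branches end in three-element
   Windkessel elements (`R1`, `R2`, `Ct`).

Numerics: a two-step (MacCormack) predictor-corrector per segment,
characteristic-based boundary closures, CFL-limited fixed time step
(default cap 0.25 ms, chosen so the valve ODEs remain well resolved), with
the heart period an integer number of steps. All internal arithmetic is
CGS; interfaces use clinical units (mmHg, mL, s), converted through
1 mmHg = 1333.22 dyn/cm^2. Simulations run cycle by cycle until stroke
volume and mean aortic pressure change by less than 0.1% between cycles.
Everything is deterministic: identical configurations reproduce waveforms
bit-identically.

# The normalized elastance stand-in

The published population-average normalized elastance curve is tabulated in
the primary literature, not distributable here, so the package uses a
smooth surrogate. The default is a half-cosine upstroke to the peak
followed by a cosine relaxation lasting `en_rel * t_max` (default 0.9):

```
E_N(t) = (1 - cos(pi t / t_max)) / 2                     t <= t_max
         (1 + cos(pi (t - t_max) / (en_rel t_max))) / 2  t_max < t <= (1 + en_rel) t_max
         0                                               later in the cycle
```

This tracks the published average curve's decay (about 0.85 of the peak
at 1.25 `t_max`, half near 1.5 `t_max`, fully relaxed by ~1.9 `t_max`)
and — crucially — relaxes *exactly* to zero within diastole, so the
diastolic stiffness floor equals `Eed` for every contractility and the
LVEDP input pins the end-diastolic volume at `LVEDP/Eed + Vd` throughout
the study's contractility range. A double-Hill product family
(`en = "hill"`, parameters `n1, n2, a1, a2`) is also implemented; its
power-law tail leaves a residual elastance of several percent of `Ees`
deep into diastole, which measurably impairs filling of strongly
contractile ventricles (at `Ees` above ~6 mmHg/mL the end-diastolic
volume collapses by tens of mL), so it is not the default.

The time of peak elastance defaults to `t_max = 0.375 T` (0.30 s at
75 bpm), matching measured human time-to-peak elastance (~0.32 s at
rest); this places end-systole near 0.45 s and yields gradients
consistent with the Bernoulli relation for the simulated valve area,
flow and ejection time (the waveform-level decomposition is checked in
the test suite).

Diastole is closed with a constant-pressure atrium behind a linear diode
resistance (default 0.005 mmHg s/mL). The paper-level input is the
end-diastolic pressure (LVEDP): the atrial pressure is auto-tuned each
cycle until the end-diastolic ventricular pressure matches the LVEDP
target within 0.2 mmHg, which also pins the end-diastolic volume at
`LVEDP/Eed + Vd`.

# Valve rate calibration and the opening-time margin

`calibrate_valve_rates()` finds the smallest rate coefficient on a
geometric grid (factor 1.25) for which the valve reaches the fully open
state (`zeta >= 0.999`) during ejection, with opening and closure
coefficients equal. At that minimum the orifice is still flow-limited for
roughly the first third of systole (about 90 ms to 90% open at the
baseline), which makes the effective area depend on flow — the
pseudo-stenosis regime — and adds roughly 20% to the mean gradient.

The sensitivity experiments, however, treat the valve area as a controlled
independent variable: a case labelled "AVA 0.6 cm^2" should actually
present that area to the flow. The sweep drivers therefore multiply the
calibrated minimal rate by a margin (`kvo_margin`, default 8), which
brings opening times into the echocardiographically observed 25-45 ms
range. The mean gradient is saturated in this regime (doubling the
margin moves the baseline mean TPG by only a few percent), so the margin
is not a sensitive tuning knob.

# Afterload: definitions, calibration, and its fixed point

Total vascular resistance (TVR) is mean aortic pressure over cardiac
output; structurally it is the parallel sum of the terminal `R1 + R2`
(plus a small contribution from viscous losses along the tree). Total
arterial compliance (TAC) is the sum of all vessel-wall compliances
`integral dA/dP dx` plus the terminal `Ct`; because the wall law is
pressure-dependent, TAC is a function of the operating pressure.
`SV/PP` (stroke volume over pulse pressure) is the clinical estimator and
serves as an initial guess; it is biased and, for weak ventricles, cannot
be driven to an arbitrary target, so it is not used as the calibration
closure.

`calibrate_case()` iterates: simulate to periodic steady state, measure
achieved TVR = MAP/CO and achieved TAC = aggregate compliance at the
achieved MAP, rescale terminal resistances and (vessel + terminal)
compliances toward the targets, and repeat until both are within 1%
(at most 10 outer iterations, with per-iteration correction factors
clamped to [0.5, 2] for stability). This re-iteration is required because
any change in the ventricle moves the operating pressure and therefore the
pressure-dependent TAC. Compliance rescaling re-solves each segment's
width pressure `P1` so local compliance at the reference pressure scales
exactly; the arctangent law has a maximum attainable compliance for a
fixed inflection pressure, beyond which the remainder is carried by the
terminal compliances so the aggregate stays exact.

# The synthetic arterial tree

The unpublished reference geometry cannot be shipped, so
`synthetic_tree()` builds a plausible systemic tree from textbook
dimensions: an eight-piece tapering aorta (root area 5.3 cm^2), carotid,
subclavian/brachial, celiac, mesenteric, renal and iliac/femoral branch
paths (24 segments, 12 terminals; a 103-segment variant subdivides the
same skeleton). Reference wave speeds rise from 4.8 m/s at the root to
~9 m/s distally (normal-adult values); the wall-law inflection pressure is
80 mmHg; about two thirds of the total compliance resides in the vessel
walls (the physiological distribution) and the remainder in the terminal
compartments. Terminal resistances are distributed inversely to terminal
cross-section, with `R1` matched to the terminal segment's characteristic
impedance to limit spurious reflections. Small seeded log-normal jitter
(sigma 2%) on lengths and areas makes each seed a distinct but equivalent
"patient"; all physics is deterministic given the geometry. The packaged
`tree24.csv` is seed 7 and is labelled non-anatomical in its header.

What the synthetic tree does *not* emulate: anatomical branching detail
(it has 12 terminals, not ~50), cerebral and coronary beds, vessel
curvature and tapering laws fitted to imaging, and any wave-reflection
fine structure of a real arterial tree. Results that depend on aggregate
afterload (the sensitivity directions, calibration fixed points,
conservation properties) transfer; quantitative gradients on a different
geometry are expected to shift by tens of percent, which is why
reproduction of published effect sizes is assessed with wide tolerances.

# The sensitivity study

`default_sweeps()` encodes the study design: each determinant varied over
its physiological range (Ees 0.5-6 mmHg/mL, Eed 0.03-0.31 mmHg/mL,
TVR 0.6-1.8 mmHg s/mL, TAC 0.5-2 mL/mmHg) in 10 evenly spaced values at
four AVA levels (0.6, 1.0, 1.5, 2.0 cm^2; 160 cases), all other
parameters held at baseline, plus 40 coupled-afterload cases where TAC is
tied to TVR along the hyperbola `TAC = (TVR_0 TAC_0) / TVR` (the two do
not vary independently in vivo; the constant is exposed since its
published value is not printed).

The baseline (held-fixed) operating point is anchored to the invasively
characterised validation patient — Ees 3.3, Eed 0.1 mmHg/mL, LVEDP
11 mmHg, Vd 39.3 mL — with afterload TVR 1.2 mmHg s/mL and TAC 1.1
mL/mmHg (mid-range of the sweep intervals) and heart period 0.8 s with
`t_max = 0.375 T`. Heart period and `t_max` are assumptions (the source
study does not state them) and are plain configuration values.

Effects are summarised by OLS (`stats::lm`) of mean TPG on the
determinant: the slope per natural unit with its standard error and
two-sided t-test p-value (n - 2 df), and the slope per 10% increase of
the determinant, scaled by the determinant's *baseline operating value*
(`beta * 0.1 * baseline`). Scaling by the baseline value — rather than by
the lowest sweep value — is the convention under which the per-unit and
per-10% effect sizes of the reference study are mutually consistent, and
it is the natural reading of "effect of a 10% increase" around the
operating point.

Mean TPG is averaged over the ejection window, defined as the longest
contiguous interval with the valve open (`zeta` above its floor) and
forward transvalvular flow; the averaging window is a modelling choice
since gradients are only defined during ejection.

# Numerical and degenerate-input choices

* `zeta` floor `1e-4`: keeps inertance and the Bernoulli coefficient
  finite through valve closure; combined with the diode rule it yields
  regurgitation-free closure.
* Initialization: tree uniformly pressurized at 80 mmHg, zero flow,
  valve closed, ventricle at its end-diastolic volume. Convergence to the
  periodic cycle typically takes 6-10 cycles from cold and 2-4 warm.
* Junction iteration: fixed-point on the dynamic-pressure corrections,
  under-relaxed (0.5), converged to 1e-10 relative; non-convergence after
  200 iterations aborts with the segment and time.
* Negative areas, CFL violations and ventricular volume below the dead
  volume abort with diagnostics rather than continuing silently.
* A ventricle too weak to open the valve produces a flagged degenerate
  summary (no ejection window) rather than an error.
* Problem sizes: the default spatial step is 1 cm (about 300 nodes on the
  24-segment tree) and the default time-step cap 0.25 ms; halving the
  time step changes stroke volume and mean TPG by under 0.5%, halving
  the spatial step by under 1%. The packaged sensitivity batteries use
  these defaults with a 0.4 ms cap, a resolution chosen after verifying
  it reproduces the finer-step summaries within a fraction of a percent.
* A case whose advective velocity outruns the automatic step's CFL
  margin (possible at the extreme low-stiffness corner of the diastolic
  sweep, where end-diastolic volumes are very large) is retried with a
  1.5-fold finer step rather than aborted.

# Known limitations

* No baroreflex or autoregulation: parameter changes do not recruit
  compensatory responses, by design (isolated-effect quantification).
* No atrial mechanics, mitral dynamics, right heart or pulmonary loop.
* No regurgitation, no leaflet mechanics, no sinus vortices, no viscous
  valve losses; the valve is the two-term gradient model throughout.
* The absolute gradient level follows the two-term valve relation for
  the simulated valve area, flow and ejection time. Published effect
  sizes from other implementations depend on their (unpublished)
  geometry and elastance tabulation; effect *signs*, orderings across
  AVA levels and interaction structure are robust to those differences,
  while per-unit magnitudes can shift by tens of percent. In particular,
  with afterload calibrated at fixed mean pressure, a compliance change
  moves diastolic and systolic load in opposite directions and its net
  effect on the gradient is sensitive to wave-reflection timing, i.e. to
  the tree geometry.
* Stroke volume is reported as the forward (Doppler-equivalent) ejected
  volume; the small reverse closing volume (1-2 mL at the default valve
  rates) is excluded, mirroring echocardiographic practice.
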