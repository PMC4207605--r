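---
title: "Models and measures for rhythmic cup-and-ball manipulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and measures for rhythmic cup-and-ball manipulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cupball` analyses a rhythmic object-manipulation task: a subject moves a
"cup" horizontally while a "ball" swings inside it, and the question is which
movement strategies make the object's dynamics predictable, effortful, or
smooth. This vignette documents the model, the estimators, the numerical
choices and the limitations; the README shows a worked example.

## The object model

The object is a cart-pendulum: the cup is a point mass `m_cup` on a
horizontal line, the ball a point mass `m_ball` on a rigid rod of length `l`
suspended from the cup, under gravity `g`. Defaults are
`model_params()`: 0.6 kg, 2.4 kg, 0.25 m, 9.81 m/s². Sign conventions:
cup displacement `x` is positive to the right; the ball angle `theta` is
positive when the ball is displaced opposite to positive cup displacement,
so anti-phase coordination (ball left while cup is at its right peak) has
`theta > 0`.

The ball obeys

    l theta'' = x''(t) cos(theta) - g sin(theta),

so for a *prescribed* cup trajectory the ball is a driven pendulum whose
input is the cup acceleration; the applied force does not enter. The ball
angle is unconstrained: full rotations are allowed (in the original task
display the ball cannot leave the cup, but that is a rendering property,
not a mechanical constraint).

### Force conventions

Two conventions for the applied (hand) force are implemented:

* **rendered** (default):
  `F = (m_cup + m_ball) x'' + m_ball a_ball`, where
  `a_ball = x'' - l (theta'' cos theta - theta'^2 sin theta)` is the ball's
  horizontal acceleration. Eliminating `theta''` with the ball equation
  gives the closed form
  `F = x'' (m_cup + m_ball + m_ball sin² theta) + m_ball sin(theta) (g cos theta + l theta'^2)`.
  This convention treats the hand as carrying the full translational
  inertia of the object *plus* the pendulum reaction, as a haptic rendering
  of the object on a manipulandum does. It is the convention under which
  the period-1 strategy (10 cm peak-to-peak, 1 Hz, `theta0 = 1` rad)
  strobes a constant force of -4.1 N — the anchor that fixes both the
  force model and the time-origin convention (see below). All strategy
  measures use it by default.
* **lagrangian**: `F = m_cup x'' + m_ball a_ball`, the textbook
  cart-pendulum hand force (coefficient
  `m_cup + m_ball - m_ball cos² theta` in the closed form). It differs
  from the rendered convention by exactly `m_ball x''(t)`, conserves
  mechanical energy when `F = 0`, and its force-free linearisation
  oscillates in the anti-phase mode analysed below.

`forward_simulate()` inverts whichever convention produced the force, so
inverse dynamics followed by forward dynamics reproduces the prescribed cup
trajectory to integrator accuracy under either convention. Tests assert
the round trip at 1e-4 m over 45 s.

### Time origin and execution variables

A strategy is four scalars: peak-to-peak cup amplitude `A`, cup frequency
`f`, and the ball state `(theta0, omega0)` at a reference time. The cup is
modelled as the peak-aligned cosine `x(t) = (A/2) cos(2 pi f t)`, so `t = 0`
is a positive cup peak — the same event at which experimental trials are
strobed. This makes simulated and experimentally strobed ball states
directly comparable. Exactly one of the two candidate time origins
(peak-aligned cosine vs zero-crossing sine) yields a constant strobed force
at the period-1 anchor strategy; the peak-aligned convention is the one
that does, and the test suite asserts it.

### Linear vibration modes

`linear_mode_analysis()` linearises the *conservative* free object about
hanging equilibrium. It has a zero-frequency rigid-translation mode and one
oscillatory anti-phase mode at
`f = sqrt((g/l)(1 + m_ball/m_cup)) / (2 pi)` (1.11 Hz at the defaults).
Because the centre of mass is stationary in free oscillation and the
ball's horizontal excursion is bounded by the rod length, the largest
force-free peak-to-peak cup amplitude is `2 l m_ball / (m_ball + m_cup)`
(10 cm at the defaults) — far below typical task amplitudes, which is what
rules the free-oscillation mode out as an explanation of observed
behaviour.

### Integration

All prescribed-cup and forward simulations use deSolve's adaptive `lsoda`
at `rtol = atol = 1e-8`, resampled on a uniform 120 Hz output grid (the
experimental recording rate). Simulated trials last 45 s — one experimental
trial — and no transient is discarded: the simulation is the object's
behaviour from the chosen initial condition onward. Integrator failures
raise errors carrying the solver's diagnostics; in grid sweeps they are
logged per cell instead of aborting the sweep.

## Stroboscopic analysis

`strobe_at_cup_peaks()` samples force and ball states once per cycle at the
positive cup-position maxima (a Poincaré section; minima are not strobed).
For trajectories generated from a strategy the peak times are analytic
(`t = k/f`, including `t = 0` and, for whole-period durations, the final
peak — a 45 s, 1 Hz trajectory has 46 strobes); recorded trials use the
numeric peak detector described below. `bifurcation_scan()` repeats this
over a grid of initial ball angles, exposing the period-1 branch
(zero strobe variance), quasi-periodic bands (bounded scatter, ~5 N wide at
`theta0 = 0.4`), and chaotic scatter (tens of newtons near
`theta0 = -1.35`). `find_period1_strategy()` Newton-refines the exact
period-1 fixed point of the strobe map; it is the ground truth used by the
parameter-recovery tests.

## Strategy measures

### Mutual information

`mutual_information(force, phase)` estimates
`MI = ∫∫ p(F, φ) ln[p(F, φ) / (p(F) p(φ))] dF dφ` in nat. The joint
density is a product-Gaussian kernel estimate evaluated on a 128×128 grid
spanning `[min F - 3h, max F + 3h]` × `[0, 2π)`; phase circularity is
handled by replicating samples at `φ ± 2π` so kernel mass wraps across the
cycle boundary; marginals are numerical integrals of the grid-normalised
joint, which makes the estimate a discrete Kullback–Leibler divergence and
therefore exactly non-negative; integration is trapezoidal in force and
periodic-rectangular in phase.

Bandwidths follow Silverman's rule of thumb, with one deliberate choice:
the force dimension uses the *cycle count* as its effective sample size,
`h_F = 0.9 min(sd, IQR/1.34) n_cycles^{-1/5}`. Within a cycle the force
samples are near-deterministic functions of the phase — they are not
independent draws, and the independent information about the force
distribution enters once per cycle. With raw-sample bandwidths the MI
surface over the result space is dominated by a monotone amplitude trend
(the marginal force entropy grows with amplitude while the conditional
scatter stays bounded) and loses the chaotic-versus-periodic structure
that the strobe-variance and Lyapunov measures show. With the
cycle-effective bandwidth the MI surface recovers that structure and its
range over the default map is a few tenths of a nat. The phase dimension
keeps the raw-sample Silverman bandwidth: phase is a deterministic uniform
sweep whose coverage genuinely refines with every sample. A constant force
series has no definable density; MI is 0 by convention, with a warning.

The estimator is deterministic given its inputs, invariant under affine
rescaling of the force (bandwidth and grid co-scale), and calibrated
against shuffled surrogates: the tests require MI of an independent
surrogate to fall below the 95th percentile of 100 shuffles and the MI of
structured data to exceed it.

### Predictability index

`predictability_index(strobe, normalizer)` is
`1 - Var(strobed force) / normalizer`, clipped to [0, 1]: 1 for a
perfectly repeatable (period-1) strategy, 0 when the strobe scatter
reaches the reference variance. On result-space maps the package
normalises by each strategy's *own* continuous-force variance — relative
cycle-to-cycle scatter. The alternative, normalising every cell by the
map's largest strobed-force variance, makes the index saturate near 1 over
the entire regular half-plane (chaotic variances are orders of magnitude
larger) and destroys its concordance with MI; with the per-strategy
normaliser the two predictability surfaces rank-correlate strongly, which
is the cross-validation the index exists for.

### Sensitivity

`mi_sensitivity()` perturbs frequency, amplitude and initial ball angle by
±10% of their standard ranges (0.04 Hz, 3.6 cm, π/10 rad; the initial
angular velocity is left out — its influence on the measures is minor and
it doubles the cost), recomputes MI for each of the six perturbed
strategies, and reports the largest `|ΔMI|` in units of 10% of the map's
MI range. Values above 1 mean the MI change exceeds 10% of the range.
Perturbations that leave the simulable domain are skipped with a warning.
A limitation: under this package's MI estimator the sensitivity surface is
*largest near the anti-phase MI ridge* (where the MI gradient is steep)
rather than in the chaotic region (where whole-trajectory KDE MI is smooth
in the execution variables), so sensitivity comparisons between regions
should be interpreted with that in mind.

### Global Lyapunov exponent

`global_lyapunov()` is the largest finite-time Lyapunov exponent of the
two-state driven ball subsystem. The reference trajectory is integrated at
tolerance 1e-8; a tangent vector is propagated through the variational
dynamics with Jacobian `J = [[0, 1], [(-x'' sin θ - g cos θ)/l, 0]]` in
renormalised 0.01 s steps (classical Runge–Kutta on the linearised system,
using reference states at half-step resolution), accumulating
`λ = (1/T) Σ ln(growth)`. The exponent is computed separately from initial
unit vectors along the angle and angular-velocity directions and the
larger is reported (both are attached as an attribute). The default
horizon is 60 s. Finite-horizon estimates of neutral systems carry a
positive bias of order `ln(ω)/T` (the tangent flow of a conservative
oscillator is bounded but not contracting), so the zero-exponent property
of the undriven pendulum is verified at a 120 s horizon, where the bound
is comfortably below 0.02 s⁻¹. Horizons below 10 s are rejected as
unreliable.

### Effort and smoothness

`mean_squared_force()` is the time average of `F²` (N²) over the series —
the signal-power proxy for mechanical effort. `mean_abs_jerk()` takes the
third derivative by central differences and averages its absolute value;
two dimensionless normalisations are available:

* **peak**: divide by the trial maximum `|jerk|`. Any pure sinusoid of any
  amplitude and frequency gives `mean|cos|/max|cos| = 2/π`, which is the
  calibration the tests assert to 1e-3.
* **cycle_amplitude**: divide by the jerk amplitude implied by the
  signal's excursion at the cycle frequency,
  `(max s - min s)/2 · (2πf)³`. A sinusoid at the cycle frequency again
  gives `2/π`. Result-space maps use this variant for the normalised ball
  jerk: chaotic ball trajectories contain isolated jerk spikes that make
  the peak denominator a near-arbitrary single sample, turning the map
  surface into a plateau of ties, while the excursion-based denominator is
  stable. One caveat: a chaotic ball that circulates accumulates angle, so
  its excursion can exceed one rotation; steady circulation then counts as
  smooth (small normalised jerk), which is also what makes the in-phase,
  large-amplitude region the smoothness optimum.

`spectral_arc_length()` is the (negative) arc length of the normalised
Fourier magnitude spectrum up to an adaptive cutoff — the highest
frequency below 20 Hz where the normalised magnitude still exceeds 0.05 —
with the frequency axis normalised by that cutoff and 4× zero padding.
Values are ≤ 0; closer to zero is smoother. The measure is invariant to
amplitude scaling and decreases as broadband noise is added; at very small
added noise the change is dominated by spectral leakage of the harmonic
itself and is not strictly monotone, so the monotonicity test uses
well-separated noise levels.

## The result space

`evaluate_result_space()` sweeps the `(A, theta0)` plane at fixed
frequency (1 Hz) and initial ball velocity (0) — the two variables the
experimental task pins down — simulating 45 s per cell and evaluating the
requested measures. The default grid is 37 × 33 (1 cm × ~0.1 rad); the
package's acceptance checks use a 20 × 20 grid of the same extent, which
evaluates in a few minutes on one CPU. Failed cells are `NA` with a logged
reason; a plain-text cache file makes sweeps resumable. `locate_optima()`
returns the grid arg-optimum of each selection criterion (maximum MI,
minimum mean squared force, minimum Lyapunov exponent, minimum normalised
ball jerk), breaking ties toward larger amplitude and then larger ball
angle; `map_lookup()` interpolates surfaces bilinearly and clips
out-of-domain queries to the boundary with a warning.

On the default conditions the four optima fall in mutually distinct
regions — maximum predictability at large amplitude and anti-phase angles,
minimum force at small amplitude near `theta0 ≈ 1`, minimum Lyapunov
exponent at anti-phase angles between π/4 and π/2, maximum smoothness at
in-phase angles — which is the dissociation that makes the task able to
discriminate between selection criteria.

## The experimental pipeline

`detect_cycle_peaks()` locates cycle maxima and minima: the signal is
low-pass filtered for detection (zero-phase Butterworth, cutoff five times
the nominal cycle frequency, mirror-padded so boundary extrema survive the
filter), candidate extrema closer than half a nominal period keep only the
most extreme, maxima and minima are forced to alternate, a prominence rule
discards wiggles below 25% of the running peak-to-peak amplitude, and
times/values are refined by parabolic interpolation. A record that merely
ends mid-rise does not fabricate a boundary peak: boundary samples only
count when they come within 5% of the local extreme level.

`estimate_execution_variables()` strobes each trial at its cup-position
maxima: per-cycle frequency from peak intervals, per-cycle amplitude as
the peak-to-trough excursion of the full cycle, ball angle and angular
velocity interpolated at each maximum. When a velocity channel is absent
it is derived by zero-phase low-pass filtering (4th-order Butterworth,
10 Hz — the recordings' derivative content is far below that) followed by
fourth-order central differences. Window means use the cycles whose strobe
time lies in the closed 25–45 s window (transient-free late practice; a
peak at exactly 45 s counts, and an exact 1 Hz peak-aligned trial has 21
window cycles); fewer than 5 window cycles raises a warning flag.

`trial_strategy_measures()` computes the measure set from continuous
recordings: MI between the raw force and a cup phase interpolated linearly
from 0 to 2π between successive maxima (an analytic-signal phase is
available as an alternative), mean squared force of the whole force
channel, and smoothness on cycle-averaged profiles — each cycle spline-
resampled to a common length (linear resampling would add interpolation
kinks that a third derivative amplifies), averaged, circularly padded
(the averaged cycle is periodic) and low-pass filtered with odd-reflection
padding before jerk and spectral arc length. `map_lookup_measures()`
returns the simulated counterparts by bilinear lookup of a result-space
map at the trial's mean execution variables.

`early_late_comparison()` contrasts the first and last five trials of each
subject with a two-sided paired t-test across subjects (α = 0.05 and 0.10
both reported); identical early/late values give the degenerate `t = 0`,
`p = 1`. `asynchrony_stats()` matches each metronome beep in the 20–45 s
window to the nearest cup extremum and summarises the signed differences;
`asynchrony_amplitude_correlation()` is the pooled per-trial correlation
helper.

## The synthetic cohort generator

The generator exists so the whole pipeline is testable without human
recordings; it emulates the statistical structure of practice data and
explicitly does *not* model any human controller.

Per subject, `strategy_schedule()` draws a per-trial target: the amplitude
follows an exponential learning curve from 21.45 cm to 28.03 cm
peak-to-peak with a 12-trial time constant (the early/late group values
and the saturation around trial 30 that the emulated protocol shows),
plus a between-subject offset (SD 3 cm) and trial-to-trial jitter
(SD 1.5 cm); the ball starts near an anti-phase target of 0.95 rad
(jitter 0.12 rad), except in chaotic episodes — probability 0.35 on trial
1, decaying with the learning timescale — where it starts in-phase around
-1.1 rad and the object behaves chaotically, as early-practice recordings
do. `generate_synthetic_subject()` realises each trial by forward
simulation of the full cart-pendulum under proportional-derivative
tracking of the target sinusoid (gains 6000 N/m and 200 N·s/m, fixed-step
RK4 at 8 substeps per 120 Hz frame, all of a subject's trials integrated
as one vectorised batch) with white motor noise (SD 1 N) held constant
within each frame, then adds Gaussian sensor noise to the recorded cup
position (2 mm) and ball angle (0.01 rad). Metronome beeps run at twice
the cup frequency. All randomness derives from one seed per subject,
derived in turn from the cohort seed; runs are bit-reproducible, and the
generator restores the caller's RNG state.

What the generator does *not* emulate: human corrective control (the PD
tracker is plumbing — real subjects correct intermittently and
anticipatorily), within-trial drift of the intended strategy, delays or
coloured noise, and ball-state selection by the subject (the ball state is
set at trial start and then evolves passively). Pipeline tests passing on
synthetic cohorts therefore validate the estimators and statistics, not
any claim about human motor learning.

Noiseless trials built by `generate_clean_trial()` from the Newton-refined
period-1 fixed point round-trip all four execution variables through the
pipeline to better than 1e-3, and the type-I error of the early/late
contrast is calibrated at the schedule level (1000 zero-learning
replicates reject at ≈5%); the power of the default learning effect is
exercised on one full-dynamics cohort.

## Numerical choices and degenerate inputs

* Integrator tolerances 1e-8 (relative and absolute) everywhere; the
  period-1 fixed-point refinement uses 1e-11 for its return map.
* Trajectory validity is checked algebraically: substituting all stored
  channels into the closed-form force equation leaves residuals below
  1e-6 N for package-generated trajectories. The ball equation can only be
  checked by differentiating the stored angular velocity, which is
  finite-difference limited (~1e-4 rad/s² at 120 Hz); inverse dynamics
  uses it as a consistency gate at tolerance 1e-3 before filling a force
  channel.
* Zero-phase filtering pads by odd reflection (value- and
  slope-continuous) for generic channels and by mirror reflection
  (extremum-preserving) inside the peak detector.
* Degenerate inputs have defined behaviour: zero-amplitude strategies are
  valid (undriven pendulum); constant signals give zero jerk, an error for
  the spectral arc length (no spectrum to normalise), an error for peak
  detection, and MI 0 with a warning; empty force series and non-uniform
  time grids are rejected.
* Ties in `locate_optima()` break toward larger amplitude, then larger
  ball angle.

## Known limitations

* The rendered force convention is anchored to the period-1 strobed-force
  value; it is not the Lagrangian hand force (the two differ by
  `m_ball x''`), and only the Lagrangian variant conserves energy.
* MI values are estimator-conditional: bandwidth policy changes absolute
  values substantially (the map *pattern* is the robust object, and the
  calibration properties pin the estimator down). Comparisons with MI
  values from other estimators should be made on ranks, not levels.
* The sensitivity measure inherits the MI estimator's smoothness across
  the chaotic region (see above).
* The cycle-amplitude jerk normalisation treats steady ball circulation
  as smooth; for bounded-swing signals it coincides with the usual
  amplitude normalisation.
* No friction, damping, rod elasticity or 3-D dynamics; the model is the
  planar rigid cart-pendulum throughout.
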