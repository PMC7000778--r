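---
title: "Spring-mass analysis of treadmill sprinting: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spring-mass analysis of treadmill sprinting: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slipgait)
```

## The measurement chain

`slipgait` turns raw treadmill force-plate recordings of sprint running
into the quantities used to compare running-specific prosthesis (RSP)
configurations in athletes with a unilateral transtibial amputation:
spatiotemporal step metrics, spring-mass leg stiffness, and between-leg
symmetry indices. The chain is:

1. **Filtering.** Ground reaction forces (GRFs, 1000 Hz) are low-pass
   filtered with a 4th-order zero-phase Butterworth filter at 30 Hz —
   implemented, as is standard in gait analysis, as a 2nd-order design
   run forward and backward, which cancels phase shift and doubles the
   magnitude order. Marker trajectories (200 Hz) are filtered the same
   way at 7 Hz. R's `signal::filtfilt` does not condition its start-up
   state, so the series is padded by odd reflection at both ends and
   trimmed after filtering; this keeps the DC gain exactly 1 on real
   traces.
2. **Contact detection.** Stances are maximal runs of filtered vertical
   GRF at or above 30 N. Aerial gaps shorter than 20 ms are merged and
   contacts shorter than 50 ms discarded; sprint contact times
   (~0.10–0.15 s) and aerial times (~0.05–0.35 s) leave a wide margin
   around both guards. Intervals are half-open (`[onset, offset)`), so
   stance plus aerial samples partition the trace and step time is
   exactly contact time plus subsequent aerial time.
3. **Leg labelling.** Legs strictly alternate on a treadmill; labels
   are seeded by the configured first-contact leg. When markers are
   present, a consistency check asks which leg's marker rides the belt
   during each stance and warns if it disagrees.
4. **Step metrics.** For each stance with a following stance: contact
   time `t_c`, aerial time `t_a`, step time `t_step = t_c + t_a`, step
   frequency `1/t_step`, contact length `L_c = v * t_c` with `v` the
   belt velocity, stance-average vertical GRF (also in body weights,
   `g` = 9.81 m/s²), peak vertical GRF, and peak resultant GRF from all
   three channels.
5. **Spring-mass estimates.** Per stance:
   contact angle `theta = asin(v * t_c / (2 * L0))`; vertical
   centre-of-mass (CoM) drop `delta_y` by twice integrating
   `a = f_v/m − g` over one stride with the steady-running closure
   (mean vertical velocity zero over the stride), read
   touchdown-to-minimum within the stance; leg compression
   `delta_L = delta_y + L0 (1 − cos theta)` (McMahon–Cheng); leg
   stiffness `k_leg = peak vGRF / delta_L` in kN/m; and, for the
   affected leg, prosthesis displacement
   `delta_RSP = peak resultant GRF / k_RSP`. The affected leg's length
   is measured to the distal end of the unloaded prosthesis, the
   unaffected leg's to the floor; the leg tag on every stance keys the
   lookup so the two can never be swapped.
6. **Symmetry.** For each variable, the symmetry index
   `SI = (AL − UL) / (0.5 (AL + UL))` is computed from the per-leg
   *trial means* (not per-step SIs averaged): the trial summary is the
   level at which legs are compared. SI is 0 at perfect symmetry,
   positive when the affected-leg value is larger, and bounded in
   (−2, 2) for positive variables.
7. **Statistics.** Trial-level outcomes across configurations are
   analysed with linear mixed models (subject random intercept;
   prosthesis model categorical; stiffness, height and velocity
   continuous), delegated to `lmerTest::lmer`. One-sample t-tests
   compare SI samples against zero, Bonferroni corrections use
   `min(1, p·m)`, and percent differences between configuration means
   are expressed relative to the slower configuration, rounded to one
   decimal for reporting.

## Trial validity

A maximum-velocity trial counts only if the athlete completes at least
8 strides while holding station on the treadmill. Station keeping is
judged from the fore-aft marker position at successive touchdowns with
a default drift limit of 0.3 m — the criterion is qualitative in
origin, and 0.3 m is roughly a third of a treadmill deck. Without
markers a coarse fallback estimates drift from the net fore-aft GRF
impulse and says so.

## The synthetic-data generator

Real sessions from the underlying study are not deposited, so the
package carries a generator that produces sessions with known ground
truth. Running is modelled as a spring-loaded inverted pendulum (SLIP):
a point mass `m` on a massless linear leg spring of stiffness `k` and
natural length `L0`, with stance governed by spring force plus gravity
and flight ballistic. The two legs may differ in `k`, `L0` and
touchdown angle. The model is conservative; total mechanical energy is
therefore an integration diagnostic, and the test suite requires drift
below 0.01% over 20 strides (measured drift is orders of magnitude
smaller).

Steady gait is a fixed point of the apex-to-apex return map over one
full stride (one step of each leg). Because energy is conserved, the
apex is parameterised by height alone — forward velocity follows from
the energy budget — and the fixed point is a 1-D root-bracketing
problem solved with `uniroot` to a residual below 1e−6 m. Stance
dynamics are integrated with `deSolve::lsodar` at `rtol = atol = 1e−11`
with the takeoff event (leg back at natural length) located by the
integrator's root finder; output is interpolated onto the 1000 Hz
force grid from a 0.1 ms dense grid that includes the exact grid
times. Flight phases use the ballistic closed form.

Sessions are written in the treadmill frame: the CoM is near
stationary and the belt moves backward at the realised stride-average
forward velocity, which is also what the config reports as belt
velocity. Marker traces ride the belt during their own leg's stance
and swing forward along a smooth cosine ease between contacts.
Gaussian sensor noise (default 5 N on every force channel — the
medio-lateral channel is pure noise — and 1 mm on markers) is added
from a single master seed, so generation is bit-reproducible.

**Default study conditions.** The defaults emulate a sprint trial of a
75 kg athlete near 8 m/s: affected leg `L0` 1.02 m (2 cm taller than
the unaffected 1.00 m, the usual prosthesis-height convention),
stiffness 18 vs 22 kN/m, touchdown angles 0.54 vs 0.52 rad. At the
periodic gait this produces an affected-leg stance-average vertical
force about 6% below the unaffected leg, contact-time SI near +0.09
and stiffness SI −0.20 — asymmetry directions and magnitudes in line
with published treadmill sprinting of athletes with a unilateral
amputation. These values were chosen once, from a parameter sweep for
gait existence and realism, and are not adjusted per analysis.

**What the generator does not emulate.** Real GRFs have impact
transients, asymmetric loading/unloading shapes (especially for the
unaffected leg), soft-tissue and treadmill vibration, and belt-speed
fluctuation; markers have soft-tissue artefact. Passing the recovery
tests therefore shows the estimation chain is correct for spring-mass
gait with additive white noise — not that spring-mass assumptions hold
for any particular athlete.

## Numerical choices and known biases

- **Event widening.** The 30 Hz zero-phase filter spreads the sharp
  force onset symmetrically, so detected stances start a few
  milliseconds before true touchdown and end after true takeoff. On
  noiseless simulated sprinting this inflates contact time by roughly
  6–8%, hence the contact angle and the CoM drop (the stride window
  opens while the CoM is still descending), and deflates the
  stance-average force; the net effect is a systematic *underestimate*
  of leg stiffness, up to about 14% at the default sprint conditions
  (the acceptance suite recomputes this number). This bias is a
  property of the standard filter-then-threshold measurement chain
  itself, which the package reproduces deliberately; comparisons
  between legs or configurations, which share the bias, are affected
  far less — the recovered force-asymmetry SI is within 0.01 of ground
  truth.
- **Double integration.** With the window taken at the true stride
  boundaries, the trapezoidal double integration with zero-mean
  velocity closure matches the simulator's CoM excursion to better
  than 1%; the 5% tolerance asserted in the tests is generous.
- **Belt-speed check.** The 7 Hz marker filter needs tens of
  milliseconds to settle, so the belt-speed estimate uses the mean
  |marker velocity| over the central half of each stance; on simulated
  sessions it lands within about 1.5% of the true belt speed. It is a
  quality-control channel only — the contact angle and contact length
  always use the configured belt velocity.
- **Degenerate inputs.** Zero-variance SI samples, single-subject
  cohorts, rank-deficient fixed designs, non-steady strides (mean
  vertical force off body weight by >15%), and contact geometries with
  `v t_c > 2 L0` all raise typed errors rather than returning numbers.

## Design choices where the design was open

- "4th-order Butterworth" is read as 2nd-order applied twice
  (zero phase), the standard biomechanics interpretation; a causal
  single-pass design of the full order is available via
  `zero_phase = FALSE` for sensitivity analyses.
- `delta_y` is defined touchdown-to-minimum, not apex-to-minimum,
  because the McMahon–Cheng compression formula adds the stance-phase
  drop below touchdown height to the geometric term `L0 (1 − cos θ)`.
- Trial-level step frequency is the mean of per-step frequencies (not
  the reciprocal of the mean step time); for the near-periodic strides
  of a steady trial the two differ negligibly, and the choice is
  exposed by keeping both `t_step` and `f_step` in the records.
- The reference level for prosthesis-model contrasts is the model with
  the slowest group-mean maximum velocity, so faster models appear as
  positive coefficients and positive percent differences.
- The prosthesis displacement `delta_RSP` is computed and reported per
  affected-leg stance but feeds nothing downstream.
- An optional per-leg energy-loss factor at takeoff (mimicking
  prosthesis hysteresis) was considered and deliberately left out of
  the conservative simulator: it breaks the energy diagnostic that
  anchors the physics tests, and none of the estimation chain needs it.

## Problem sizes

The test suite and acceptance script use sessions of 5–20 strides,
a 5-point stiffness sweep (12–18 kN/m, symmetric legs, α = 0.55 rad,
8 strides each, noiseless), 10⁴ random pairs for the SI properties,
and 200 replicate cohorts (8 subjects × 9 configurations) for the
mixed-model size check — sizes at which every quantity the suite
asserts is stable to well inside its tolerance.

## Worked example

```{r example, eval = FALSE}
p <- slip_params(n_strides = 10, seed = 42)
dir <- tempfile("session")
generate_session(p, path = dir)     # forces.csv, markers.csv, config, truth.csv
fit <- analyze_session(dir)
print(fit)
coef(fit)                           # two-leg average of every metric
fit$si                              # symmetry indices
write_results(results_table(fit), file.path(dir, "results.csv"))
```
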