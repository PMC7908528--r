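---
title: "Two-point force-velocity profiling: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-point force-velocity profiling: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fvtp)
```

## The model

Maximal multi-joint efforts are well described by a linear force-velocity
relationship, `F(v) = F0 − a·v`. `fvtp` stores a profile as the
parameter set (F0, V0, a, P0) with the invariants `a = F0/V0` and
`P0 = F0·V0/4`; the power-velocity curve `P(v) = v·F(v)` is a downward
parabola with its apex at `v = V0/2`, which is where P0 lives. The slope
is kept as a positive magnitude because that is how practitioners quote
it; the regression coefficient of force on velocity is `−a`.

The two-point method measures one `(Fmax, Vmax)` point under each of two
load conditions and passes a line through them (`fit_two_point()`). With
two points this *is* the least-squares solution, a fact the test suite
checks against an independent linear solve over 10,000 random
configurations. `fit_linear()` generalises to any number of load
conditions via ordinary least squares and collapses to the closed form at
n = 2.

Within one jump trial, peak force, peak velocity and peak power are taken
as **independent maxima** over the concentric phase — they need not occur
at the same sample. This matters because those independent maxima are
what feeds the two-point fit; the convention is stated prominently here
since alternatives (e.g. force at the instant of peak velocity) yield
different profiles.

## Per-test processing conventions

### Jump (force plate)

The vertical ground-reaction force is filtered with a **causal**
second-order 10 Hz Butterworth low-pass (single forward pass, as
acquisition software traditionally applies; the small group delay
affects all trials equally). Kinematics follow from impulse-momentum:
`a(t) = (F − W)/M`, v and position by cumulative trapezoidal
integration from movement onset, power as `F·v`.

Tunables (config keys under `jump`):

| parameter | default | unit | rationale |
|---|---|---|---|
| `cutoff_hz` | 10 | Hz | standard jump-analysis cutoff |
| `onset_sd` | 5 | quiet-standing SD | onset = first excursion of \|F − W\| beyond `max(5·SD, 10 N)`, backtracked to the last 1-SD crossing; a common jump convention since the source protocols leave it unspecified |
| `flight_threshold_N` | 10 | N | flight when F drops below this |
| `quiet_window_s` | 1 | s | window for estimating system weight W and its SD |

Two deliberate choices: **system weight is estimated from the plate**
(quiet-standing mean of the first second), not from reported body mass,
absorbing calibration offsets — the dynamic mass is `W/g`; and the lowest
centre-of-mass position is the minimum of twice-integrated net force
between onset and takeoff, so the concentric window is
`[lowest, takeoff]`.

### Cycling (friction-loaded ergometer)

The device reports power and cadence; pedal velocity is
`2π·crank·rpm/60` (crank default 0.170 m, configurable — typical for
this ergometer class) and force is `P/v`. Cadence is smoothed with a
0.5 s centred moving average before peak picking because device cadence
is quantised per revolution. **Fmax is force at the instant of maximal
power**, not `max(P/v)` over the trace: the latter rewards
near-zero-velocity start-up samples where the ratio is numerically
unstable. Since it is genuinely ambiguous whether peak velocity should be
read at maximal cadence or at the peak-power instant, both are emitted
(`Vmax`, `V_at_Pmax`).

### Isokinetic (knee extension)

Force records at 500 Hz are filtered with a **zero-phase** 5 Hz
second-order Butterworth (forward-backward, reflective 1 s padding), so
force peaks keep their time index. Velocity is device-constrained and
treated as constant within a trial; the linear velocity is
`ω·π/180·lever_arm`. The first and last 10% of samples are excluded from
the peak search (`iso$exclusion_fraction`) because the dynamometer
accelerates and decelerates there and the constant-velocity assumption
fails; the fraction is configurable since devices differ. Pmax of the
standard test is taken from the fast (180°/s) trial, Fmax from the slow
(60°/s) one, matching standard practice.

### Trial selection

Repeated trials per condition keep the best one: highest peak power for
jump and cycling, highest peak force for isokinetic trials; ties keep the
first occurrence.

## Statistics

* **Pearson correlations** with p from `t = r√(n−2)/√(1−r²)` and 95%
  CIs by **Fisher z with the normal critical value**,
  `tanh(atanh(r) ± 1.96/√(n−3))`. The method is not named in the source
  literature for this analysis; it was chosen because it reproduces 10 of
  the 12 published (r → CI) cells of the n = 12 generalizability table
  exactly at two decimals. The two remaining cells (r = 0.55 and
  r = 0.23) differ by one unit in the second decimal and are exactly
  reproduced by unrounded coefficients consistent with the printed
  rounding (0.545, 0.234) — i.e. the published table rounded r *after*
  computing the interval. No alternative CI method closes that gap from
  the printed inputs.
* **Correlation-block averages** use magnitudes `mean(|r|)` by default.
  One published cell is printed as −0.47 with a CI of (−0.14, 0.82) that
  is only consistent with +0.47; the implementation does not silently
  flip signs, but the magnitude convention is what reproduces the
  published block means (0.47 and 0.51). The flag `use_magnitude = FALSE`
  gives the raw mean.
* **Paired comparisons** by the dependent-samples t test on
  two-point-minus-standard differences, df = n − 1, two-sided. Constant
  differences (zero variance) are a degenerate-comparison error rather
  than t = 0, because a constant offset between methods makes the t
  statistic undefined, not zero.
* **Normality screening** wraps the standard Royston approximation of the
  Shapiro-Wilk test.
* **No multiple-testing correction** is applied anywhere, matching the
  analysis this package mirrors; treat the stars as descriptive.
* Missing data are handled **pairwise-complete**, and the n actually used
  is reported next to every r.

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` draws per-subject true profiles per test from
log-normal distributions (positivity guaranteed; default CV 15% for both
F0 and V0) around population means chosen to mimic a cohort of physically
active women (n = 12, body mass 67.4 ± 6.2 kg): jump 1700 N / 4.5 m/s,
cycling 600 N / 3.4 m/s, isokinetic 520 N / 2.6 m/s. These satisfy the
qualitative orderings reported for such cohorts (F0 and V0 highest in the
jump, lowest in isokinetic; slope steepest in the jump, flattest in
cycling). Default load conditions are jump {1, 24} kg (unloaded vest vs
loaded, 2 trials each), cycling {2, 10} kg two-point plus the standard
6 kg sprint, isokinetic {60, 180}°/s (2 trials each).

**Between-test structure.** Cross-test correlation targets are imposed on
log F0 (default 0.6) and log P0 (default 0.7) through equicorrelated
Gaussian latents; since `log P0 = log F0 + log V0 − log 4` with
independent F0 and V0 blocks, the implied log V0 equicorrelation is
`ρ_V = (ρ_P(σ_F² + σ_V²) − ρ_F σ_F²)/σ_V²`, and configurations whose
implied 3 × 3 matrix is not positive semi-definite are rejected at
configuration time. At equal CVs the defaults give ρ_V = 0.8.

**Jump actuator.** The simulated jump is quasi-static: quiet standing, a
sinusoidal unweighting-braking dip of prescribed depth (0.25 m, net zero
impulse), then a concentric push whose plateau force F\* and peak
velocity v\* jointly satisfy the F-V law and the push-off dynamics over
the dip depth (`F* = F0 − a·v*`, `v* = √(2d(F*−W)/M)`). Force moves
between levels along half-cosine ramps so the 10 Hz measurement filter
can track it, and the hold duration is chosen so the concentric velocity
peaks exactly at v\*: the measured `(Fmax, Vmax)` point lies *on* the
true line, which is what makes "recover F0 and V0 end to end" a
well-posed check. Activation dynamics, countermovement depth variation
and bilateral asymmetry are deliberately absent — a green recovery test
establishes that the signal-processing chain is unbiased for this
actuator, not that real jumps obey it.

Subjects whose predicted takeoff velocity under the heaviest load falls
below 0.6 m/s (a 2 cm rise — barely leaving the ground) are redrawn,
emulating the study-entry screening that every participant can actually
jump with the loaded vest; about 0.5% of draws at the defaults. Profiles
that cannot leave the ground at all still simulate, flagged
`no_takeoff`.

**Cycling.** Pedal velocity rises with first-order dynamics (τ = 1 s) to
a load-dependent plateau `v_p(load) = (V0/2)·L_ref/(L_ref + load)`
(L_ref = 6 kg), with multiplicative cadence noise (CV 2%) and power
recorded as `F(v)·v` pointwise. The load-velocity coupling is modelled
directly rather than through Coulomb flywheel friction for a structural
reason: with velocity-independent friction and a 5:1 load ratio, the
light-load plateau necessarily overshoots the optimal velocity V0/2
(the conditions `R(light) ≥ F0/2` and `R(heavy) < F0` cannot hold
simultaneously when `R` scales 5×), which would move peak power off the
plateau mid-trajectory and make truth recovery ill-posed. The direct
mapping keeps every plateau at or below V0/2 — heavier load, lower
cadence, higher force — at the cost of not reproducing realistic peak
cadences for very light loads.

**Isokinetic.** Force ramps (0.3 s half-cosine) to the plateau the F-V
law predicts at the device velocity, holds 1.5 s, ramps down, plus
Gaussian sensor noise (SD 8 N). Device velocities at or beyond V0 are
rejected as infeasible.

Noise defaults — jump force SD 5 N, cadence CV 2%, isokinetic force SD
8 N — are plausible sensor magnitudes for the respective instruments;
all are configurable, and every random stream derives from the single
cohort seed through per-trial counters so any individual trial is
reproducible in isolation.

## Numerical choices

* Integration is cumulative trapezoidal with `v(onset) = 0`; the
  impulse-momentum closure (`v(takeoff)` = net impulse / M) holds to
  1e-9 relative by construction and is asserted in the tests.
* The causal filter is warm-started at the first sample's steady state,
  so a quiet-standing offset produces no start-up transient; the
  recursion runs through `stats::filter` (C speed). The digital
  (bilinear) response attenuates slightly more than the analogue
  prototype near Nyquist — the analytic magnitude response is used as an
  upper bound in the contract tests.
* The two-point fit refuses equal velocities (degenerate), non-negative
  slopes and non-positive intercepts (invalid profile), naming the
  violated condition. Profiles with V0 > 20 m/s, or F0 > 20 body weights
  when body mass is known, warn about extreme extrapolation but are
  returned.
* Least squares uses the closed form at n = 2 and a QR-based solve
  (`lm.fit`) otherwise.
* Report CSVs round to 6 decimals; re-running on identical inputs is
  byte-identical.

## Known limitations

* The actuator models are quasi-static; none of the simulators reproduce
  activation/relaxation dynamics, fatigue across trials, or
  musculoskeletal geometry.
* The cycling channel's force measure is interpretively fragile even in
  real data (the published cross-test force correlation for cycling is
  negative and negligible); the simulator does not attempt to model why.
* Two-point extrapolation to the axes amplifies measurement error when
  the two conditions are close in velocity — visible in the jump test,
  whose loads span only ~0.4 m/s; worst-case zero-noise recovery error is
  ~3% there vs ~0.1% for cycling.
* Standard-condition and two-point loads overlap for the jump (the
  unloaded trial serves both roles), so their sampling errors are
  correlated; the package mirrors the protocol rather than fixing this.
* Flight-time jump heights, per-leg analyses, torque-based isokinetic
  quantities and Bland-Altman/ICC agreement statistics are out of scope.
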