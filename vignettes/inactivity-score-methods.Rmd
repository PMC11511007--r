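---
title: "Detecting emergencies from uncertain inactivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting emergencies from uncertain inactivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inactivityscore)
```

## The problem

Elderly people living alone are at risk of "long lie" events: falling and
remaining on the ground for an hour or more before help arrives.  A
non-intrusive safety net watches the home's binary activity sensors (motion
detectors, door contacts, disaggregated smart-meter activity) and raises an
alarm when the household has been inactive for abnormally long, given its
usual daily rhythm.

The classical quantity for this is the *duration of inactivity* `DI(t)`: the
elapsed time since the last activity event.  `DI(t)` implicitly trusts every
event.  One pet walking past a motion sensor, or one disaggregation artifact,
resets it to zero — and a sensor that chatters due to a fault pins it there,
blinding the detector.  This package scores inactivity in a way that degrades
gracefully with sensor quality, assuming each sensor `s` carries a known
certainty `c(s) ∈ [0, 1]` that an event it emits reflects genuine human
activity.

## The Inactivity Score

The score lives on a uniform time grid with step `Δt` (default 60 s) and
follows the recursion

```
IS(t) = (IS(t - 1) + a) × RF(t, E_t),      IS(t0) = 0,
```

where `a` is the per-step gain (default: the step length in seconds, so an
undisturbed score equals elapsed seconds) and `E_t` is the set of distinct
sensors with at least one event in the step `(t - Δt, t]`.  The reduction
factor multiplies one term per triggered sensor:

```
RF(t, E_t) = ∏_{s ∈ E_t} (1 - c(s) · I(t, s)).
```

Each event therefore scales the score by its sensor's *effective* certainty.
A fully certain activation (`c = 1`) contributes a factor 0 and resets the
score, reproducing `DI(t)` exactly; an uncertain one only shrinks it; several
independent simultaneous activations shrink it more than any single one; and
with no events the empty product leaves the score growing by `a` per step.
The score is non-negative and can never grow faster than `a` per step.

The *sensor impact* `I(t, s)` guards against chattering sensors.  If sensor
`s` last fired at `l(t, s)`, then

```
I(t, s) = (t - l) / (γ (1 - c))   if t - l < γ (1 - c),   and 1 otherwise,
```

with `γ` a decay horizon (default 4 h).  A re-fire shortly after the previous
activation has impact near 0, so its factor `1 - c·I` is near 1 and the score
barely drops: a faulty sensor firing every few minutes cannot hold the score
down, while a trusted sensor's *first* activation after a quiet spell acts at
full strength.  The window `γ (1 - c)` vanishes for fully certain sensors —
they always act at full strength — and widens as certainty falls, which is
exactly the regime in which rapid repeats are suspicious.  The chattering
scenario is asserted in the test suite: a `c = 0.3` sensor firing every five
minutes leaves `DI` pinned at or below one grid step of its firing interval
while the score keeps rising across the whole day.

Two conventions close the recursion.  `l(t, s)` is the activation *strictly
before* the one being evaluated (treating it as the current firing would
force `I = 0` and make every event a full reset, a degenerate reading), and a
sensor's very first activation has impact 1.  Multiple firings of one sensor
within a single grid step collapse to one set member whose `l` is the most
recent strictly earlier firing — possibly within the same step.  Noise-origin
events update the activation history exactly like genuine ones, because a
deployed detector cannot tell them apart.

`duration_of_inactivity()` computes the baseline on the same grid, resetting
at the end of any step containing an event.  Keeping both on the grid makes
the full-certainty equivalence `IS ≡ DI` exact rather than approximate, which
the tests assert identically, and costs at most one step (60 s) of timing
resolution relative to the continuous definition.

## Alarm thresholds

An alarm requires `IS(t) > thres(t)`.  The threshold adapts to the
household's own history:

1. **Reference times** — one candidate per calendar day over the past `ψ`
   days (default 70) at the same clock time as `t`, kept only if its weekend
   status matches `t`'s.  Weekday and weekend rhythms differ, so the two
   populations never mix; with full history a weekday query has 50
   references, a weekend query 20.
2. **Windowed maxima** — around each reference time, the maximum score in a
   `± β` window (default 1 h), tolerating day-to-day jitter in the routine.
3. **Outlier clipping** — the boxplot bound `Θ = Q3 + 1.5·IQR` over those
   maxima caps the influence of rare atypical days (a trip away, a party).
   Quartiles use linear interpolation between order statistics
   (`stats::quantile` type 7); the convention is configurable because the
   method is mildly sensitive to it only at small reference counts.
4. **Scaling** — `thres(t) = min(max(ISmax), Θ) · α`, default `α = 2`,
   trading false alarms against detection latency.

Thresholds are *undefined* — and alarms impossible — during an
initialization period (default 10 weeks) and whenever fewer than
`min_references` (default 5) references have usable history; quartiles on one
or two points are meaningless.  Undefined thresholds are reported as `NA`,
never silently treated as zero or infinity.  An alarm *onset* is a grid point
above its threshold whose predecessor was not above its own, so a prolonged
excursion counts once; a predecessor with an undefined threshold counts as
"not above".

Causality: thresholds at `t` consult only scores strictly before `t`.  With
the defaults this is automatic (references lie at least one day back and
`β = 1 h`), and the windowed maxima are additionally clipped to `< t` when
configurations could violate it.  Reference periods that themselves contained
alarms are *not* excluded from the history.

Two implementations coexist deliberately: a readable per-query path
(`compute_threshold()`, built from `reference_times()`, `window_maxima()`,
`iqr_upper_bound()`) and a vectorized fast path (`threshold_series()`) that
exploits the fact that same-clock-time references are exact grid strides when
the step divides one day.  The test suite asserts the two agree point-wise on
random histories.

## Synthetic households

The simulator generates everything the evaluation needs without external
data:

* **Activity** — an inhomogeneous Poisson process with a 24-hour intensity
  profile.  The default profile has a quiet night (0.2 events/h, 00–05), a
  morning peak (3/h, 06–08), a daytime plateau (1.5/h, 09–17), an evening
  peak (3/h, 18–21) and a wind-down (0.8/h), totalling ≈ 37 events/day
  before the per-sensor hourly thinning — comparable, after filtering, to
  the 13–17 events/day seen in published single-occupant motion-sensor
  homes.  Saturdays and Sundays are scaled by `weekend_scale` (default 1.2,
  more time spent at home) so the weekend-aware thresholds have structure to
  learn.  Events are distributed over sensors by multinomial weights.
* **Certainties** — sampled per noise level from a truncated normal via
  rejection: `N` (all 1), `L` (μ 0.95, σ 0.02 on [0.9, 1]), `M` (0.90, 0.10,
  [0.8, 1]), `H` (0.85, 0.20, [0.6, 1]).
* **Noise sets** — for each sensor with certainty `c` and `|s|` genuine
  events, exactly `round((1 - c)·|s|)` spurious events (round-half-to-even;
  the product is generally non-integer).  Their time-of-day follows the
  sensor's own empirical hourly activation histogram, mixed with a
  `global_fraction` (default 0.1) of clock-uniform events; the magnitude of
  the time-independent component is a documented knob, not an inferred
  constant.  Calendar days are uniform over the span, and noise timestamps
  are drawn independently of real events (collisions allowed).

All draws are reproducible: a seed produces bit-identical streams, and
seeded helpers restore the caller's RNG state.

What the simulator does *not* emulate: multi-resident households, room
topology and sensor correlation within rooms, pets with their own schedules,
behavioural drift (seasonality, illness), recording outages.  Passing tests
on synthetic data therefore demonstrate the mechanics of the method — score
dynamics, threshold adaptation, protocol bookkeeping — not field performance
on real homes.

## Evaluation protocols

**False positives.**  The input streams contain no genuine emergencies, so
every alarm onset after the initialization period is a false positive;
onsets during initialization are not counted.  The rate divides by the
post-initialization span in days (the denominator convention is stated here
because reported per-day rates are meaningless without one).

**Detection latency.**  An emergency at `te` stops genuine activity; noise
keeps flowing.  The trial input is the genuine events before `te` merged with
the complete noise stream, and the detection time is the first grid point at
or after `te` whose score exceeds its threshold.  Latencies are capped at 7
days (censored beyond that), and a trial whose score is already above
threshold at `te` is excluded — "already in alarm" is operationalized as the
score exceeding the threshold at the grid point at or just before `te`, since
an alarm has no defined duration.  Thresholds during a trial are computed
from the trial's own history: pre-`te` reality plus post-`te` noise, with no
counterfactual activity.  Trials are independent; no score history leaks
between them.

A study draws onset times uniformly over the post-initialization span.  The
multi-level study replays the *same* onset set at every noise level — a
variance-reduction choice that makes level-to-level comparisons paired.  Each
trial is computed incrementally (scores can only diverge from the full-stream
ones after `te`), and `verify_detection()` re-checks detected trials by full
recomputation; the acceptance tests do this post hoc.

The expected directions, which the acceptance suite asserts on a 120-day,
five-sensor household with 100 trials per level and three seed replicates:
median detection time is non-decreasing from `N` to `H` (noise events keep
shrinking the score after `te`), and post-initialization false-positive
onsets are non-increasing (incomplete resets inflate the historical maxima,
raising thresholds).  Monte-Carlo slack for these monotonicity checks was
fixed a priori at `max(600 s, 10 %)` for medians over 300 pooled trials and
`max(2, 20 %)` for pooled onset counts.

## Numerical and degenerate-input choices

* Timestamps are naive local clock times handled in a fixed zone; no
  daylight-saving arithmetic.  Duplicate timestamps are allowed; ties keep
  input order.
* The hourly thinning filter is half-open: an event exactly one hour after
  the last kept event of its sensor is kept.
* Streams with recording gaps can be cut with `split_at_gaps()` (default
  1 h); the score itself keeps accumulating across gaps if not split, which
  is the honest reading of missing data as "no observed activity".
* The per-step gain `a` defaults to the step length expressed in seconds.
  Reading it instead as a fixed 1 s per step only rescales the score;
  thresholds derive from the same series, so alarm behaviour is unchanged.
* An empty reference set or empty maxima multiset raises an explicit error
  at the operation level and yields an undefined threshold at the detector
  level.
* Problem sizes in the tests — 100-to-120-day households, 100 trials per
  level, spot checks on 1 s grids — were chosen as the smallest sizes at
  which every qualitative property is stable across seeds.

## Known limitations

The certainties are assumed known and constant; estimating them, and
adapting them over time, is out of scope.  Detection latency is hours, not
minutes: this is a fallback safety net behind wearables and alarm buttons,
not a primary emergency system.  Scores are household-level; room-level
scoring would need sensor topology the package does not model.
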