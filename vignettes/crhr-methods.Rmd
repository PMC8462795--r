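---
title: "Estimating the circadian rhythm in heart rate from wearable data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the circadian rhythm in heart rate from wearable data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crhr)
```

## The model and its assumptions

Consumer wearables record heart rate (HR), step counts and (on some
devices) sleep intervals continuously for months.  `crhr` models waking
HR in 5-minute bins as

$$\mathrm{HR}_t = a - b\cos\!\Big(\frac{\pi}{12}(t - c)\Big) + d\,A_t + \varepsilon_t,
\qquad \varepsilon_{t+1} = k\,\varepsilon_t + N(0, \sigma^2),$$

a 24-h cosinor (basal level $a$, amplitude $b$, phase $c$ = clock time of
the HR minimum) plus a linear acute effect of activity $A_t$ (steps per
minute) and an AR(1) error process.  The correlated error absorbs
hormonal and behavioural influences with a roughly one-hour timescale
(at the population-typical $k = 0.9339$ per 5-minute bin the
decorrelation time $-5/\log k$ is about 73 minutes), while $\sigma$
captures measurement error and fresh external effects.  Assumptions worth
stating explicitly:

* HR during sleep is not modelled at all — sleep labels exist only to
  discard sleep data, so sleep physiology cannot contaminate the phase.
* The activity effect is linear; saturation at running intensities is
  deliberately ignored (it has little effect on the other parameters).
* One phase per 2-day window: the circadian phase is treated as constant
  within a window and re-estimated for every window.

The likelihood is the exact Gaussian density of the stationary AR(1)
process observed on a gappy 5-minute grid: the first residual uses the
stationary marginal $N(0, \sigma^2/(1-k^2))$, and a residual following a
gap of $g$ bins is $N(k^g r_{\mathrm{prev}},\,
\sigma^2(1-k^{2g})/(1-k^2))$.  Charging gaps of any length are therefore
handled exactly rather than imputed or dropped, which is the reason a
likelihood-based approach is preferred over least squares here.  A unit
test verifies the implementation against a dense multivariate-normal
evaluation on random gappy fixtures to $10^{-8}$.

One genuine ambiguity in the source material is the time base of $k$:
the population histogram is captioned per *minute*, but only the
per-5-minute-bin reading reproduces the stated one-hour correlation
timescale.  This package defines `k` per 5-minute bin throughout, and
where a scenario requires the per-minute reading we translate it as
$k_{\mathrm{bin}} = k_{\mathrm{min}}^5$.

## Preprocessing rules

HR and steps are averaged/totalled into 5-minute bins (so denser
recording periods are not over-weighted); missing HR stays missing.
Step records whose native interval spans bin boundaries are apportioned
pro-rata, which conserves daily totals exactly.  Sleep intervals are
consolidated by absorbing wake interruptions shorter than 2 h; wake
spans bounded by sleeps longer than 2 h become "days" (naps of at most
2 h do not split a day, though their bins are excluded).  Each interior
sleep yields one 2-day fit window pairing the flanking wake days, with
time measured in hours since local midnight of the first day; windows
with fewer than 48 five-minute observations (about 4 h of data — a
robustness floor this package adds) are dropped.  All timestamps are
treated as local civil time with no DST arithmetic; DST transitions pass
through as-is (a documented caveat, not a feature).  Apple-Watch-style
exports without sleep labels get sleep separators from charging gaps
(HR gaps of at least 4 h containing zero steps).

## Posterior sampling

The six parameters are sampled with the Goodman–Weare affine-invariant
stretch move: 32 walkers, a 100,000-draw default budget per window, the
first 20% of sweeps discarded as burn-in.  The prior is a wide uniform
box (`a` 30–120 bpm, `b` 0–20 bpm, `d` 0–2 bpm/(steps/min), `σ` 0.5–30
bpm, `k` 0–0.999) chosen to cover the population histograms with wide
margins; the phase is unconstrained up to wrapping.  Because the phase is
circular, the ensemble is augmented with a periodic-translation
Metropolis move (each sweep, each walker proposes a uniform shift of `c`
with probability 0.15): without it, walkers coalesce into one sector of a
diffuse phase posterior and the 80% arcs under-cover.  The sampler run is
bit-reproducible from its seed, and its correctness is tested against a
6-d Gaussian (moments) and a 1-d double well (χ² against quadrature).

Summaries: posterior means (circular mean for `c`), central 80% intervals
(10th–90th percentile; for `c`, quantiles of wrapped deviations about the
circular mean).  Central intervals rather than HPD because they are
unique and match the confidence-band convention.

Day-to-day tracking fits windows in time order, giving window $n$ a
circular Gaussian prior on `c` centered at window $n-1$'s posterior
circular mean with s.d. 1 h — the posterior is sampled instead of the
bare likelihood.  Only the phase is propagated: phase continuity is the
scientific claim being exploited, and propagating all six parameters
would let one bad window poison the chain.  A prior wider than the
circle (s.d. ≥ 100 h) is treated as exactly flat, so tracking with an
uninformative prior reproduces independent fits seed-for-seed.  Walkers
for tracked windows start half from the phase prior and half uniformly
around the circle, so a likelihood mode far from the prior center is
still found (initialization affects mode-finding only, not the
stationary distribution).

## What phase uncertainty to expect

At the population-central parameters ($b = 4$ bpm, $\sigma = 6.9$ bpm,
$k = 0.93$ per bin) a 2-day window contains limited low-frequency
information: the AR(1) spectral density at one cycle per day implies a
phase standard error of several hours, and the package's calibration
study reproduces that (median 80% width ≈ 11 h for flat-prior fits).
Tracked posteriors are capped near ±1 h by the sequential prior — which
is exactly the uncertainty the showcased real-data tracks display.  The
practical consequence, documented rather than hidden: single-window
flat-prior phase estimates at these noise levels are coarse; phase
tracking (or a strongly rhythmic subject, $b \gtrsim 6$ bpm with weaker
noise correlation) is what makes day-resolution phase dynamics visible.
This is also why the tracking validation scenarios below simulate a
strongly rhythmic subject ($b = 6$ bpm, $k = 0.9339^5$ per bin, the
per-minute reading): under the weaker regime the tracker has nothing to
track, and no qualitative shift behavior could be exercised.

A related calibration note: frequentist coverage of the 80% phase arcs at
a *fixed* truth sits slightly below nominal (≈ 0.65–0.70 in our studies)
even with generous sampling budgets.  The HR minimum of a normally
entrained subject lies inside the removed sleep gap, so the phase is
inferred by extrapolation and its posterior is systematically drawn
toward features of the observed waking span.  Bayesian intervals
guarantee coverage averaged over the prior, not at an adversarial fixed
point; we report the behavior as measured.

## The phase-response curve

For each day flanked by two phase estimates, activity is re-timed
relative to the previous night's phase (relative hour 0 = the HR
minimum), totalled into 24 one-hour bins, and paired with the
night-to-night phase shift $y$ (wrapped to $(-12, 12]$; advance
positive, delay negative).  Ordinary least squares of $y$ on the bin's
step total, bin by bin, gives the average phase shift per step for
activity at each relative hour.  The 24 slopes are summarized with a
4-parameter asymmetric sinusoid — offset, amplitude, trough phase, and a
trough-to-peak time $\tau$ that lets the rising half-period ($\tau$ h, a
scaled half-cosine) differ from the falling one ($24-\tau$ h).  The fit
profiles the linear parameters over a coarse $(\varphi, \tau)$ grid and
refines by multi-restart Nelder–Mead with $\tau$ kept in $(1, 23)$ by a
logistic transform; ties break to lowest RSS, then lowest $\tau$.

Two estimator decisions the source leaves open, made here explicitly:

* **High-leverage bins.**  Relative hours at the edge of the waking span
  have near-zero activity variance, so their slopes are set by a handful
  of days and can be wild.  The curve fit weights bins by inverse squared
  slope standard error and drops bins whose SE exceeds 3× the median.
  Raw slopes are always reported untouched.
* **Intrinsic period.**  The daily shift decomposes as
  $y = \delta_0 + \sum_h m(h)\,x_h$ with $\delta_0$ the zero-activity
  drift; the intrinsic period is $24 - \delta_0$ h.  $\delta_0$ is
  estimated as the intercept of the day-level regression of $y$ on all 24
  bin totals jointly — the pure zero-activity intercept, which stays
  unbiased when hourly step totals are correlated across hours, where a
  single-bin intercept or the curve-offset-times-daily-steps shortcut
  (both provided as fallbacks) would be biased.  In simulation this
  recovers a 24.2-h period to ±0.01 h over 100 days with exact phases.

A known limitation, characterized in development: when hourly activity
totals are cross-correlated (e.g. a single exclusive daily exercise bout
creates negative cross-hour covariance), the per-bin *simple* regression
slopes inherit a multiplicative bias — the classic correlated-regressor
effect.  The slope profile's shape survives, but its DC component can be
attenuated by tens of percent.  The day-level intercept period estimator
is immune; users comparing slope-curve offsets across populations with
very different activity structure should keep this in mind.

The shuffled control (permuting the nightly shifts across days while
leaving activity in place) must flatten the slopes — it does, and this is
asserted in the test suite.  A non-overlapping robustness variant
computes shifts across two nights (lag 2), so the two phase fits of each
pair share no HR data; its slope profile agrees with the standard
one-night PRC.

## The simulator

`crhr_simulate()` generates the full data regime with known ground truth:
model-exact HR with exact-gap AR(1) residuals; a sleep schedule with
night-to-night jitter (s.d. 20 min), optional naps, shift transitions and
charging gaps; lognormal waking activity (median ≈ 4 steps/min, scaled by
morning/evening commute peaks) plus independent per-hour 30-minute brisk
episodes (0.7/day expected), giving ≈ 10,200 steps/day spanning the
0–100+ steps/min regime; sleep-period HR (basal − 8 bpm, not
model-governed) emitted only so preprocessing can be shown to discard it.
The true clock is either pinned or dynamic:
$\mathrm{phase}_{n+1} = \mathrm{wrap}(\mathrm{phase}_n + (24 - \tau_{\mathrm{int}})
+ \sum_h \mathrm{prc}(h)\,x_h)$, updated each midnight.  Episodes are
independent across clock hours *by design*: exclusive daily bouts induce
the cross-hour covariance bias described above, and the default generator
should not build a known estimator bias into every downstream study
(the bias itself is documented instead).

What the simulator does *not* emulate — so passing tests say nothing
about these: device-specific sleep-scoring quirks, HR artifacts
(arrhythmia, sensor dropout mid-bin), nonlinear HR–activity response at
running intensity, light exposure as a separate zeitgeber, travel across
time zones, and DST.

## Validation scenarios and problem sizes

The acceptance studies (mirrored in `scripts/acceptance.R`) use these
fixed designs, chosen once:

* Likelihood oracle: 100 random gappy fixtures, $n \le 50$, agreement
  with dense multivariate-normal evaluation within $10^{-8}$.
* Recovery/calibration at central truth: 20 two-day windows at the full
  100k budget (phase error), 100 windows at a 20k reduced budget
  (interval coverage).
* Tracking: a strongly rhythmic subject (see above) through a 7-h
  schedule shift — pinned clock (12 days, phase must hold) and an
  entraining clock with PRC amplitude $1.2\times10^{-4}$ h/step (28
  days, the track must re-lock; the truth adjusts ≈ 1 h/night, about the
  fastest a 1-h-s.d. sequential prior can follow).
* PRC: 100-day null (fixed 24-h clock; slopes and period must be exactly
  null) and 100-day recovery with a known sinusoidal PRC — DC
  $0.2/10220$ h/step (balancing a 24.2-h intrinsic period at the default
  activity level), amplitude $6\times10^{-5}$ h/step, peak at relative
  hour 16, which is the entrainment-stable geometry for a day-active
  schedule under this sign convention.  PRC studies consume ground-truth
  phase tracks from the simulator ledger, isolating the PRC estimator
  from phase-estimation noise; the MCMC-phase path is exercised
  end-to-end elsewhere without tight numeric bounds.
* Non-overlap robustness: 150 days, inverse-variance-weighted correlation
  between the one-night and two-night slope profiles.
* Sampler: closed-form 6-d Gaussian moments; 1-d double-well χ² at the
  1% level against quadrature, thinned to near-independence.

These sizes keep the full suite within a coffee break on one core while
leaving each check statistically meaningful.

## Known limitations

* Phase is barely identified in single flat-prior 2-day windows at
  population-central noise; see the uncertainty section.
* The PRC attributes all entrainment to measured steps; correlated
  zeitgebers (light, meals) are absorbed into the activity PRC.
* Uncertainty from the nightly phase estimates is not propagated into the
  PRC regression (days are attributed with posterior-mean phases).
* Sub-5-minute HR cadence irregularities within a bin are handled by a
  simple mean; boundary (first/last) windows of a record are not fit.
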