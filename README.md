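# crhr — circadian rhythm in heart rate from wearable data

`crhr` extracts daily physiological parameters from consumer-wearable
heart-rate, step and sleep streams, tracks the circadian phase of heart
rate day by day, and estimates a personalized phase-response curve (PRC)
of the heart-rate clock to activity.  It is aimed at circadian and sleep
researchers working with Fitbit / Apple Watch style exports, and ships a
full synthetic-data simulator with a known ground-truth clock so the whole
pipeline can be validated without any real recordings.

## The model

Waking heart rate in 5-minute bins is modelled as a cosinor plus a linear
activity effect with AR(1) correlated errors:

```
HR_t = a − b·cos(π/12 · (t − c)) + d·A_t + ε_t,     ε_{t+1} = k·ε_t + N(0, σ²)
```

* `a` — basal heart rate (bpm)
* `b` — amplitude of the 24-h circadian oscillation (bpm)
* `c` — clock time of the circadian HR minimum, the circadian phase (h)
* `d` — acute HR increase per unit activity (bpm per step/min)
* `σ` — innovation noise (bpm); `k` — AR(1) carry-over per 5-min bin

Sleep data is used only to discard sleep; the AR(1) likelihood handles
charging gaps exactly, so irregular records do not bias the fit.  The six
parameters are sampled per 2-day window (centered at a sleep period) with
an affine-invariant ensemble MCMC; day-to-day phase tracking feeds the
previous night's phase (plus 1 h of Gaussian width) forward as a prior.
The PRC is estimated by re-timing each day's activity relative to the
current circadian phase, regressing night-to-night phase shifts on hourly
step totals in 24 one-hour bins, and summarizing the bin slopes with a
4-parameter asymmetric sinusoid; the intrinsic circadian period follows
from the curve's vertical position (the zero-activity daily drift
`δ₀`, period `= 24 − δ₀`).

## Worked example

Simulate six days of wearable data from a strongly rhythmic subject
(circadian amplitude 6 bpm), run the pipeline, and inspect the phase
track:

```r
library(crhr)

subject <- crhr_params(a = 73.5, b = 6, c = 3.3, d = 0.32, sigma = 6.9,
                       k = 0.9339^5)
sim  <- crhr_simulate(sim_config(params = subject, n_days = 6, seed = 1))
prep <- crhr_preprocess(sim$records)
prep$windows
#> 5 fit window(s)
#>   window_id  day1_date      sleep_midpoint n_obs
#> 1         1 2023-03-06 2023-03-07 02:45:31   384
#> 2         2 2023-03-07 2023-03-08 03:06:42   381
#> ...

fit_window(prep$windows[[1]], n_total_samples = 100000, seed = 2)
#> Heart-rate model fit (80000 posterior draws, acceptance 0.46)
#>   a       74.185  [72.006, 76.293]
#>   b        2.723  [0.416, 5.430]
#>   c        4.937  [0.693, 11.172]
#>   d        0.317  [0.279, 0.354]
#>   sigma    7.132  [6.786, 7.486]
#>   k        0.719  [0.670, 0.768]

track <- track_phases(prep$windows, n_total_samples = 20000, seed = 3)
track
#> Phase track: 5 window(s), 0 flagged
#>        date sleep_midpoint_h phase_mean_h ci80_lo ci80_hi phase_difference_h
#>  2023-03-06             2.76         5.03   0.938   11.65              2.273
#>  2023-03-07             3.11         4.74   3.668    5.84              1.631
#>  2023-03-08             2.98         3.28   2.558    4.05              0.300
#>  2023-03-09             3.36         2.65   2.044    3.27             -0.716
#>  2023-03-10             3.00         3.23   2.285    4.19              0.228
```

The generating phase is `c = 3.3` h.  The first (flat-prior) window is
wide, and the sequential 1-h prior then pulls the track onto the truth
with ~±1 h bands; `phase_difference_h` is the wrapped offset between the
HR minimum and the sleep midpoint (advance positive).  With a longer
record (≥ ~50 days) the PRC becomes estimable:

```r
prc <- crhr_prc(track, prep$binned)   # needs a longer track in practice
plot(prc)                             # bin slopes + fitted curve
prc$period_h                          # intrinsic period, hours
```

Real exports are read with
`read_device_export(paths, dialect = c("generic", "fitbit_split", "applewatch"))`,
and `exec/crhr` wraps the same steps as a command line
(`crhr simulate|track|prc --out DIR ...`).

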