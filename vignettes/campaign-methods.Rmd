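---
title: "Models and methods behind cytocampaign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cytocampaign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytocampaign)
```

`cytocampaign` analyses moored-buoy campaigns of automated pulse-shape flow
cytometry: per-particle five-channel optical pulses (forward scatter FWS,
sideward scatter SWS, orange/yellow/red fluorescence FLO/FLY/FLR) acquired
every two hours by two alternating protocols, turned into gated cluster
abundances, hourly-regularized series, abundance-pulse onsets, environmental
lag estimates and diel cell-cycle signatures. Because raw campaigns of this
kind are rarely public, the package carries a full synthetic-campaign
generator whose statistical structure mimics a late-winter Mediterranean
deployment; every downstream method is validated against the generator's
ground truth. This vignette documents the models, the defaults and the
reasoning behind the design choices.

## The synthetic campaign generator

### Environmental forcing

Each variable (nitrate+nitrite, phosphate, silicate, wind speed,
precipitation, solar radiation, temperature, salinity) is an hourly series:
baseline + event kernels + AR(1) noise (coefficient 0.9, per-variable
marginal sd). Baselines are constants except solar radiation and temperature,
which ramp linearly across the campaign. Event kernels are impulses (single
hour; rainfall), decaying pulses (step then exponential decay with an
e-folding time in hours; nutrient injections, wind events, temperature dips
with negative magnitude), or ramps. Concentration-like variables are clamped
at zero after summation. The default scenario places two major nitrate pulses
(2.31 uM peak in mid-February, 1.15 uM on 9 March), a moderate late-February
rise, phosphate pulses trailing the nitrate ones, two precipitation impulses,
four >5 m/s wind events and a 10-day instrument outage in mid-March over a
73-day window.

The default scenario drives all clusters from a single modeled limiting
nutrient (nitrate+nitrite). The middle of the three abundance pulses is
therefore produced by a moderate synthetic nitrate event rather than by a
separate phosphate/precipitation pathway — one deliberate simplification of
a multi-nutrient reality the generator does not attempt to model.

### Population dynamics

Per-capita growth for a cluster is

μ(t) = `nutrient_gain` · nut(t − `response_lag_days`) · K(h),

where nut is the limiting-nutrient series and K(h) is a wrapped-Gaussian
division kernel in local hour-of-day, centred on `division_hour`, width
(1 − `synchrony`) · 12 h, discretely normalized to unit daily mean (so a
day's growth is independent of synchrony; at synchrony 0 the kernel is
exactly uniform). Abundance integrates dN/dt = (μ − λ)N hourly in log space,
with growth booked at the arriving hour so abundance and cell-size phases
stay aligned. Loss λ is constant; days whose mean wind speed exceeds
5 m/s end with a multiplicative collapse (1 − `wind_collapse_factor`).
In the default scenario λ = gain × 0.25 uM, i.e. growth balances loss at
0.25 uM nitrate: abundances decline between pulses and bloom when a
nutrient event lifts nut above that reference — which also pins the true
pulse onset at exactly (event onset + response lag), the anchor all pulse
recovery tests use.

Mean per-cell forward scatter mirrors the division cycle: cells grow between
divisions and the cells added around the division hour are small, so
log mean-FWS follows the *negative* of the cumulative diel division excess
C(h) = ∫(K − 1)/24, scaled by `fws_growth_rate`/2 in log units. This makes
the diel components of abundance and mean FWS exactly anti-phased by
construction — the qualitative behaviour of synchronized phytoplankton,
where maximum abundance follows division while cell size is at its minimum.
A light-anchored growth term (fixed photoperiod) was considered and
rejected: it pins the FWS minimum at dawn regardless of division hour,
breaking the anti-phase for dark-dividing clusters. The diel amplitude of
abundance scales with the gross growth rate μ; a realistic turnover
(μ ≈ λ ≈ 0.4 day⁻¹) is therefore needed for the diel signal to clear the
observation noise, and the diel test fixtures are parameterized that way.

### Listmode synthesis

Per sample, each cluster contributes Poisson(abundance × analysed volume)
particles. A particle's pulse on every channel is a raised cosine
A·sin²(πi/(L−1)) of odd integer length L ≥ 3 (drawn around the cluster's
mean length) whose amplitude A is lognormal around the cluster's optical
signature (log10-mV mean and sd per channel); the FWS amplitude is scaled by
the cluster's current diel size factor. The raised cosine was chosen because
it is unimodal, non-negative, and has closed forms for the oracle tests:
trapezoid area exactly A(L−1)/2, maximum exactly A. Lengths are kept odd so
the peak falls on a sample point: with even lengths the sampled maximum is
only 0.75–0.9 of the amplitude, which silently pushes part of a dim
cluster below the acquisition trigger and biases its recovered abundance
(−16% for the picophytoplankton in an early build). Values are
digitized to 1 uV (3 decimals), which both mimics an instrument and makes
the CSV round-trip byte-exact. Sub-trigger junk particles are added at
`noise_event_rate` per cm³; the acquisition trigger is deliberately *not*
applied at synthesis — the recorded stream carries every particle and
thresholding is a processing step, so the Poisson conservation between truth
abundance and pre-trigger event counts is testable.

The two default protocols reproduce the acquisition settings of an
automated two-protocol deployment: 7 mV FLR trigger, 4.5 mm³/s, 4 min
(targeting picophytoplankton; volume efficiency 0.35, matching a reported
0.38 cm³ mean analysed volume against a 1.08 cm³ nominal product — the
deficit is reproduced, not explained) and 10 mV, 9 mm³/s, 10 min (5.4 cm³
nominal, 0.98 efficiency for a 5.3 cm³ mean). The picophytoplankton optics
place their red fluorescence between the two trigger levels (≈8.3 mV,
narrow spread), so the low-trigger protocol records them and the
high-trigger protocol rejects them — the mechanism by which two protocols
target different size classes.

### Desk-scale campaigns

`default_scenario(abundance_scale = s)` multiplies all baselines by `s`
(floored at 5 cells/cm³ so rare clusters keep analyzable counting
statistics). The packaged analyses and the acceptance script run the full
73-day, two-protocol campaign at `s = 0.01` — about 750 particles per
sample pair, a bundle of a few hundred MB, and a complete simulate+analyse
cycle in under two minutes — with identical dynamics but Poisson noise
roughly 10× larger than at field abundances. Estimator-calibration studies
(lag, pulse, diel recovery) run on truth series with explicit observation
noise instead, at the sizes stated below. Consequences of the scaling are
visible and expected: the sparsest clusters pick up occasional spurious
pulse detections from counting noise, and cross-cluster abundance ratios
are not preserved below scale 1.

## Descriptors, trigger and gating

Per event and channel: `total` = trapezoid area at unit spacing (a length-1
pulse degenerates to its value — the quadrature rule is a documented choice,
as pulse-shape instruments only advertise "area under the curve"),
`maximum`, `length`, and the derived max FLO / max SWS ratio (undefined,
flagged, when max SWS is 0 — never ±Inf). The trigger keeps events with
pulse maximum ≥ level on the trigger channel, boundary-inclusive; retention
is monotone non-increasing in the level. Analysed volume is flow rate ×
duration × efficiency (mm³→cm³), overridden by an explicit measured volume
when the metadata carries one; abundance is count/volume.

Gating assigns each triggered event to the first matching gate in priority
order, using a boundary-inclusive even-odd point-in-polygon rule on two
descriptor axes (log10 or linear per axis). The signature-specific gates
(PicoFLO on the FLO/SWS ratio vs max FWS; HighSWS on max SWS vs max FLR;
HighFLO on total FLO vs total FWS) take precedence over the size-ladder
gates (total FLR vs total FWS for picoeukaryotes, nano- and
microphytoplankton); manual gating practice resolves the same conflicts by
drawing the distinctive cytogram first. The shipped rectangles are
calibrated to the synthetic optics only (boxes ±0.45–0.6 decades around the
cluster means, ≥ 3 amplitude-sd margins); real data require a user-supplied
scheme (YAML). Events with non-positive values on a log axis are counted
and left Unassigned rather than raising an error.

## The loess engine

The smoother is a from-scratch local polynomial regression: at each hourly
grid point, the q = ceiling(span·n) nearest source points by time distance
(all equidistant ties included) are weighted by the tricube
(1 − (d/dmax)³)³ and fitted with a weighted least-squares polynomial in
coordinates centred on the query point; the fitted value is the local
intercept. Defaults: degree 2 (the convention of the reference
implementations of local regression), no robustness iterations (Gaussian
family), distance = absolute time difference in hours. Points at exactly
d = dmax carry zero weight; the neighbourhood widens until degree+1 points
have positive weight. The pointwise standard error is σ̂·‖l‖ with l the
local hat vector and σ̂² the tricube-weighted residual variance with a
degrees-of-freedom correction.

Spans are stated per analysis rather than globally, because span is a
fraction of the series length and the "same" physical window means
different spans on different windows: `span_trend = 0.3` for long-term
trends and the environmental series; `span_pulse = 0.03` (≈ a 3-day tricube
window on a 2-hourly, 73-day campaign) for pulse-onset detection — wide
enough to bridge the diel cycle, narrow enough that smoothing an asymmetric
onset corner (slow decline into steep rise) displaces the slope
zero-crossing by only a few hours, where a 0.3 span displaces it by more
than a day; `span_diel = 0.05` for the diel stage, always applied *within*
an analysis window of one to three weeks so the small span resolves the
24-h cycle. The SE is reported pointwise; within a two-sided data gap it is
strongly inflated but not monotone in the distance to the nearest
observation — leverage peaks where the neighbourhood is most one-sided,
near the gap edges — so gap grid points are additionally flagged
`low_confidence` by a max-gap rule (default 6 h) rather than by an SE
threshold. Extrapolation beyond the observed range is refused unless
explicitly enabled.

Slopes are central finite differences of the hourly fitted values
(one-sided at the ends). Fits are verified per grid point against an
independent definitional WLS solve (50 random irregular fixtures,
agreement ≤ 1e-8) and reproduce polynomials of degree ≤ d exactly.

## Pulse onsets, cross-correlation, succession

An abundance-pulse onset is an hour where the smoothed slope crosses from
non-positive to positive, stays positive for `persistence_h` (default 12 h),
and the subsequent rise reaches `min_fold` (default 1.5×) of the onset
value; the series start counts as a crossing if it begins rising. Peak,
end (first return below the onset value) and fold-change follow. Both knobs
are exposed; the defaults suppress diel wiggles (12 h ≈ half a period) and
sub-50% fluctuations.

`windowed_ccf` computes Pearson r between env(t − k) and the target series
over an analysis window extended `lead_days` (default 1) backwards, on an
hourly lag grid up to `max_lag_days`, reporting lags in days. Only
non-negative lags are searched by default (the environment leads the
biology); the best lag maximizes r, not |r|. Because the best lag is the
maximum over a few hundred candidates, the significance screen uses a
Bonferroni-corrected one-sided Gaussian bound, qnorm(1 − 0.025/n_lags)/√n:
an uncorrected 1.96/√n bound is exceeded almost surely under the null once
hundreds of lags are scanned. Even corrected, the bound ignores serial
correlation in both series and is anti-conservative on smoothed data —
it is a screening rule for the summary table, not a test.

Recovering a *configured* environment→abundance delay has one subtlety:
under the generator's own dynamics the abundance **level** is an integral
of the driver, so its correlation peak sits at the transport delay plus a
growth/loss kinetic offset of several days. The delay parameter itself is
defined on the growth response — d log N/dt = gain·nut(t − lag) − λ is an
exact shifted copy of the driver — so the lag-recovery study correlates the
driver with the per-capita growth rate (the loess slope of log abundance).
With 10% observation noise on a 2-h schedule, a 3.1-day lag is recovered
within ±0.25 day in ≥95% of runs. Succession order sorts clusters by the
onset of a given pulse, grouping onsets that fall in the same hour.

## Diel decomposition

The diel component is the difference between a small-span and a large-span
loess fit of the same windowed series (the small-span fit equals trend +
residual exactly, by construction). Hour-of-day boxplot statistics (median,
quartiles, n per bin, in a configurable local zone, default UTC+1 since the
deployment locale's clock convention is a choice, not data) are computed on
the residual **at observed sample times only**: with 2-hourly sampling only
12 of 24 bins are populated, and the loess values between samples are
interpolation, not data — profiling them measurably distorts the phase
statistics. The increase interval is the longest circular run of positive
median-to-next-median steps (ties broken by total rise); a profile rising
through the whole cycle is flagged degenerate rather than reported as a
24-h interval. The division-hour proxy is the circular midpoint of the
rising arc from the profile's minimum to its maximum — for a symmetric
division burst this estimates the kernel centre regardless of synchrony,
and it is more robust than the increase-interval endpoints, which react to
single noisy bins. The FWS peak hour (earliest on ties, flagged) marks the
pre-division size maximum. Whether hourly boxplots should summarize the
residual or the raw series is genuinely open; the residual is the default
and `use = "raw"` is available.

## Problem sizes and what the tests show

The acceptance studies run at: 50 loess oracle fixtures (n = 100–700);
500 single-sample abundance recoveries (λ = 1080 events); 20 six-cluster
gating samples; 50 lag-recovery and 100 null CCF runs; 100 randomized
three-pulse scenarios (two clusters each); 50 diel seeds at each synchrony
in {0.3, 0.5, 0.8}; and the full 73-day desk-scale campaign twice for the
determinism hash. These sizes keep the whole suite within a desktop run
while leaving the statistical margins (binomial/χ² error of the measured
rates) well inside the asserted thresholds.

Passing them shows the estimators recover the generator's truth under the
generator's assumptions — lognormal optics, raised-cosine pulses, Poisson
sampling, AR(1) forcing noise, a single limiting nutrient, loss as a
constant rate. Real campaigns add instrument drift, optical overlap between
clusters, chain-forming colonies, grazing and advection, none of which the
generator emulates; the gating scheme in particular is calibrated to the
synthetic optics and is not a field scheme. The package's claims about real
data are therefore methodological (the machinery is correct), not
ecological.
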