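---
title: "Circadian analysis of locomotor activity: models, indices and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian analysis of locomotor activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circact)
```

`circact` analyzes binned locomotor-activity records (actograms) from
rodents kept under light-dark (LD) cycles, constant darkness (DD) and
jet-lag protocols, and ships a synthetic actogram generator with known
ground truth so that every estimator in the package can be validated
without animal data. This vignette explains the statistical machinery, the
generator, and the design decisions that were genuinely open.

## Data model

An `activity_series` is a gapless vector of non-negative counts in equal
bins (5 min by default; any width dividing 60). Missing bins are explicit
`NA`s: analyses exclude them from means and variances, report the missing
fraction, and refuse to run when more than 10% of a window is missing.
That threshold is a policy of this package, chosen because silent
imputation can manufacture rhythmicity; records that fragmented need
attention, not averaging. A `light_schedule` describes the protocol as
contiguous LD/DD epochs plus signed shift events (a +6 h event advances
lights-on by 6 h, realized by shortening one dark phase) and named stage
bounds. Zeitgeber Time anchors ZT0 to lights-on; in DD, phase is referred
to activity onset (CT12) instead, so `zt_of()` refuses DD epochs. Day
indices are 0-based and bins are half-open intervals, which keeps stage
segmentation exactly tiling.

## Free-running period: the chi-square periodogram

For each candidate period \(P\) (stepped by one bin across 20-28 h in DD,
23-25 h in LD), the record is truncated to an integer number of cycles and
folded into \(p\) columns. The statistic

\[
Q_p = \frac{n^2}{p}\,
\frac{\sum_{h=1}^{p} (\bar x_h - \bar x)^2}{\sum_{i=1}^{n} (x_i - \bar x)^2}
\]

is \(\chi^2_{p-1}\)-distributed under the null of no rhythm at \(P\),
which supplies the per-candidate significance line (\(\alpha = 0.05\) by
default). The best period is the significant maximum; exact ties break
toward 24 h for determinism. Truncation to whole cycles is deliberate:
unequal column depths would bias the column means. The scan ranges and
level are conventional for rodent work; both are exposed as arguments.

Folding is only defined at whole-bin periods, so the reported period grid
has the resolution of the bin width (5 min = 0.083 h on raw records).

## Nonparametric stability indices

On hourly data (`rebin()` to 60 min happens internally, because the
intradaily index is defined on successive hours), interdaily stability is

\[
IS = \frac{n \sum_{h=1}^{p} (\bar x_h - \bar x)^2}
          {p \sum_{i=1}^{n} (x_i - \bar x)^2},
\]

the variance of the mean cycle profile over the total variance: 1 for a
signal repeating identically every cycle, near 0 for white noise. It
equals \(Q_p/n\) at the same period — an identity the test suite asserts
to `1e-9`, tying the two modules together. The folding period is the
periodogram's best period rounded to the nearest whole hour (hourly
folding needs an integer column count); the rounding is logged. Whether
one should instead interpolate to the exact non-integer period is
an open choice with no canonical answer; rounding is the simplest
reproducible reading, and the identity above pins its semantics.

Intradaily variability,

\[
IV = \frac{n \sum_{i=2}^{n} (x_i - x_{i-1})^2}
          {(n-1) \sum_{i=1}^{n} (x_i - \bar x)^2},
\]

measures hour-to-hour fragmentation: it tends to 0 for a slowly varying
sinusoid (for an hourly-sampled 24-h sinusoid the exact discrete value is
\(4\sin^2(\pi/24) \approx 0.068\)), to about \(2n/(n-1) \approx 2\) for
Gaussian white noise, and to 4 for a maximally alternating sequence. Both
indices are invariant under affine rescaling of the record.

## Wavelet instantaneous period and the V index

Period *stability* over days is assessed with a Morlet continuous wavelet
transform (center frequency 6, the canonical choice; scale-to-period
factor 1.033) over a geometric scale grid spanning 16-32 h, evaluated in
the Fourier domain after demeaning and zero-padding. Cell significance is
tested against a red-noise background: an AR(1) process whose lag-1
coefficient is estimated from the analyzed series itself (the full
analyzed window, the simplest reproducible choice),
with a \(\chi^2_2\) threshold at the 5% level. Cells outside the cone of
influence (e-folding distance of the wavelet response) are never
significant, and track entries outside it are excluded downstream, because
edge artifacts would inflate the apparent period spread.

The instantaneous-period track takes, per time step, the period of the
maximum-power significant cell; steps with no significant cell are
invalid. The track's histogram is summarized by its Shannon entropy
\(SE = -\sum_i p_i \ln p_i\) (natural log, so the normalizer below is also
in nats) and condensed into the variability index

\[
V = 1 - \frac{SE}{\ln N},
\]

which is 1 when all \(N\) valid observations fall in a single histogram
bin and 0 when each occupies its own bin. The histogram bin width defaults
to twice the period-grid resolution of the wavelet scale grid: the usual
shorthand for this choice ("twice the sampling resolution") is ambiguous
between a bin width and a bin count, and a width is the only reading that
yields a well-formed histogram for arbitrary tracks, so that is the
default; the parameter is exposed so other readings remain testable.

## Waveform phase metrics

A mean waveform folds the record at a stated period base — 24 h for LD
stages, the animal's own estimated free-running period for DD — and
averages per phase bin. Activity onset is the phase where the curve rises
above its mean baseline and stays above for at least 2 h; the boundary
case of exactly 2 h counts, since the strict/weak distinction is
unobservable at hourly resolution. When several runs qualify on a
fragmented profile the longest is taken, which makes the rule equivariant
under circular rotation (a property the tests check). Alpha is the total
supra-baseline time, rho the remainder; activity-in-alpha the share of
activity in the supra-baseline bins. The phase angle of entrainment is
\(\psi = (12 - \mathrm{ZT}_{onset}) \times 60\) minutes, positive when
activity starts before lights-off. Diurnal activity implements the
below-baseline rule literally — the share of total activity in *below-baseline*
phase bins — even though the share of activity during lights-on is an equally natural
reading; that alternative is available via
`diurnal_activity(rule = "lights_on")`.

Per-day onsets (needed for the jet-lag fit) apply the same rule to each
single day's hourly profile against that day's own mean. A single day is
much noisier than a mean waveform, so the daily profile is smoothed with a
3-bin circular moving average before thresholding, and the detected start
is then advanced to the first bin that is supra-baseline in the *raw*
profile, canceling the smoothing's early bias. Days without a qualifying
run are flagged missing and dropped, never imputed.

## Jet-lag resynchronization: PS50

After an abrupt 6-h advance, the onset phase (minutes before the
post-shift lights-off) relaxes from its displaced value to the entrained
value. The transition is summarized with the variable-slope sigmoid

\[
y = Bottom + \frac{Top - Bottom}{1 + 10^{(\log PS_{50} - x)\,HillSlope}},
\]

with \(x\) on the log10 axis of days post-shift (day 1 = first cycle under
the new schedule). This is the standard dose-response parameterization:
the fitted curve passes through \((PS_{50}, (Top+Bottom)/2)\), so
\(PS_{50} = 10^{\log PS_{50}}\) is literally the number of days to half
resynchronization. Reading \(x\) as linear days would instead put the
half-point at \(x = \log PS_{50}\), contradicting that definition, which
is why the log-days axis is used on both the generator and the fitting
side. Fits use Levenberg-Marquardt least squares over a small grid of
starting values (asymptotes from the early/late day means, midpoint from
the day nearest halfway, slopes 1 and 3), keeping the converged fit with
the smallest residual sum of squares.

Group comparison uses the extra sum-of-squares F-test,
\(F = [(SS_0 - SS_1)/(df_0 - df_1)] / (SS_1/df_1)\). The default sharing
scheme follows standard curve-comparison practice: the null model shares a
single \(\log PS_{50}\) while Bottom, Top and HillSlope stay
group-specific in both models; the alternative frees \(\log PS_{50}\).
The stricter scheme that also shares the asymptotes across groups is
available (`share = "all_but_ps50"`) but is only appropriate when the
groups share their entrained phase angles: when asymptotes differ by an
hour or more, the misspecified shared asymptotes absorb the PS50
difference and the test loses real effects — we observed exactly this on
simulated cohorts, which is why it is not the default.

## Circular statistics and the masking probe

Rayleigh tests use the mean resultant length \(r = |\sum_k
e^{i\theta_k}|/n\) with the standard small-sample p approximation. The
LD-to-DD phase difference \(\Delta\psi\) compares the circular mean onset
phase over the last 10 LD days (folded at 24 h) with the first 10 DD days
(folded at the animal's own estimated period), expressed in hours on the
24-h circle and wrapped to \((-12, 12]\). Onsets enter as absolute times
(day \(\times\) 24 + clock hour): folding at a non-24-h period must see
real elapsed time, not clock labels. Circular means are used throughout —
arithmetic means break near the wrap point. Group-level coherence of
per-animal \(\Delta\psi\) values is again a Rayleigh test at 24 h; the
between-group contrast is a Student's t-test on the wrapped values, as in
the source analysis chain, with the caveat that a genuinely circular
two-sample test would differ for dispersed samples.

## The synthetic actogram generator

Activity is an inhomogeneous Poisson count process: rate `rate_active`
per bin inside the active phase (duration `alpha_hours` of each cycle),
`rate_rest` outside, with per-bin intensity weighted by the exact overlap
of the bin with the active window. Three degradations mimic pathology:

* `drift_sd` — a Gaussian random walk on the cycle-to-cycle period,
  eroding interdaily stability and the wavelet V index;
* `fragmentation` — each hour-scale bout of the active phase is deleted
  (dropped to the rest rate) with this probability. Bouts, not individual
  5-min bins, are the deletion unit: independent bin-level deletions
  average out at the hourly scale on which IV is defined and would leave
  the fragmentation index blind to them;
* `masking_gain` — counts during lights-on are binomially thinned by this
  factor (1 = no masking), modeling the direct suppressive effect of
  light on activity.

Under a jet-lag schedule the true onset phase follows the PS50 sigmoid
exactly, so resynchronization ground truth is exact by construction
rather than emergent from a dynamic clock model; this keeps round-trip
tests sharp. All randomness flows from one integer seed; identical seeds
give bit-identical records.

The default two-group study (`study_config()`) freezes the conditions the
analyses are validated against: a control-like cohort and a
hypothalamic-lesion-like cohort. The anchored values are free-running
periods 23.58 vs 23.92 h, active-phase durations 13.43 vs 13.08 h, PS50
2.78 vs 3.96 days, post-jet-lag phase angles 3 vs 92.33 min, cohort sizes
6 vs 9 (DD) and 6 vs 6 (jet-lag), 15-day DD screening, and LD staging
with a single 6-h advance. Parameters without a direct anchor were
calibrated once against the target index profile of those cohorts and
then frozen: rest-rate 2.2 against ~85% activity-in-alpha;
drift/fragmentation (0.05, 0.25) and (0.25, 0.45) against IS near 0.44 vs
0.31 and IV near 0.68 vs 1.04; LD rest rates against a ~25-35% diurnal
activity band; masking gains 0.3 vs 0.9 against the direction of the
LD-DD phase-difference contrast (stronger masking in controls). The Hill slope defaults to 3, making
resynchronization to a 6-h advance essentially complete within about ten
days, as in typical murine re-entrainment time courses.

Because each experimental arm emulates its own study condition, the
group configuration carries per-arm overrides: the jet-lag arm's
generator phase is the *expressed* phase angle (what the fitted sigmoid
describes), while the phase-difference arm models a 90-min clock lead
partially hidden by masking. These are different views of the same
animal, not contradictory parameter sets.

What the generator does **not** emulate: ultradian bout structure within
the active phase beyond Poisson noise, light-driven positive masking,
aftereffects of entrainment on tau, gradual tumor progression within a
stage, or inter-animal correlation. Passing tests therefore demonstrate
estimator correctness under the stated statistical structure, not
robustness to every feature of real records.

## Numerical choices and degenerate inputs

* Constant (zero-variance) series make \(Q_p\), IS and IV undefined and
  raise errors rather than returning 0/0 artifacts.
* Histogram probabilities must sum to 1 within `1e-9`; V is clamped to
  `[0, 1]` against floating-point leakage.
* The AR(1) coefficient is clipped to `[0, 0.99]` so the background
  spectrum stays finite on near-integrated series.
* Periodogram folding, IS folding and stage segmentation all truncate to
  whole cycles/days with half-open intervals; nothing is double-counted.
* Gaussian-noise series are real-valued internally (the analyses are
  affine-invariant); only written count files are clipped at zero.

## Problem sizes

The validation suite and the acceptance script run on the scale of the
emulated study itself — 15-day DD records and 26-day jet-lag records in
5-min bins, cohorts of 6-9 animals, 20-seed recovery ensembles, 100-seed
noise ensembles — which keeps every check a faithful miniature of the
real workflow while completing in well under a minute each.

## Known limitations

Hourly folding quantizes IS's period to whole hours, which penalizes
free-running periods far from an integer (a 23.58-h rhythm folded at 24 h
smears); comparisons between groups with different tau therefore mix
stability and rounding effects, exactly as they would in any hourly NPCRA
implementation. Daily onset detection at hourly resolution quantizes the
resynchronization axis to 60-min steps, which widens the sampling
distribution of pooled PS50 estimates relative to fitting the true onset
times. The t-test on wrapped \(\Delta\psi\) values inherits the usual
caveat about linear tests on circular data.
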