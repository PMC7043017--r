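---
title: "Methods: staging, microarchitecture, phenotyping and statistics in somnotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staging, microarchitecture, phenotyping and statistics in somnotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

somnotype analyses telemetric recordings from rodent stress studies in
which sleep is expected to differ between behavioral phenotypes: EEG,
nuchal EMG and locomotor-activity channels are staged into wake (W),
slow-wave sleep (S) and REM sleep (P) in 10-second epochs; hypnograms
are reduced to the outcome measures of such studies (state-time
percentages by photoperiod, awakenings and exaggerated motor responses,
REM fragmentation); animals are phenotyped as active or passive copers
from resident-intruder defeat latencies; and groups are compared with a
mixed-design ANOVA. This vignette explains each model, its parameters
and assumptions, and the design choices that were genuinely open.

## Sleep staging

Each 10-s epoch is summarized by spectral, EMG and activity features.
EEG band powers come from a single Hann-tapered periodogram of the
epoch (the simplest FFT-based estimator); a bin belongs to a band when
its center frequency lies in the half-open interval `[lo, hi)`, which
makes band power additive over disjoint bands. Three bands are used:

* delta, 0.5–4 Hz, the slow-wave band;
* theta, 4–8 Hz, the band dominating rodent REM sleep;
* total, 0.5–25 Hz, the normalization denominator.

Two ratios drive the stage decision: the **delta ratio**
(delta / total power, in [0, 1], high in SWS) and the **theta ratio**
(theta / delta power, high in REM). The delta band's lower edge is a
deliberate choice: definitions of "delta" as low as 0.05 Hz circulate,
but a 0.5 Hz edge keeps the delta ratio inside [0, 1] because the band
then nests inside the total band; the wider variant remains selectable
via `epoch_features(delta = c(0.05, 4))`. EMG is summarized as the RMS
of the mean-subtracted epoch (a scale-appropriate amplitude-versus-
baseline statistic), and activity as the counts falling in the epoch.

Staging is a deterministic threshold tree, applied per epoch:

1. EMG amplitude at or above the wake threshold, **or** any activity at
   or above the activity threshold (default 1 count) scores W — muscle
   tone and movement trump everything;
2. otherwise a delta ratio at or above its threshold (default 0.5)
   scores S;
3. otherwise a theta ratio at or above its threshold (default 2)
   scores P;
4. otherwise the epoch falls back to W, which is conservative against
   inflating sleep.

Commercial scorers implement comparable logic behind an unpublished
probability matrix; a fixed threshold tree was chosen because it is
fully inspectable and testable (an exhaustive truth-table oracle covers
it). The EMG wake threshold is the only data-driven parameter: in a
recording that samples both wake and sleep, the per-epoch log EMG
amplitudes are bimodal (tone versus atonia), and
`calibrate_thresholds()` places the threshold at the midpoint of the
two modes found by two-means on the log amplitudes. When the modes are
not separated by at least a factor 1.5 the calibration falls back to
the 60th percentile with a warning. All four thresholds can be pinned
in the pipeline configuration.

Two optional smoothing rules (`smooth_stages()`) enforce, first, that
REM is entered only from SWS (a P epoch whose previous non-P stage is W
is relabeled W) and, second, that single-epoch stages flanked by an
identical stage are absorbed. Smoothing is off by default for metric
computations so that metrics see raw per-epoch decisions, and is
intended for display.

## Hypnogram metrics

State percentages in a clock window are epoch counts over the window
length; the REM share is computed as the complement of wake and SWS so
the three percentages sum to exactly 100 in floating point. Windows are
half-open `[start, end)` on the epoch grid anchored at the recording's
first sample; off-grid windows are an error rather than a resample, and
consecutive windows partition time. Study values are expressed as
change from baseline in percentage points, with baseline the mean of
the two baseline days.

An **awakening** is any S→W or P→W transition at epoch resolution — no
minimum prior-sleep or minimum-wake duration is imposed, since the
protocols this implements state none. An awakening is an **exaggerated
motor response** when, within the first 10 s after the transition, the
absolute mean-subtracted EMG crosses 200 µV *and* any locomotor
activity is registered in that horizon. Both criteria are required; the
threshold applies to rectified EMG because burst polarity is arbitrary,
and "concurrent" activity can only be resolved at the activity
channel's native 10-s interval.

**REM fragmentation** follows the single/sequential episode taxonomy: a
REM episode is a maximal run of P epochs; it is *sequential* (seq-REM)
when the next episode starts within 3 min (gaps of exactly 180 s count
as sequential, "3 min or less"), and *single* (sin-REM) otherwise. Two
conventions were open and are fixed as: the last episode of a window,
having no follower, is labeled single (the defining "followed within
3 min" condition is satisfiable only by a close follower); and episodes
straddling the window edge are counted when at least one epoch lies
inside, with gaps computed from full episode extents.

## Coping phenotype

Each defeated animal contributes seven daily defeat latencies, capped
at 900 s when no defeat occurs; their arithmetic mean feeds a
two-cluster analysis under the assumption that mean latencies are
bimodal. In one dimension the two-means optimum is a threshold split of
the sorted values, so `two_cluster_partition()` solves the objective
exactly by enumerating all splits (ties to the leftmost split, making
it deterministic). Lloyd iterations from percentile-based starting
centroids were considered and rejected: on unfavourable configurations
they converge to a non-optimal split, which the exact enumeration never
does, at lower cost. The longer-latency cluster is *active* (active
copers resist longer).

`bootstrap_classify()` resamples animals with replacement `n_boot`
times (default 1000; the seed is mandatory), partitions each resample,
and assigns every animal — in-sample or not — to the nearest centroid.
The **active probability** is the fraction of resamples in which the
animal lands in the active cluster; animals with probability ≥ 0.9 are
*active*, ≤ 0.1 *passive*, and strictly inside the band *excluded*
(their classification flipped in more than 10% of resamples). Closed
band edges were chosen; resamples with all-identical values are skipped
and more than 20% of them abort with a not-bimodal error. A rare
resample drawn almost entirely from one component is split internally
by two-means, which can leave reliably classified animals a fraction of
a percent away from probability 0 or 1; the labeling band absorbs this.

## Group statistics

The study design is split-plot: a between-subjects group factor
(control / passive / active) crossed with a repeated timepoint factor.
`mixed_anova()` tests group against the subjects-within-group error and
time and group×time against the time-by-subjects error; missing cells
are an error, never imputed. The Greenhouse–Geisser epsilon — computed
from the pooled *within-group* covariance of the repeated measures, the
split-plot convention — multiplies the within-subject degrees of
freedom (default on; F statistics are unchanged). Note that some
software computes epsilon without removing group means first, which
conflates group separation with nonsphericity; the pooled-within form
is used here. `tukey_hsd()` performs the post hoc pairwise
comparisons with the studentized-range distribution and the
Tukey–Kramer allowance for unequal group sizes; in the pipeline it is
run per timepoint with the pooled within-timepoint error, the
conservative reading of an unstated convention. `two_sample_t()` is the
pooled-variance test used for two-group latency contrasts, with the
degenerate zero-variance case fixed to `t = 0, p = 1` when means agree.

Type-I calibration is verified on null simulations with iid noise, for
which sphericity holds exactly; the uncorrected F tests are asserted to
reject at 3–7% (α = 0.05). The Greenhouse–Geisser correction is left
out of that particular assertion deliberately: under true sphericity
the estimated epsilon is below 1 and the corrected test is known to be
mildly conservative, so including it would measure the correction's
bias, not the decomposition's calibration.

## Synthetic ground truth

The generator exists so every stage of the analysis can be validated
against known truth without animal recordings. Stage dynamics are
semi-Markov: geometric bout lengths with state- and photoperiod-
specific means, and an embedded transition matrix per photoperiod with
W→P forbidden (REM entered only from SWS). Defaults were set once to
qualitative rodent values — roughly 70% sleep in the light period
(bout means W 9, S 18, P 6 epochs) and 70% wake in the dark (W 30,
S 10, P 4), with a 12-h light cycle (lights on 07:00). After a REM
bout, with probability 0.3 a short SWS gap (≤ 18 epochs) is inserted
and REM resumes, reproducing the clustering of sequential REM episodes.

Signals are state-conditioned: EEG is Gaussian noise spectrally shaped
in the frequency domain to the stage's band weights (SWS 75% delta,
REM 75% theta, wake broadband; total RMS 100 µV); EMG is white noise at
30/10/5 µV RMS in W/S/P (tone, reduced tone, atonia); activity is
Poisson at 3 counts per wake epoch and 0 in sleep. Injected arousal
events add a 1-s Hann-windowed 20 Hz burst of specified peak amplitude
2 s into the first wake epoch, and force the epoch's activity positive
or zero to build designed positives and negatives for the detector.
Defeat latencies are normal per day around a passive (540 s) or active
(776 s) component mean with 80 s daily scatter, floored at 1 s and
capped at 900 s; seven-day means then scatter by about 30 s, so the
components are cleanly separable. A passive animal drawn nearly 4 sd
above its component mean is genuinely indistinguishable from an active
one — a ~10⁻⁴-per-animal tail event that bounds what any classifier
can do on these data.

What the generator does **not** emulate bounds what passing tests show
about real data: there is no 1/f background, no spindles or
theta rhythmicity, no movement artifacts, no circadian drift within
photoperiods, and state-conditioned distributions are exactly
stationary. Staging accuracy near 100% on this synthetic data
demonstrates correctness of the pipeline's logic, not expected field
performance on noisy telemetry.

## Numerical choices and problem sizes

Epoch grids are anchored at the first sample; trailing partial epochs
are dropped with a message. EDF output quantizes each channel to
16 bits over its own amplitude range (integer activity counts
round-trip exactly). Band powers use one-sided periodogram bins with
the Nyquist bin halved; the zero-variance ANOVA convention (`F = 0,
p = 1`) triggers on sums of squares below 10⁻¹² of the total. The
bundled validation runs use desk-scale sizes chosen to exercise every
code path: one 24-h recording at 250 Hz for staging recovery, 100
designed arousal events at 125 Hz, 1000 random hypnograms for the
counting oracles, 100 simulated cohorts (15 + 8 animals, 1000 bootstrap
resamples) for phenotype recovery, 1000 null panels for ANOVA
calibration, and a five-animal, five-timepoint pipeline study at
100 Hz.

## Known limitations

Staging thresholds are global per recording (no time-varying
calibration); sub-epoch microarousals are invisible at the 10-s grid;
the REM-entry smoothing rule is a stand-in for transition priors, not a
claim about any commercial scorer; the exclusion band convention
(closed at 0.1/0.9) and the last-episode labeling rule are fixed
choices among defensible alternatives; and the ANOVA covers the
two-factor split-plot design only — random-slope mixed models and
nonparametric alternatives are out of scope.
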