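---
title: "Linking cortical silent periods to action stopping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking cortical silent periods to action stopping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopcsp)
```

## The scientific question

The stop-signal task measures how quickly a person can cancel an initiated
response: the stop-signal reaction time (SSRT), estimated from the go-RT
distribution, the stopping success rate, and the stop-signal delay (SSD).
Transcranial magnetic stimulation over primary motor cortex during tonic
contraction produces a motor evoked potential (MEP) followed by a cortical
silent period (CSP) — a transient suppression of voluntary EMG whose duration
indexes GABA~B~-mediated intracortical inhibition. This package implements,
end to end, the analysis chain needed to ask whether individual differences in
CSP duration track individual differences in SSRT: a race-model task
simulator, a ground-truthed EMG synthesizer, SSRT estimation and participant
screening, automated MEP/CSP extraction, and a robust correlation plus
cross-validation inference layer.

Because raw participant data for studies of this design are typically
available only on request, the synthetic cohort is a first-class module, not
a test fixture: it encodes the study conditions (27 participants, 5 x 96-trial
blocks with 25% stop trials, 20 TMS pulses per participant) and a tunable
latent coupling between true CSP and true stop latency, so every downstream
stage can be validated against known ground truth.

## The behavioral simulator

Each trial draws an ex-Gaussian go finish time; on stop trials it races
independently against `SSD + stop latency`, the stop latency being Gaussian
truncated at zero. A response escapes on a stop trial when the go process
finishes before the stop process, and any go finish slower than the 1 s
response window counts as an omission. The SSD follows the one-up/one-down
staircase (start 250 ms, step 50 ms, clamped to [0, 900] ms), carried
continuously from the practice block onward, which drives the probability of
responding on a stop trial toward one half.

The default participant (`behavior_model()`) uses ex-Gaussian parameters
mu = 466, sigma = 68, tau = 80 ms, chosen so the go-RT mean (546 ms) and SD
(105 ms) match the behavioral table the generator emulates; `stop_mu = 215` ms
matches the group-mean stop latency. Three values are not derivable from any
published quantity and were fixed once:

* `stop_sigma = 30` ms — trial-to-trial stop-latency variability, set within
  the range reported for healthy adults (the published 21 ms figure is a
  between-subject SD, a different quantity);
* `p_omission = 0.015` — together with the natural >1 s tail of the
  ex-Gaussian (~0.2%) this reproduces ~2% go omissions;
* `p_choice_error = 0.004` — reproduces 99.6% go accuracy.

Trigger failures (`p_trigger_failure`) are exposed because the consensus
stop-signal framework discusses them, but default to zero. The stop-trial
response rule is `trigger failure OR go < SSD + stop`, gated by the response
window; attentional lapses (`p_omission`) apply to go trials only.

Sampling bounds, not inference, motivate two conventions: SSD bounds keep the
stop signal displayable inside the 1 s trial, and responses slower than 1 s
are omissions because the go stimulus itself lasts 1 s.

```{r session}
tt <- simulate_session(sst_design(), behavior_model(), seed = 1)
s <- summarize_session(tt)
c(ssrt = s$ssrt, p_respond = s$p_respond_signal, go_rt = round(s$go_rt))
```

## SSRT by the integration method

`estimate_ssrt_integration()` builds the go-RT set from **all** experimental
go trials — omissions replaced by the maximum observed go RT, choice-error
RTs included — sorts it, and subtracts the mean SSD (over all stop trials)
from the `n`th value, `n = clamp(round(p(respond|signal) * N_go), 1, N_go)`.
Three conventions here are genuinely open in the literature and are fixed,
documented choices:

* the quantile index uses round-half-away-from-zero; the alternative
  conventions differ by at most one order statistic, an O(1/N_go) effect;
* mean go RT and the go-RT set include choice-error trials (their RTs are
  valid go-process finish times);
* mean SSD averages over all stop trials, successful or not, consistent with
  how the staircase samples SSDs.

The five-criterion exclusion screen (`apply_exclusion_criteria()`) uses the
printed strict inequalities: stopping success outside (40%, 60%), omissions
above 25%, choice errors above 10%, race-model violation (unsuccessful-stop
RT above go RT), SSRT below 50 ms. The choice-error rate is passed separately
from the summary because accuracy is defined on responded trials and the two
would otherwise be one number defined twice.

## The EMG synthesizer

A sweep is 600 ms at 8 kHz with the stimulus at 200 ms: band-limited
(20-250 Hz) Gaussian background scaled to an exact 0.05 mV RMS — 30% of the
maximal-contraction RMS — plus a deterministic biphasic MEP (0.49 mV
peak-to-peak, 35 ms, 22 ms latency) and a silent period during which the
background is attenuated to `silence_floor = 0.02` before ramping back over
10 ms. Two synthesis choices matter and were validated numerically before
being frozen:

* **The MEP waveform is a steep-edged biphasic pulse**,
  `sign(sin) * |sin|^0.4` over one period, not a smoothly tapered sinusoid.
  Compound muscle action potentials rise and fall steeply; with a strongly
  tapered waveform no threshold detector can recover the nominal duration,
  because several milliseconds of taper per edge sit below any plausible
  threshold.
* **The background is silenced from MEP onset**, not merely after MEP offset:
  voluntary drive ceases during the compound potential itself. Superimposing
  full-amplitude background on the MEP would also inflate its detected
  peak-to-peak amplitude by the noise excursion (~0.05-0.08 mV). The
  ground-truth CSP still spans MEP offset to activity return.

The generator does **not** model electrode placement, amplifier electronics,
mains interference, movement artifacts, habituation, or non-stationary
contraction drift; the background is stationary within a sweep. Passing the
recovery tests therefore shows that the detectors implement their rules
correctly at a realistic signal-to-noise ratio, not that they are robust to
every artifact class real recordings contain.

## MEP and CSP detection

All thresholds are *baseline-relative*, computed per sweep from the
pre-stimulus window [-110, -10] ms (100 ms ending safely before the
stimulus), which makes detection exactly invariant to rescaling the sweep.
The envelope is full-wave rectification followed by a 5 ms centered moving
average.

The MEP stage compares the rectified raw signal against the rectified-raw
baseline mean + 2 SD; the CSP stage compares the envelope against envelope
statistics. Keeping each comparison dimensionally consistent is essential at
this sampling rate: the envelope's baseline SD is ~1/3 of the raw signal's,
and a rectified-raw comparison against envelope-derived statistics would set
its threshold at ~1.4 sigma of the noise, yielding false MEP onsets on a
fifth of sweeps (measured during design).

* **MEP onset** — first time in the post-stimulus search window ([10, 60] ms,
  after a 5 ms artifact blank) where the rectified raw signal exceeds
  threshold and dwells there >= 3 ms. **Offset** — first >= 3 ms sub-threshold
  dwell after the rectified-raw peak. The dwell suppresses both single-cycle
  noise excursions (a 2 ms dwell still passed ~18% of pure-noise sweeps;
  3 ms passes ~1.5%) and the instantaneous zero crossing of the biphasic
  waveform.
* **CSP end** — first time at or after MEP offset where the envelope stays at
  the pre-stimulus level for >= 10 ms continuously. The nominal threshold is
  baseline mean - 2 SD, floored at 0.25 x baseline mean. The floor is not
  cosmetic: a rectified envelope is nonnegative, so flooring at zero would
  make the return condition vacuously true (CSP = 0) on the ~5% of sweeps
  whose baseline SD exceeds half the baseline mean. The silent-period
  envelope sits near 0.02 x baseline and the recovered level near 1.0, so
  any floor well inside (0.02, 1) separates the two states; 0.25 is
  config-exposed (`csp_floor_frac`).

At the default signal-to-noise ratio the detector's median absolute CSP error
is ~3.5 ms with a detected-vs-true regression slope of ~1.0 over the
50-200 ms range, and MEP amplitude/duration are recovered within 5% / 3 ms.
A +2-4 ms mean CSP bias remains (threshold crossings occur a little into the
recovery ramp); it is shared across participants and so does not attenuate
between-subject correlations.

The contraction-level screen divides the pre-stimulus RMS by the
participant's MVC **RMS**. The conventional MVC figure (mean peak-to-peak
per 500 ms window, in microvolts) is reported alongside, but an RMS must be
normalized by an RMS: for band-limited EMG the windowed peak-to-peak is
~7x the RMS, and dividing by it would misclassify a true 30% contraction as
~4% and reject every sweep. `compute_mvc()` therefore returns both forms.

## The coupled cohort

`generate_population()` draws a latent standard-normal trait per participant
and loads it onto both true CSP (106 +/- 26 ms) and true stop latency
(215 +/- 21 ms) with loading `sqrt(|rho|)`, giving `cor = rho` in
expectation. The default `coupling_rho = 0.6` was fixed once to the magnitude
of the observed CSP-SSRT association this generator emulates (r ~= 0.59) and
is not revisited by any test. Per-pulse CSP jitters around the participant's
true value with SD 8 ms, a plausible within-subject trial-to-trial
variability (unreported in the source literature). Each participant also gets
a resting motor threshold (55 +/- 4% of stimulator output) carried as
uncorrelated metadata, so the specificity of the CSP-SSRT association can be
tested against a variable that should correlate with nothing.

One global seed is split deterministically into per-participant seeds (and
those into per-pulse seeds), so any participant's data can be regenerated
without the rest and all outputs are bit-reproducible.

A deliberate simplification: all participants share the same go process, so
between-subject variance in mean go RT and SSD is far smaller than in real
cohorts (where it is dominated by go-speed differences). The CSP-SSRT
question is unaffected — SSRT variance is driven by the stop process — but
analyses of go-RT heterogeneity would need the behavior model varied per
participant.

## Robust inference

`pearson_family()` is a thin wrapper over `stats::cor.test()` that screens
several predictors against one outcome at a Bonferroni-adjusted alpha
(reported at full precision, 0.05/4 = 0.0125).

`skipped_pearson()` implements the projection-based skipped correlation: a
minimum-covariance-determinant center (`MASS::cov.rob`; exhaustive and hence
deterministic at the cohort sizes targeted here), projection of all points
onto the direction from the center to each point, the MAD-median rule with
cutoff `sqrt(chi^2_{2, 0.975})`, union of flags over projections, then
Pearson's r on the unflagged points. On exactly collinear data the MCD is
undefined and the center falls back to the coordinate-wise median, which is
all the projection step needs. Inference is a percentile bootstrap of the
*entire* procedure over resampled subject pairs (2000 resamples, 95% CI;
p is twice the smaller tail of the bootstrap distribution at zero).
Re-running the outlier search inside every resample is the honest bootstrap
of the estimator actually used, and is wider than bootstrapping the
once-cleaned sample: resamples with duplicated points can flag aggressively,
so the CI reflects outlier-search instability as well as sampling noise.
This is a documented property, not a defect; the point estimate and the
permutation test below carry the confirmatory weight.

`loocv_predict()` computes leave-one-out predictions of the outcome from the
predictor via the exact OLS identity `pred_i = y_i - e_i / (1 - h_i)`,
algebraically identical to refitting each fold (and unit-tested against
explicit refits). Because LOO folds share n - 2 points, the usual parametric
p for the predicted-observed correlation is invalid;
`loocv_permutation_test()` shuffles the outcome (5000 times by default) and
reruns the pipeline per shuffle. The null distribution of a cross-validated
prediction correlation is *negative-biased* — under independence the
regression line chases noise and predictions anti-track the left-out values,
so null r values near -0.5 are routine at n = 27. A two-tailed p therefore
cannot fold the null at zero: the test doubles the smaller tail of the
empirical null at the observed value, with the +1 correction in each tail
(minimal attainable p: `2/(n_perm + 1)`). Folding at zero (counting
`|r_null| >= |r_obs|`) would report p ~= 0.37 for an observed r of 0.51 that
not one of 5000 shuffles exceeded — a miscalibration, confirmed by the
type-I-error suite, not a conservative variant.

## Problem sizes used by the validation suite

The test suite exercises every property at sizes chosen to give stable
verdicts: staircase calibration over 100 sessions; SSRT recovery on sessions
of 10,000 go / 2,500 stop trials (20 replicates, median error bounded by
10 ms); CSP recovery over 10 participants x 20 pulses plus exact index-level
agreement with an exhaustive scan oracle on 100 sweeps; permutation type-I
error over 200 null replicates of 500 shuffles; and end-to-end power over 50
full pipeline replicates at coupling 0.6, n = 27 (the power criterion asks
for a positive skipped r with permutation p < 0.05 in at least 60% of
replicates; measurement noise attenuates the latent coupling, so this is a
lower bound, not an equality). The planted-outlier check is asserted on the
median over 20 replicates because the skipped estimator legitimately trims
borderline points in a ~quarter of draws at n = 27, shifting r by slightly
more than the 0.1 tolerance on those single draws.

## Known limitations

* The simulator assumes i.i.d. trials: no fatigue, sequential effects, or
  post-stop slowing.
* The EMG background is stationary Gaussian; real tonic EMG has burst
  structure and slow drift, and real silent periods end gradually rather
  than with a linear ramp.
* The skipped-correlation family follows the projection/MCD variant; numerical
  agreement with any specific external toolbox build is not claimed beyond
  the properties tested here.
* The MEP/CSP detector thresholds are validated against this package's
  generator; applying them to recordings with different bandwidths or
  contraction levels may require retuning `csp_config()`.
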