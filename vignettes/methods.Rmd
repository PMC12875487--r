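---
title: "Modelling rhythmic and melodic expectations in continuous EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling rhythmic and melodic expectations in continuous EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`musictrf` implements a complete analysis chain for asking whether continuous
EEG recorded during music listening encodes *probabilistic* expectations about
upcoming notes — and whether those expectations are carried by the rhythmic
(note timing) or the melodic (pitch) structure of the stimulus. This vignette
is the package's own account of the models involved, the choices we made where
the design was genuinely open, and what the synthetic-data tests do and do not
establish.

## 1. From melodies to information

A monophonic melody is an onset-sorted sequence of pitched events. Two
discrete *viewpoint* sequences summarize it:

* **cpitch** — the raw MIDI note numbers, defined from the first note;
* **ioi-ratio** — the ratio of each note's preceding inter-onset interval
  (IOI) to the one before it, defined from the third note. Ratios are rounded
  to six decimals before symbolization, so rhythms quantized to a sixteenth
  grid produce a small exact alphabet; this rounding grid is our choice, since
  sub-grid ornaments have no canonical symbolization.

Each viewpoint feeds a variable-order Markov model with *prediction by
partial matching* (PPM) smoothing: escape method C with interpolated (not
back-off) blending, no update exclusion, and a default maximum context length
of 10. At a context $c$ with total count $T$ and $t$ distinct continuations,

$$ p(s \mid c) \;=\; \frac{n(c,s)}{T + t} \;+\; \frac{t}{T + t}\, p(s \mid c'),$$

bottoming out in a uniform distribution over the alphabet. PPM internals are
not uniquely pinned down by the literature that popularized this analysis
style, so the exact recursion above is frozen by an oracle test: an
independent brute-force implementation must agree to $10^{-10}$ over all short
sequences.

Note-by-note **surprise** is $-\log_2 p(\text{observed symbol})$ and
**entropy** is the Shannon entropy of the predictive distribution, computed
separately for pitch ($S_p, E_p$) and timing ($S_t, E_t$). Predictions come
from two models: a *short-term* model built online from the unfolding melody,
and a *long-term* model trained on the other melodies of a seed-deterministic
k-fold resampling of the stimulus set (10 folds by default), optionally plus a
pretraining corpus. In the default "both+" configuration the long-term model
also updates online, note by note, within the held-out melody; whether the
reference analyses updated within or only between melodies is not documented,
so a switch (`ltm_mode`) exposes both readings. The two predictive
distributions are fused by an entropy-weighted geometric mixture,
$w_m \propto (H(p_m)/\log_2|A|)^{-b}$ with bias $b = 2$ (exposed in the
configuration): the more certain model dominates.

The first two notes of a melody have no defined ioi-ratio; their timing
surprise is marked undefined and enters the regressor bank as a
zero-amplitude impulse, which leaves all other notes unaffected.

## 2. Stimulus generation

Two generators provide the package's stimuli.

**Shuffled controls** reproduce the construction used for the experimental
control condition: pitches are permuted (identical multiset), and IOIs are
redrawn i.i.d. from a Gaussian centered on the source's mean IOI with
standard deviation `mean(IOI) − min(IOI)` — the most literal reading of the
described "added variation", exposed as `ioi_sd_rule`. Draws below half a
sixteenth are rejected and redrawn (rejection preserves the Gaussian shape
better than clamping), and accepted draws snap to the sixteenth grid,
preserving integer ratios. The low-side truncation biases the mean IOI
upward; with sources whose dispersion is moderate (as for quantized music)
the bias stays well under the 15% band the tests assert.

**Synthetic corpora** are sampled from one fixed random Markov process per
seed: a 15-pitch alphabet and an 8-symbol IOI-ratio alphabet
$\{1/2, 2/3, 3/4, 4/5, 5/4, 4/3, 3/2, 2\}$, closed under reciprocals so a
uniform draw has zero log-drift. Transition rows are a single-cycle
permutation backbone softened by a `temperature` parameter: 0 gives
deterministic repeating patterns, large values approach i.i.d. uniform draws.
Realized IOIs follow the sampled ratios multiplicatively from a 0.5 s base,
reflecting a ratio to its reciprocal when the IOI would leave
[0.125 s, 2 s]. Because ratios like 2/3 cannot stay on a sixteenth grid under
composition, synthetic corpora are *not* grid-snapped; grid snapping is a
property of the shuffling procedure, where it belongs.

One estimator caveat, documented rather than hidden: at high temperature the
generator approaches uniform sampling, so timing surprise should approach
$\log_2 8 = 3$ bits. Deep interpolated PPM is overconfident on i.i.d. data —
measured surprise plateaus near 3.6 bits at `max_order = 10` regardless of
corpus size, because sparse high-order contexts receive non-vanishing weight.
The uniform-limit test therefore measures with a model whose order matches
the generating chain (`max_order = 1`, landing at ≈3.24 bits). This is a
property of the estimator, not of the generator, and the generator's
parameters were chosen once, independent of any test outcome.

## 3. Regressors

The regressor bank is sampled at 100 Hz (the preprocessing target rate). All
event features are impulse trains at note onsets: acoustic onset (amplitude
1), preceding IOI (ms), absolute inter-pitch interval (semitones), and the
four information features $S_p, S_t, E_p, E_t$; a subsequent-IOI control
column is available. Acoustic features come from audio: a log-spaced
gammatone filterbank (Slaney's fourth-order cascade, 100–8000 Hz, 128 bands
by default), per-band Hilbert envelopes, and from them the summed envelope,
its half-wave-rectified derivative, and spectral flux (the band-summed
half-wave-rectified envelope increase). For speed the filterbank is applied
in the frequency domain and each band envelope is demodulated directly at a
decimated rate; a time-domain cascade is kept for reference. Since the
original piano soundfont is not distributable, melodies are rendered as
exponentially decaying six-harmonic tones with a 5 ms ramp at constant
velocity; the tests assert what the analysis needs — flux peaks aligned with
note onsets within ±20 ms — not timbre.

Every column is normalized to unit root-mean-square *per melody*, matching
the per-melody normalization of the reference analysis; all-zero columns are
exempt.

## 4. Encoding model and variance partitioning

The forward model is a multivariate lagged ridge regression (a temporal
response function, TRF) with lags −50…+400 ms at 100 Hz (46 lags), an
identity ridge penalty, and an unpenalized intercept handled by centering.
Training pools real and shuffled melodies; evaluation is leave-one-melody-out,
and predictions are scored per channel by Pearson correlation against a
**super-subject** ground truth — the sample-wise average EEG over all
subjects — which stabilizes the correlation target across subjects of very
different SNR. The ridge parameter is selected per subject on the decade grid
$10^{-4}…10^{8}$ by maximizing mean accuracy over folds and channels.

The implementation exploits two structural facts: design matrices depend only
on the stimuli, so per-fold Gram eigendecompositions are shared across
subjects; and correlations require only quadratic forms of the test-fold
design, so no per-lambda predictions are materialized. A test pins the engine
to a naive fit-and-predict oracle at $10^{-8}$.

Unique contributions are estimated by *variance partitioning*: a reduced
model keeps the design's dimensionality but permutes the amplitudes of the
features of interest across that melody's onsets (seed-deterministic, never
across melodies). Five reduced models mirror the reference analysis:
high-level ($S_t,E_t,S_p,E_p$), timing ($S_t,E_t$), pitch ($S_p,E_p$), IOI,
and IPI. $\Delta r = r_{\text{full}} - r_{\text{reduced}}$ is averaged over
each subject's region of interest — the top 25% of channels by full-model
accuracy pooled over conditions, so the ROI is independent of condition and
regressor set; ties break by channel order. By default one randomization is
used (matching the reference analysis), with an option to average several.
The reduced models reuse the subject's full-model lambda rather than
re-selecting it: the selection rule for reduced models is not documented in
the sources this design follows, reuse keeps the full/reduced comparison
matched, and it cuts the grid cost six-fold; `reselect_lambda = TRUE`
restores per-model selection.

Group statistics combine paired Wilcoxon signed-rank contrasts on
subject-level means with a linear mixed model
`dr ~ Condition * Model + (1|subject) + (1|melody)` fitted by maximum
likelihood, tested by likelihood-ratio $\chi^2$ on nested fits, with
Tukey-adjusted follow-up contrasts via `emmeans`. The unit of analysis is the
subject × melody × condition × model mean over ROI channels, keeping melody
as a random-effect level.

## 5. EEG preprocessing

The deterministic chain is: order-3 Butterworth bandpass 1–30 Hz applied
forward-backward (zero phase), anti-aliased resampling to 100 Hz, iterative
bad-channel detection (per-trial mean, SD and peak-to-peak, each compared to
the cross-channel distribution at 2.75 SD, repeated until stable, metrics
z-scored per metric), re-referencing to the average of F9/F10/P9/P10/Iz with
bad channels excluded from the reference, and neighbor-mean interpolation
within 18 mm (repeated once if re-detection still flags channels). Published
third-party denoising stages (artifact subspace reconstruction, ICA-based
eye-artifact labelling) are represented by a pluggable `denoise_hook` and
deliberately not reimplemented; the synthetic studies do not need them.

## 6. ERPs and cluster permutation

Note-locked epochs span −100…+500 ms with a −50…0 ms baseline; boundary
notes are skipped and counted. Trials whose overall SD exceeds the mean
trial-SD by 2.5 SDs of that distribution are rejected (the rejection metric
is one reading of an ambiguous description and is configurable). Within each
melody, notes in the top and bottom 20% of surprise are labelled high-S and
low-S (ties by note order), and subject-level ERPs are averaged per
condition and quantile over the trimmed −50…+400 ms window.

The paired contrast uses a cluster-based permutation test: point-wise paired
t statistics thresholded at the 0.025 tail, suprathreshold points clustered
by spatiotemporal adjacency, cluster mass = summed t, and a sign-flipping
Monte-Carlo null (1000 iterations by default) of the maximum absolute mass.
The "at least three neighboring electrodes" requirement is implemented as a
cluster-extent criterion — clusters spanning fewer than three distinct
electrodes are discarded, identically in the observed data and in every
permutation, which preserves the exactness of the permutation null. (The
alternative reading, an iterative per-point filter demanding three
suprathreshold spatial neighbors per sample, removes every suprathreshold
point under pure noise and drives the realized type-I error to zero; we
verified this numerically and rejected it.) Channel adjacency uses a radius
rule on the montage, calibrated to a median of 6–8 neighbors on the
synthetic 64-channel layout. The component finder and permutation loop are
implemented in C++ for throughput.

## 7. The synthetic study and what it shows

`make_fixture_study()` builds the package's stand-in for a full experiment:
a structured corpus with shuffled controls (by default 10 + 4 melodies),
per-melody regressors, and multi-subject EEG in which each active feature is
convolved with a planted kernel (difference-of-gammas producing an
N1–P1–N2–P2 morphology within 0–400 ms, a smooth scalp topography per
feature), with per-subject latency jitter (SD 10 ms), log-normal gain (SD
0.2), and spatially correlated $1/f$ noise scaled to a requested in-band
signal-to-noise ratio. By default the timing-information features ($S_t,
E_t$) drive responses only to real melodies while acoustic onset and IOI
drive both conditions — the generative analogue of the effect the pipeline
is designed to detect. The generator returns the exact per-subject kernels,
so every downstream stage has a parameter-recovery test.

The calibration suite verifies, among others: kernel recovery (relative
error $<10^{-4}$ noiseless; weight-kernel correlation $>0.95$ at SNR 1),
directional predictability contrasts between structured and shuffled
corpora, a positive group-level $\Delta r$ for timing with pitch within 2
standard errors of zero under the timing-only generative model, detection of
the Condition × Model interaction in at least 90% of repetitions, cluster
type-I error within a binomial band around 5%, and byte-identical pipeline
outputs under a fixed seed. One statistical subtlety: because the stimuli
are fixed across simulated subjects, chance within-melody correlations
between the pitch and timing amplitude sequences induce a small
fixed-stimulus component in $\Delta r_{\text{pitch}}$ that a subject-level
standard error cannot capture (real stimulus features are correlated in just
this way). The pitch-null check therefore uses the melody as the error unit
— the variance unit that actually samples the stimulus.

Problem sizes in the default test and acceptance runs are deliberately
modest — e.g. 6–14 melodies of 25–60 notes, 16–64 channels, 4–30 subjects,
and 100–500 permutation iterations — chosen as the smallest designs at which
the calibrated properties are stable.

**What passing does not show.** The synthetic EEG is linear in its
regressors with Gaussianized noise; real neonatal EEG has non-stationary
artifacts, state changes, and nonlinearities that only the pluggable
denoising hooks would address. The melody generator produces Markovian
structure, not tonal music: it validates the machinery's direction and
calibration, not any claim about real infants. The PPM model is pinned to
one defensible smoothing variant, not to bit-compatibility with any specific
historical implementation.

## 8. Known limitations

* No backward (decoding) models, banded ridge, or time-resolved penalties.
* No multiple-viewpoint linking (joint pitch × timing alphabets).
* The MIDI layer targets monophonic type-0/1 files only, by contract.
* Mixed-model follow-ups assume the default treatment parameterization;
  heavily unbalanced designs should use the tidy `delta_r_table()` output
  with external tooling.
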