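# musictrf

Does continuous EEG encode *probabilistic* musical expectations — and are
those expectations carried by rhythm (note timing) or melody (pitch)?
`musictrf` is an R package that implements the full analysis chain for this
question, end to end, together with synthetic-data generators that give every
stage a ground truth:

1. **Symbolic music** — read/write standard MIDI and a plain-text note table;
   derive the discrete *cpitch* and *IOI-ratio* viewpoint sequences and local
   interval features (IOI, IPI).
2. **Information dynamics** — a variable-order Markov model with PPM
   smoothing (escape C, interpolated, max order 10) produces note-by-note
   surprise and entropy for pitch (Sp, Ep) and timing (St, Et), combining a
   short-term model learned online from the unfolding melody with a
   long-term model trained by 10-fold resampling over the stimulus set
   ("both+": the long-term model also updates online).
3. **Regressors** — impulse trains at note onsets (onset, IOI, IPI,
   Sp/St/Ep/Et) plus acoustic features from a gammatone filterbank (spectral
   flux, envelope, envelope derivative), each normalized to unit RMS per
   melody.
4. **Encoding model** — multivariate lagged ridge regression (temporal
   response functions, lags −50…+400 ms), leave-one-melody-out
   cross-validation, per-subject lambda on the grid 10⁻⁴…10⁸, accuracies
   scored against a group-average "super-subject" EEG.
5. **Variance partitioning** — reduced models with onset-shuffled feature
   amplitudes; Δr = r(full) − r(reduced) over the top-25% accuracy ROI;
   Wilcoxon signed-rank and mixed-model (lme4 + emmeans) group statistics.
6. **ERPs** — surprise-quantile (top/bottom 20%) note-locked potentials with
   cluster-based sign-flip permutation testing over channels × time (Rcpp
   core).
7. **Synthetic studies** — melody corpora with tunable Markov structure,
   shuffled control stimuli, and multi-subject EEG generated by convolving
   planted response kernels with the regressors plus 1/f noise.

The scientific core in one line: for stimulus features
$x_f(t)$ and EEG channel $y_c(t)$, fit
$y_c(t) = \sum_f \sum_{\tau=-50\,\text{ms}}^{400\,\text{ms}} w_{c,f,\tau}\,
x_f(t-\tau) + \varepsilon$ by ridge regression, and measure each feature
set's unique contribution as the drop in cross-validated prediction accuracy
when its amplitudes are temporally randomized.

## Worked example

A small synthetic study, end to end:

```r
library(musictrf)

cfg <- run_config(n_real = 6, n_shuffled = 2, n_subjects = 6,
                  n_notes = 30, n_channels = 32, use_acoustic = FALSE,
                  folds = 4, n_perm = 200, seed = 42)
res <- run_pipeline(cfg)

res$accuracy$full
#> <accuracy_table 'full'> 6 subjects x 8 melodies x 32 channels, mean r=0.5359

aggregate(dr ~ condition + model, res$delta, mean)
#>    condition     model            dr
#> 1       real highlevel  1.159428e-01
#> 2   shuffled highlevel -1.901852e-02
#> 3       real       ioi  2.952476e-02
#> 4   shuffled       ioi  4.616475e-02
#> 5       real       ipi -2.142806e-04
#> 6   shuffled       ipi  9.475666e-04
#> 7       real     pitch  2.524426e-03
#> 8   shuffled     pitch -4.622928e-05
#> 9       real    timing  1.148689e-01
#> 10  shuffled    timing -2.178734e-02

res$stats_timing_pitch$lrt
#>              term     chisq df            p
#> 1       condition  89.54562  1 2.996490e-21
#> 2           model  23.93740  1 9.951959e-07
#> 3 condition:model 179.44938  1 6.392097e-41
```

Read it as the pipeline's designed-in result: the synthetic EEG encodes the
timing-information features (St, Et) for real melodies only, and the analysis
recovers exactly that — Δr for the timing model is large and positive in the
real condition, near zero in the shuffled condition and for the pitch model,
while low-level IOI tracking appears in both conditions; the Condition ×
Model interaction is highly significant.

A thin CLI wraps the same API:

```sh
Rscript inst/cli/musictrf-cli.R make-fixture --out fixture/ --seed 1
Rscript inst/cli/musictrf-cli.R run-all --out results/ --seed 1
```

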