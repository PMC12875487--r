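# Deterministic EEG preprocessing: zero-phase Butterworth bandpass +
# anti-aliased resampling, iterative bad-channel detection, custom-average
# re-referencing, and neighbor-mean interpolation. Third-party denoising
# stages (artifact subspace reconstruction, ICA-based eye-artifact removal)
# are pluggable hooks, not reimplemented here.

#' EEG recording container
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate (Hz).
#' @param channel_names character vector, one per row of `data`.
#' @param positions numeric matrix channels x 3 (mm), rownames = channels.
#' @param bad_channels character vector of flagged channel names.
#' @param reference reference description.
#' @param segments optional integer vector assigning each sample to a trial
#'   (melody) segment; used by per-trial quality metrics.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names = NULL, positions = NULL,
                          bad_channels = character(0),
                          reference = "none", segments = NULL) {
  if (is.null(channel_names)) {
    channel_names <- sprintf("Ch%02d", seq_len(nrow(data)))
  }
  rownames(data) <- channel_names
  if (!is.null(positions)) {
    stopifnot(nrow(positions) == nrow(data))
    rownames(positions) <- channel_names
  }
  structure(
    list(data = data, fs = fs, channel_names = channel_names,
         positions = positions, bad_channels = bad_channels,
         reference = reference, segments = segments),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz, ref=%s, %d bad\n",
    nrow(x$data), ncol(x$data), x$fs, x$reference, length(x$bad_channels)
  ))
  invisible(x)
}

#' Zero-phase bandpass filter and resample a recording
#'
#' Order-3 Butterworth bandpass applied forward-backward (zero phase), then
#' anti-aliased resampling to `fs_out`.
#'
#' @param rec an [eeg_recording()].
#' @param low,high band edges in Hz (defaults 1 and 30).
#' @param fs_out output rate (default 100 Hz).
#' @return filtered, resampled [eeg_recording()].
#' @export
bandpass_and_resample <- function(rec, low = 1, high = 30, fs_out = 100) {
  if (fs_out > rec$fs) stop_config("fs_out exceeds the recording rate")
  if (rec$fs < 2 * high) stop_config("sampling rate below twice the upper edge")
  bf <- signal::butter(3, c(low, high) / (rec$fs / 2), type = "pass")
  out <- t(apply(rec$data, 1L, function(x) {
    resample_ts(signal::filtfilt(bf, x), rec$fs, fs_out)
  }))
  seg <- rec$segments
  if (!is.null(seg)) {
    idx <- pmin(floor(seq(0, ncol(rec$data) - 1) * fs_out / rec$fs) + 1L,
                ncol(out))
    seg <- seg[match(seq_len(ncol(out)), idx)]
    seg[is.na(seg)] <- seg[which(!is.na(seg))[1]]
  }
  eeg_recording(out, fs_out, rec$channel_names, rec$positions,
                rec$bad_channels, rec$reference, seg)
}

channel_trial_metrics <- function(rec) {
  seg <- rec$segments %||% rep(1L, ncol(rec$data))
  trials <- unique(seg)
  n_ch <- nrow(rec$data)
  met <- list(mean = NULL, sd = NULL, p2p = NULL)
  mean_m <- sd_m <- p2p_m <- matrix(NA_real_, n_ch, length(trials))
  for (j in seq_along(trials)) {
    x <- rec$data[, seg == trials[j], drop = FALSE]
    mean_m[, j] <- rowMeans(x)
    sd_m[, j] <- apply(x, 1L, stats::sd)
    p2p_m[, j] <- apply(x, 1L, function(v) diff(range(v)))
  }
  list(mean = mean_m, sd = sd_m, p2p = p2p_m)
}

#' Iteratively detect outlier channels
#'
#' For every trial segment and metric (per-trial mean, SD, peak-to-peak), a
#' channel is flagged when its value deviates from the cross-channel mean of
#' that metric by more than `z` cross-channel standard deviations. Flagged
#' channels are removed from the reference distribution and the scan repeats
#' until no new outliers appear.
#'
#' @param rec an [eeg_recording()] with >= 8 channels.
#' @param z deviation threshold in SD units (default 2.75).
#' @return character vector of bad channel names.
#' @export
detect_bad_channels <- function(rec, z = 2.75) {
  if (nrow(rec$data) < 8L) stop_config("need at least 8 channels")
  mets <- channel_trial_metrics(rec)
  bad <- logical(nrow(rec$data))
  repeat {
    new_bad <- bad
    for (met in mets) {
      good <- which(!new_bad)
      if (length(good) < 3L) break
      for (j in seq_len(ncol(met))) {
        v <- met[good, j]
        mu <- mean(v)
        s <- stats::sd(v)
        if (!is.finite(s) || s == 0) next
        new_bad[good[abs(v - mu) > z * s]] <- TRUE
      }
    }
    if (identical(new_bad, bad)) break
    bad <- new_bad
  }
  if (all(bad)) stop_data_quality("all channels flagged as bad")
  rec$channel_names[bad]
}

#' Re-reference to the average of a fixed electrode set
#'
#' Subtracts the sample-wise mean over `ref_labels` from every channel. Bad
#' channels listed in `rec$bad_channels` are excluded from the reference
#' average (but still re-referenced).
#'
#' @param rec an [eeg_recording()].
#' @param ref_labels reference electrode labels
#'   (default `c("F9","F10","P9","P10","Iz")`).
#' @return re-referenced [eeg_recording()].
#' @export
rereference <- function(rec, ref_labels = c("F9", "F10", "P9", "P10", "Iz")) {
  missing <- setdiff(ref_labels, rec$channel_names)
  if (length(missing)) {
    stop_config(paste("reference electrodes absent:",
                      paste(missing, collapse = ", ")))
  }
  use <- setdiff(ref_labels, rec$bad_channels)
  if (!length(use)) stop_config("all reference electrodes are bad")
  ref <- colMeans(rec$data[use, , drop = FALSE])
  rec$data <- sweep(rec$data, 2L, ref)
  rec$reference <- "custom-average"
  rec
}

#' Interpolate bad channels from spatial neighbors
#'
#' Replaces each bad channel with the sample-wise mean of the good channels
#' within `radius_mm` of it. If re-detection still flags channels, the
#' detect-and-interpolate step repeats up to `max_iter` times.
#'
#' @param rec an [eeg_recording()] with `positions`.
#' @param radius_mm neighborhood radius (default 18).
#' @param z re-detection threshold (as [detect_bad_channels()]).
#' @param max_iter maximum repeat count (default 2).
#' @return [eeg_recording()] with bad channels replaced and the bad list
#'   cleared.
#' @export
interpolate_bads <- function(rec, radius_mm = 18, z = 2.75, max_iter = 2L) {
  if (is.null(rec$positions)) stop_config("channel positions required")
  for (iter in seq_len(max_iter)) {
    if (!length(rec$bad_channels)) break
    D <- as.matrix(stats::dist(rec$positions))
    for (ch in rec$bad_channels) {
      nb <- rec$channel_names[
        D[ch, ] <= radius_mm & rec$channel_names != ch &
          !(rec$channel_names %in% rec$bad_channels)
      ]
      if (!length(nb)) {
        stop_interpolation(sprintf(
          "bad channel %s has no good neighbor within %g mm", ch, radius_mm
        ))
      }
      rec$data[ch, ] <- colMeans(rec$data[nb, , drop = FALSE])
    }
    rec$bad_channels <- character(0)
    if (iter < max_iter && nrow(rec$data) >= 8L) {
      rec$bad_channels <- detect_bad_channels(rec, z)
    }
  }
  rec
}

#' Full preprocessing pipeline for one recording
#'
#' Stage order: bandpass + resample, bad-channel detection, re-referencing
#' (bad channels excluded from the reference), optional denoising hook,
#' neighbor interpolation. Deterministic: identical input yields identical
#' output.
#'
#' @param rec raw [eeg_recording()].
#' @param low,high,fs_out filter/resample settings.
#' @param z bad-channel threshold.
#' @param ref_labels reference electrode set.
#' @param radius_mm interpolation radius.
#' @param denoise_hook optional `function(rec) rec` slot where external
#'   artifact-removal algorithms would run; default identity.
#' @return preprocessed [eeg_recording()].
#' @export
preprocess_eeg <- function(rec, low = 1, high = 30, fs_out = 100, z = 2.75,
                           ref_labels = c("F9", "F10", "P9", "P10", "Iz"),
                           radius_mm = 18, denoise_hook = identity) {
  rec <- bandpass_and_resample(rec, low, high, fs_out)
  rec$bad_channels <- detect_bad_channels(rec, z)
  rec <- rereference(rec, ref_labels)
  rec <- denoise_hook(rec)
  rec <- interpolate_bads(rec, radius_mm, z)
  if (any(!is.finite(rec$data))) stop_data("non-finite samples after preprocessing")
  rec
}
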