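# Stimulus regressor bank sampled at the EEG rate. Event-based columns are
# impulse trains at note onsets (amplitude = the feature value); acoustic
# columns are computed from synthesized audio through a gammatone filterbank.

#' Feature matrix container
#'
#' @param values numeric matrix, samples x features, with named columns.
#' @param fs sampling rate in Hz.
#' @param melody_id label.
#' @param normalized logical; TRUE after [normalize_features()].
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, fs, melody_id = "melody",
                           normalized = FALSE) {
  structure(
    list(values = values, fs = fs, melody_id = melody_id,
         normalized = normalized),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix '%s'> %d samples @ %g Hz, features: %s\n",
    x$melody_id, nrow(x$values), x$fs,
    paste(colnames(x$values), collapse = ", ")
  ))
  invisible(x)
}

onset_samples <- function(m, fs, n_samples) {
  idx <- round(m$notes$onset * fs) + 1L
  idx[idx >= 1L & idx <= n_samples]
}

#' Event-based regressors for a melody
#'
#' One impulse per note at the sample nearest its onset. Amplitudes: `onset`
#' = 1, `ioi` = preceding IOI in ms, `ipi` = absolute pitch interval in
#' semitones, `Sp`/`St`/`Ep`/`Et` = surprise/entropy estimates; undefined
#' values (first notes, undefined timing viewpoint) contribute amplitude 0.
#' With `include_ioi_next = TRUE` a subsequent-IOI column is added.
#'
#' @param m a [melody()].
#' @param info rows of an `info_estimates` table aligned to the melody's
#'   notes (same length and order), or `NULL` to skip the information columns.
#' @param fs output sampling rate (default 100 Hz).
#' @param include_ioi_next add the subsequent-IOI control column.
#' @param pad_s trailing silence appended after the last note, so lagged
#'   responses fit inside the matrix.
#' @return a [feature_matrix()].
#' @export
event_regressors <- function(m, info = NULL, fs = 100,
                             include_ioi_next = FALSE, pad_s = 0.5) {
  n <- n_notes(m)
  if (!is.null(info) && nrow(info) != n) {
    stop_alignment("info table not aligned with melody notes")
  }
  iv <- local_intervals(m)
  dur_total <- max(m$notes$onset + m$notes$duration) + pad_s
  n_samp <- as.integer(round(dur_total * fs)) + 1L
  idx <- round(m$notes$onset * fs) + 1L
  keep <- idx >= 1L & idx <= n_samp
  cols <- c("onset", "ioi", "ipi",
            if (include_ioi_next) "ioi_next",
            if (!is.null(info)) c("Sp", "St", "Ep", "Et"))
  vals <- matrix(0, n_samp, length(cols), dimnames = list(NULL, cols))
  z <- function(x) ifelse(is.na(x), 0, x)
  put <- function(col, amp) {
    vals[cbind(idx[keep], match(col, cols))] <<- z(amp)[keep]
  }
  put("onset", rep(1, n))
  put("ioi", iv$ioi * 1000)
  put("ipi", iv$ipi)
  if (include_ioi_next) put("ioi_next", iv$ioi_next * 1000)
  if (!is.null(info)) {
    put("Sp", info$Sp); put("St", info$St)
    put("Ep", info$Ep); put("Et", info$Et)
  }
  feature_matrix(vals, fs, melody_id = m$id)
}

#' Synthesize a simple harmonic rendering of a melody
#'
#' Each note becomes an exponentially decaying 6-harmonic tone at its
#' fundamental (equal-tempered, A4 = 440 Hz), with a 5 ms linear onset ramp
#' and constant amplitude across notes. A parametric stand-in for a piano
#' timbre: what matters downstream is that onsets produce realistic
#' broadband flux, which tests assert by alignment.
#'
#' @param m a [melody()].
#' @param sr audio sampling rate (default 44100 Hz).
#' @param n_harmonics number of harmonics (default 6).
#' @param decay_tau exponential amplitude decay constant in seconds.
#' @return list with `wave` (numeric vector) and `sr`.
#' @export
synthesize_audio <- function(m, sr = 44100, n_harmonics = 6L,
                             decay_tau = 0.25) {
  total <- max(m$notes$onset + m$notes$duration) + 0.5
  wave <- numeric(as.integer(ceiling(total * sr)))
  for (i in seq_len(n_notes(m))) {
    f0 <- 440 * 2^((m$notes$pitch[i] - 69) / 12)
    dur <- m$notes$duration[i] + 3 * decay_tau
    t <- seq(0, dur, by = 1 / sr)
    env <- exp(-t / decay_tau)
    ramp_n <- max(round(0.005 * sr), 1L)
    env[seq_len(min(ramp_n, length(env)))] <-
      env[seq_len(min(ramp_n, length(env)))] *
      seq(0, 1, length.out = min(ramp_n, length(env)))
    tone <- numeric(length(t))
    for (h in seq_len(n_harmonics)) {
      hf <- h * f0
      if (hf < sr / 2) tone <- tone + sin(2 * pi * hf * t) / h
    }
    tone <- tone * env
    i0 <- as.integer(round(m$notes$onset[i] * sr)) + 1L
    i1 <- min(i0 + length(tone) - 1L, length(wave))
    wave[i0:i1] <- wave[i0:i1] + tone[seq_len(i1 - i0 + 1L)]
  }
  if (max(abs(wave)) > 0) wave <- wave / max(abs(wave)) * 0.9
  list(wave = wave, sr = sr)
}

# Analytic-signal magnitude via FFT (Hilbert envelope). Zero-pads to a
# highly composite length so the FFT stays O(n log n) for awkward lengths.
hilbert_envelope <- function(x) {
  n0 <- length(x)
  n <- stats::nextn(n0, c(2, 3, 5))
  if (n > n0) x <- c(x, numeric(n - n0))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)[seq_len(n0)]
}

# Slaney 4th-order gammatone filter (cascade of four second-order sections),
# with coefficients returned so the cascade can be applied either in the
# time domain or (much faster for long signals) in the frequency domain.
gammatone_coefs <- function(cf, fs) {
  T <- 1 / fs
  erb <- 24.7 + cf / 9.26449
  B <- 1.019 * 2 * pi * erb
  arg <- 2 * cf * pi * T
  e1 <- exp(B * T)
  s1 <- sqrt(3 + 2^1.5)
  s2 <- sqrt(3 - 2^1.5)
  a1 <- -(2 * T * cos(arg) / e1 + 2 * s1 * T * sin(arg) / e1) / 2
  a2 <- -(2 * T * cos(arg) / e1 - 2 * s1 * T * sin(arg) / e1) / 2
  a3 <- -(2 * T * cos(arg) / e1 + 2 * s2 * T * sin(arg) / e1) / 2
  a4 <- -(2 * T * cos(arg) / e1 - 2 * s2 * T * sin(arg) / e1) / 2
  zi <- exp(2i * arg)
  zb <- exp(-(B * T) + 1i * arg)
  gain <- abs(
    (-2 * zi * T + 2 * zb * T * (cos(arg) - s2 * sin(arg))) *
      (-2 * zi * T + 2 * zb * T * (cos(arg) + s2 * sin(arg))) *
      (-2 * zi * T + 2 * zb * T * (cos(arg) - s1 * sin(arg))) *
      (-2 * zi * T + 2 * zb * T * (cos(arg) + s1 * sin(arg))) /
      (-2 / exp(2 * B * T) - 2 * zi + 2 * (1 + zi) / e1)^4
  )
  list(T = T, a = c(a1, a2, a3, a4),
       b = c(1, -2 * cos(arg) / e1, exp(-2 * B * T)), gain = gain)
}

gammatone_filter <- function(x, cf, fs) {
  co <- gammatone_coefs(cf, fs)
  y <- signal::filter(c(co$T, co$a[1], 0) / co$gain, co$b, x)
  for (k in 2:4) y <- signal::filter(c(co$T, co$a[k], 0), co$b, as.numeric(y))
  as.numeric(y)
}

# Frequency response of the cascade on (a subset of) an FFT bin grid of
# length n. `bins` are 0-based bin indices.
gammatone_response <- function(cf, fs, n, bins = seq_len(n) - 1) {
  co <- gammatone_coefs(cf, fs)
  z1 <- exp(-2i * pi * bins / n) # z^-1 on the unit circle
  den <- co$b[1] + co$b[2] * z1 + co$b[3] * z1^2
  H <- (co$T + co$a[1] * z1) / co$gain / den
  for (k in 2:4) H <- H * (co$T + co$a[k] * z1) / den
  H
}

# Mean over non-overlapping blocks (cheap anti-alias for smooth envelopes).
block_mean <- function(x, k) {
  n <- (length(x) %/% k) * k
  colMeans(matrix(x[seq_len(n)], k))
}

# Zero-phase anti-aliased resampling to an arbitrary (lower or equal) rate:
# 8th-order Butterworth lowpass at 0.4 * fs_out applied forward-backward,
# then linear interpolation onto the new sample grid.
resample_ts <- function(x, fs_in, fs_out) {
  if (fs_out > fs_in) stop_config("upsampling not supported")
  if (fs_out == fs_in) return(x)
  bf <- signal::butter(4, 0.8 * fs_out / fs_in, type = "low")
  y <- signal::filtfilt(bf, x)
  t_new <- seq(0, (length(x) - 1) / fs_in, by = 1 / fs_out)
  stats::approx(seq_along(x) / fs_in - 1 / fs_in, y, xout = t_new,
                rule = 2)$y
}

#' Acoustic regressors from an audio waveform
#'
#' Decomposes the (mono) waveform into logarithmically spaced gammatone
#' bands, takes each band's Hilbert envelope, and derives: `envelope` (band
#' sum), `env_derivative` (half-wave-rectified first difference of the
#' envelope), and `spectral_flux` (sum over bands of half-wave-rectified
#' sample-to-sample envelope increases), all resampled to `fs_out`.
#'
#' @param audio list with `wave` and `sr` (as from [synthesize_audio()]);
#'   `wave` must be a plain numeric vector (mono).
#' @param fs_out output rate (default 100 Hz).
#' @param n_bands number of gammatone bands (default 128, 100-8000 Hz).
#' @param f_range frequency range in Hz.
#' @return a [feature_matrix()] with columns
#'   `spectral_flux`, `envelope`, `env_derivative`.
#' @export
acoustic_regressors <- function(audio, fs_out = 100, n_bands = 128L,
                                f_range = c(100, 8000)) {
  if (is.matrix(audio$wave) && ncol(audio$wave) > 1L) {
    stop_format("stereo audio not supported; supply a mono waveform")
  }
  x <- as.numeric(audio$wave)
  sr <- audio$sr
  if (sr < 16000) stop_config("audio sample rate must be >= 16 kHz")
  cfs <- exp(seq(log(f_range[1]), log(min(f_range[2], sr / 2 * 0.9)),
                 length.out = n_bands))
  # One forward FFT of the (padded) signal; per band: multiply by the
  # gammatone response and the analytic-signal mask, then recover the band
  # envelope directly at a decimated rate by inverse-transforming only the
  # spectral chunk around the band center (frequency-domain demodulation --
  # the demodulating phase factor drops out of the modulus).
  n0 <- length(x)
  pad <- max(4096L, round(0.2 * sr)) # absorb the filter tail (circular FFT)
  k <- 8L                            # decimation factor; fs/k stays >> fs_out
  n <- stats::nextn(n0 + pad, c(2, 3, 5))
  while (n %% k != 0L) n <- stats::nextn(n + 1L, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(n - n0)))
  amask <- numeric(n)
  amask[1] <- 1
  amask[2:floor(n / 2)] <- 2
  if (n %% 2 == 0) amask[n / 2 + 1] <- 1
  n_s <- n %/% k
  fs_mid <- sr / k
  n0_mid <- floor(n0 / k)
  n_out <- length(resample_ts(numeric(n0_mid), fs_mid, fs_out))
  env_sum <- numeric(n_out)
  flux <- numeric(n_out)
  for (cf in cfs) {
    s <- round(cf / sr * n) - n_s %/% 2L
    s <- max(0L, min(s, n %/% 2L - n_s))
    bins <- s:(s + n_s - 1L)
    chunk <- X[bins + 1L] * gammatone_response(cf, sr, n, bins) * amask[bins + 1L]
    env <- Mod(stats::fft(chunk, inverse = TRUE))[seq_len(n0_mid)] / n
    e <- resample_ts(env, fs_mid, fs_out)
    env_sum <- env_sum + e
    flux <- flux + pmax(c(0, diff(e)), 0)
  }
  env_deriv <- pmax(c(0, diff(env_sum)), 0)
  vals <- cbind(spectral_flux = flux, envelope = env_sum,
                env_derivative = env_deriv)
  feature_matrix(vals, fs_out)
}

#' Assemble and normalize the full regressor bank for one melody
#'
#' Combines event and (optionally) acoustic columns into one matrix and
#' normalizes each column to unit root-mean-square over the melody
#' (all-zero columns are left untouched). Normalization is per melody.
#'
#' @param event a [feature_matrix()] from [event_regressors()].
#' @param acoustic optional [feature_matrix()] from [acoustic_regressors()];
#'   truncated/padded to the event matrix length.
#' @param columns optional character vector selecting/ordering columns.
#' @return a normalized [feature_matrix()].
#' @export
combine_features <- function(event, acoustic = NULL, columns = NULL) {
  vals <- event$values
  if (!is.null(acoustic)) {
    if (acoustic$fs != event$fs) stop_config("sampling rates differ")
    a <- acoustic$values
    n <- nrow(vals)
    if (nrow(a) >= n) {
      a <- a[seq_len(n), , drop = FALSE]
    } else {
      a <- rbind(a, matrix(0, n - nrow(a), ncol(a),
                           dimnames = list(NULL, colnames(a))))
    }
    vals <- cbind(vals, a)
  }
  if (!is.null(columns)) vals <- vals[, columns, drop = FALSE]
  normalize_features(feature_matrix(vals, event$fs, event$melody_id))
}

#' Read or write a feature matrix as a table with a JSON sidecar
#'
#' The values go to a tab-separated table (one column per regressor) and the
#' metadata (sampling rate, melody id, normalization flag, column order) to
#' `<path>.json`.
#'
#' @param fm a [feature_matrix()].
#' @param path table path (the sidecar gets `.json` appended).
#' @return `write_feature_matrix` returns `path` invisibly;
#'   `read_feature_matrix` returns the [feature_matrix()].
#' @export
write_feature_matrix <- function(fm, path) {
  utils::write.table(fm$values, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(
    list(fs = fm$fs, melody_id = fm$melody_id, normalized = fm$normalized,
         columns = colnames(fm$values)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t"))
  colnames(v) <- meta$columns
  feature_matrix(v, meta$fs, meta$melody_id, isTRUE(meta$normalized))
}

#' @rdname combine_features
#' @param fm a [feature_matrix()].
#' @export
normalize_features <- function(fm) {
  v <- fm$values
  for (j in seq_len(ncol(v))) {
    r <- rms(v[, j])
    if (r > 0) v[, j] <- v[, j] / r
  }
  feature_matrix(v, fm$fs, fm$melody_id, normalized = TRUE)
}
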