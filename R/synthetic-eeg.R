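# Ground-truth EEG simulator: planted per-feature response kernels convolved
# with the stimulus regressors, plus spatially correlated 1/f noise, per
# subject with latency/gain jitter. Every downstream stage is tested against
# the kernels this module returns.

#' Deterministic quasi-uniform scalp layout
#'
#' Places `n_channels` electrodes on an upper hemisphere via a Fibonacci
#' spiral, scaled so that an 18 mm radius captures about 8 neighbors on
#' average. Five peripheral electrodes are labelled `F9`, `F10`, `P9`,
#' `P10`, `Iz` (the default reference set); the rest are `E##`.
#'
#' @param n_channels number of electrodes (default 64).
#' @param scale_mm hemisphere radius in mm (default 34, calibrated for the
#'   neighborhood property at the default channel count).
#' @return numeric matrix n x 3 (mm) with electrode rownames.
#' @export
make_layout <- function(n_channels = 64L, scale_mm = 34) {
  i <- seq_len(n_channels)
  z <- (i - 0.5) / n_channels          # 0 (rim) .. 1 (vertex)
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden
  r_xy <- sqrt(1 - z^2)
  pos <- scale_mm * cbind(x = r_xy * cos(phi), y = r_xy * sin(phi), z = z)
  labels <- sprintf("E%02d", i)
  # five peripheral electrodes (lowest on the head) at spread azimuths take
  # the reference-ring names
  rim <- order(pos[, "z"])[seq_len(min(12L, n_channels))]
  az <- atan2(pos[rim, "y"], pos[rim, "x"])
  want <- c(F9 = 3 * pi / 4, F10 = pi / 4, P9 = -3 * pi / 4, P10 = -pi / 4,
            Iz = pi)
  taken <- integer(0)
  for (nm in names(want)) {
    d <- abs(atan2(sin(az - want[[nm]]), cos(az - want[[nm]])))
    d[taken] <- Inf
    j <- which.min(d)
    labels[rim[j]] <- nm
    taken <- c(taken, j)
  }
  rownames(pos) <- labels
  pos
}

# Gamma-shaped component on a lag grid (seconds), peak at `latency`.
gamma_bump <- function(lags_s, latency, width) {
  t <- pmax(lags_s, 0)
  k <- (latency / width)^2
  th <- width^2 / latency
  y <- stats::dgamma(t, shape = k, scale = th)
  if (max(y) > 0) y / max(y) else y
}

# Canonical N1-P1-N2-P2 kernel morphology on the TRF lag grid; feature index
# perturbs latencies/amplitudes so different features have distinct kernels.
make_kernel <- function(lags_s, feature_index = 1L, amplitude = 1) {
  lat <- c(0.08, 0.16, 0.25, 0.32) * (1 + 0.06 * ((feature_index %% 3) - 1))
  amp <- c(-0.6, 1.0, -0.4, 0.8) * (1 + 0.1 * ((feature_index %% 4) - 1.5))
  w <- c(0.03, 0.045, 0.05, 0.06)
  k <- numeric(length(lags_s))
  for (j in seq_along(lat)) k <- k + amp[j] * gamma_bump(lags_s, lat[j], w[j])
  amplitude * k
}

# Smooth scalp topography: Gaussian falloff from a feature-specific center.
make_topography <- function(positions, feature_index = 1L) {
  centers <- rbind(
    c(0, 20, 25), c(0, -15, 28), c(18, 5, 24), c(-18, 5, 24),
    c(10, 18, 22), c(-10, 18, 22), c(0, 0, 34), c(14, -12, 22)
  )
  ctr <- centers[(feature_index - 1L) %% nrow(centers) + 1L, ]
  d2 <- rowSums(sweep(positions, 2L, ctr)^2)
  w <- exp(-d2 / (2 * 20^2))
  w / max(w)
}

#' Specification for the generative EEG model
#'
#' @param active_features character vector of regressor names that drive the
#'   EEG (e.g. `c("onset","ioi","St","Et")` to mimic timing-only encoding).
#'   May also be a named list mapping condition (`real`, `shuffled`,
#'   `synthetic`) to a feature set, so e.g. surprise features can drive
#'   responses to real but not shuffled melodies.
#' @param snr signal-to-noise power ratio in the 1-30 Hz band.
#' @param n_subjects number of simulated subjects.
#' @param latency_jitter_ms SD of the per-subject kernel latency shift.
#' @param gain_sd SD of the per-subject log-normal gain.
#' @param noise_exponent 1/f^a exponent of the background noise.
#' @param layout electrode positions from [make_layout()].
#' @param t_min_ms,t_max_ms kernel lag span (default -50..400 ms).
#' @param amplitudes optional named numeric vector of kernel amplitudes per
#'   feature (default 1 for every active feature).
#' @param seed integer.
#' @return object of class `generative_spec`.
#' @export
generative_spec <- function(active_features = c("onset", "ioi", "St", "Et"),
                            snr = 1, n_subjects = 20L,
                            latency_jitter_ms = 10, gain_sd = 0.2,
                            noise_exponent = 1, layout = make_layout(),
                            t_min_ms = -50, t_max_ms = 400,
                            amplitudes = NULL, seed = 1L) {
  if (snr <= 0) stop_config("snr must be positive")
  structure(
    list(active_features = active_features, snr = snr,
         n_subjects = as.integer(n_subjects),
         latency_jitter_ms = latency_jitter_ms, gain_sd = gain_sd,
         noise_exponent = noise_exponent, layout = layout,
         t_min_ms = t_min_ms, t_max_ms = t_max_ms,
         amplitudes = amplitudes, seed = as.integer(seed)),
    class = "generative_spec"
  )
}

# colored (1/f^a) noise via spectral shaping, channels x samples;
# all channels shaped through one multi-column FFT
one_over_f_noise <- function(n_ch, n_samp, exponent, fs) {
  n <- stats::nextn(n_samp, c(2, 3, 5))
  f <- c(1, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f + fs / n)
  shape <- f^(-exponent / 2)
  shape[1] <- 0
  W <- matrix(stats::rnorm(n * n_ch), n, n_ch)
  out <- Re(stats::mvfft(stats::mvfft(W) * shape, inverse = TRUE) / n)
  t(out[seq_len(n_samp), , drop = FALSE])
}

# mean 1-30 Hz band power over the rows of a channels x samples matrix;
# zero-padded to a composite FFT length (power normalized to the true n)
band_power_rows <- function(x, fs, low = 1, high = 30) {
  n0 <- ncol(x)
  n <- stats::nextn(n0, c(2, 3, 5))
  X <- t(x)
  if (n > n0) X <- rbind(X, matrix(0, n - n0, nrow(x)))
  P <- Mod(stats::mvfft(X))^2 / n0
  f <- (seq_len(n) - 1) * fs / n
  sel <- (f >= low & f <= high) | (f >= fs - high & f <= fs - low)
  colSums(P[sel, , drop = FALSE]) / n0
}

band_power <- function(x, fs, low = 1, high = 30) {
  band_power_rows(matrix(x, 1L), fs, low, high)[[1L]]
}

# convolve one regressor column with a lag kernel (lag grid in samples),
# via a padded FFT: y[t] = sum_j kernel[j] * x[t - lag_samples[j]]
lagged_conv <- function(x, kernel, lag_samples) {
  n <- length(x)
  L <- length(kernel)
  m <- stats::nextn(n + L, c(2, 3, 5))
  s <- Re(stats::fft(stats::fft(c(x, numeric(m - n))) *
                       stats::fft(c(kernel, numeric(m - L))),
                     inverse = TRUE)) / m
  # s[t] = sum_j kernel[j] x[t - j + 1]; shift so index j maps to lag_samples[j]
  lag0 <- lag_samples[1L]
  y <- numeric(n)
  t_idx <- seq_len(n)
  src <- t_idx - lag0
  ok <- src >= 1 & src <= m
  y[t_idx[ok]] <- s[src[ok]]
  y
}

active_for_condition <- function(spec, condition) {
  af <- spec$active_features
  if (is.list(af)) af[[condition]] %||% character(0) else af
}

#' Generate multi-subject stimulus-locked EEG with known ground truth
#'
#' For subject `s` and melody `m`:
#' `EEG = sum_f topo_f x (kernel_f jittered for s) * feature_f + 1/f noise`,
#' with the noise scaled per recording so that the realized 1-30 Hz
#' signal-to-noise power ratio equals `spec$snr`. Returns the exact
#' per-subject kernels used.
#'
#' @param features named list of normalized [feature_matrix()] objects, one
#'   per melody.
#' @param spec a [generative_spec()].
#' @param conditions optional named character vector giving each melody's
#'   condition (for per-condition active feature sets); defaults to
#'   `"synthetic"`.
#' @return list with `eeg` (per-subject named lists of [eeg_recording()]),
#'   `kernels` (per subject: named list of channels x lags matrices),
#'   `lags_ms`, and `spec`.
#' @export
generate_eeg <- function(features, spec, conditions = NULL) {
  fs <- features[[1L]]$fs
  lag_samp <- seq(round(spec$t_min_ms / 1000 * fs),
                  round(spec$t_max_ms / 1000 * fs))
  lags_s <- lag_samp / fs
  all_feats <- unique(unlist(
    if (is.list(spec$active_features)) spec$active_features
    else list(spec$active_features)
  ))
  for (f in all_feats) {
    if (!f %in% colnames(features[[1L]]$values)) {
      stop_config(paste("active feature absent from features:", f))
    }
  }
  n_ch <- nrow(spec$layout)
  base_kernels <- lapply(seq_along(all_feats), function(i) {
    f <- all_feats[i]
    amp <- 1
    if (!is.null(spec$amplitudes) && f %in% names(spec$amplitudes)) {
      amp <- spec$amplitudes[[f]]
    }
    list(k = make_kernel(lags_s, i, amp), topo = make_topography(spec$layout, i))
  })
  names(base_kernels) <- all_feats
  if (is.null(conditions)) {
    conditions <- stats::setNames(rep("synthetic", length(features)),
                                  names(features))
  }
  with_seed(spec$seed, {
    subjects <- vector("list", spec$n_subjects)
    kernels <- vector("list", spec$n_subjects)
    for (s in seq_len(spec$n_subjects)) {
      shift <- round(stats::rnorm(1, 0, spec$latency_jitter_ms) / 1000 * fs)
      gain <- stats::rlnorm(1, 0, spec$gain_sd)
      subj_k <- lapply(base_kernels, function(bk) {
        k <- bk$k
        if (shift > 0) k <- c(numeric(shift), k)[seq_along(k)]
        if (shift < 0) k <- c(k[(-shift + 1):length(k)], numeric(-shift))
        outer(bk$topo, gain * k)
      })
      kernels[[s]] <- subj_k
      recs <- vector("list", length(features))
      names(recs) <- names(features)
      for (mi in seq_along(features)) {
        fm <- features[[mi]]
        n_samp <- nrow(fm$values)
        act <- intersect(active_for_condition(spec, conditions[[mi]]),
                         colnames(fm$values))
        sig <- matrix(0, n_ch, n_samp)
        for (f in act) {
          drive <- lagged_conv(fm$values[, f], base_kernels[[f]]$k *
                                 gain, lag_samp + shift)
          sig <- sig + outer(base_kernels[[f]]$topo, drive)
        }
        # shared low-rank background + independent per-channel noise
        shared <- matrix(stats::rnorm(n_ch * 3), n_ch, 3) %*%
          one_over_f_noise(3L, n_samp, spec$noise_exponent, fs)
        indep <- one_over_f_noise(n_ch, n_samp, spec$noise_exponent, fs)
        noise <- shared / sqrt(3) + indep
        sp <- mean(band_power_rows(sig, fs))
        np <- mean(band_power_rows(noise, fs))
        scale <- if (sp > 0 && np > 0) sqrt(sp / (spec$snr * np)) else 1
        recs[[mi]] <- eeg_recording(sig + scale * noise, fs,
                                    rownames(spec$layout), spec$layout)
      }
      subjects[[s]] <- recs
    }
    list(eeg = subjects, kernels = kernels, lags_ms = lag_samp / fs * 1000,
         spec = spec)
  })
}
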