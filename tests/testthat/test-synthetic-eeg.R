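test_that("the layout is deterministic, spread out, and neighbor-calibrated", {
  a <- make_layout()
  b <- make_layout()
  expect_identical(a, b)
  expect_equal(nrow(a), 64)
  D <- as.matrix(stats::dist(a))
  expect_gt(min(D[upper.tri(D)]), 5)
  nn <- vapply(seq_len(64), function(i) sum(D[i, ] <= 18) - 1L, 0L)
  expect_gte(mean(nn), 6)
  expect_lte(mean(nn), 10)
  expect_true(all(c("F9", "F10", "P9", "P10", "Iz") %in% rownames(a)))
})

syn_features <- function(n_mel = 2, seed = 51, n_notes = 25) {
  corpus <- generate_corpus(n_mel, n_notes = n_notes, temperature = 1,
                            seed = seed)
  names(corpus) <- vapply(corpus, `[[`, "", "id")
  lapply(corpus, function(m) normalize_features(event_regressors(m, fs = 100)))
}

test_that("the noiseless limit reduces to an exact lagged convolution", {
  fms <- syn_features()
  layout <- make_layout(8)
  spec <- generative_spec(active_features = "onset", snr = 1e9,
                          n_subjects = 1, latency_jitter_ms = 0, gain_sd = 0,
                          layout = layout, seed = 2)
  sim <- generate_eeg(fms, spec)
  rec <- sim$eeg[[1]][[1]]
  k <- sim$kernels[[1]][["onset"]] # channels x lags
  x <- fms[[1]]$values[, "onset"]
  lags <- round(sim$lags_ms / 1000 * 100)
  manual <- numeric(length(x))
  for (j in seq_along(lags)) {
    l <- lags[j]
    idx <- seq_len(length(x) - abs(l))
    if (l >= 0) manual[idx + l] <- manual[idx + l] + k[1, j] * x[idx]
    else manual[idx] <- manual[idx] + k[1, j] * x[idx + abs(l)]
  }
  expect_gt(cor(rec$data[1, ], manual), 0.999999)
  expect_error(
    generate_eeg(fms, generative_spec(active_features = "nope", seed = 1)),
    class = "config_error"
  )
})

test_that("realized SNR tracks the requested level", {
  fms <- syn_features(seed = 53)
  layout <- make_layout(16)
  for (snr in c(0.5, 1, 4)) {
    spec <- generative_spec(active_features = c("onset", "ioi"), snr = snr,
                            n_subjects = 2, layout = layout, seed = 3)
    sim <- generate_eeg(fms, spec)
    for (s in 1:2) {
      rec <- sim$eeg[[s]][[1]]
      # reconstruct the signal part from the returned kernels
      k <- sim$kernels[[s]]
      lags <- round(sim$lags_ms / 1000 * 100)
      sig <- matrix(0, nrow(rec$data), ncol(rec$data))
      for (f in names(k)) {
        x <- fms[[1]]$values[, f]
        for (j in seq_along(lags)) {
          l <- lags[j]
          idx <- seq_len(length(x) - abs(l))
          if (l >= 0) {
            sig[, idx + l] <- sig[, idx + l] + k[[f]][, j] %o% x[idx]
          } else {
            sig[, idx] <- sig[, idx] + k[[f]][, j] %o% x[idx + abs(l)]
          }
        }
      }
      bp <- function(v) musictrf:::band_power(v, 100)
      sp <- mean(apply(sig, 1, bp))
      np <- mean(apply(rec$data - sig, 1, bp))
      expect_lt(abs(sp / np - snr) / snr, 0.2)
    }
  }
})

test_that("per-condition feature sets gate which kernels drive the EEG", {
  corpus <- generate_corpus(2, n_notes = 25, temperature = 1, seed = 55)
  names(corpus) <- vapply(corpus, `[[`, "", "id")
  info <- estimate_information(corpus, folds = 2, seed = 1)
  fms <- lapply(corpus, function(m) {
    normalize_features(event_regressors(m, info[info$melody_id == m$id, ],
                                        fs = 100))
  })
  layout <- make_layout(8)
  spec <- generative_spec(
    active_features = list(real = c("onset", "St"), shuffled = "onset"),
    snr = 1e6, n_subjects = 1, latency_jitter_ms = 0, gain_sd = 0,
    layout = layout, seed = 7
  )
  conds <- c(real = "real", shuf = "shuffled")
  names(fms) <- names(conds)
  sim <- generate_eeg(fms, spec, conditions = conds)
  # same onset train in both -> the difference must be the St contribution
  expect_false(isTRUE(all.equal(sim$eeg[[1]][["real"]]$data[1, 1:100],
                                sim$eeg[[1]][["shuf"]]$data[1, 1:100])))
})

test_that("homogeneous synthetic EEG passes preprocessing with no bad channels", {
  fms <- syn_features(seed = 57, n_notes = 30)
  layout <- make_layout(16)
  spec <- generative_spec(active_features = c("onset", "ioi"), snr = 1,
                          n_subjects = 1, layout = layout, seed = 11)
  sim <- generate_eeg(fms, spec)
  rec <- sim$eeg[[1]][[1]]
  expect_length(detect_bad_channels(rec), 0)
  out <- preprocess_eeg(rec)
  expect_true(all(is.finite(out$data)))
  expect_equal(out$fs, 100)
})

test_that("generation is seed-deterministic with per-subject jitter", {
  fms <- syn_features(seed = 59)
  layout <- make_layout(8)
  spec <- generative_spec(active_features = "onset", snr = 2, n_subjects = 3,
                          layout = layout, seed = 13)
  a <- generate_eeg(fms, spec)
  b <- generate_eeg(fms, spec)
  expect_identical(a$eeg[[2]][[1]]$data, b$eeg[[2]][[1]]$data)
  # jitter makes subjects' kernels differ
  expect_false(identical(a$kernels[[1]][["onset"]], a$kernels[[2]][["onset"]]))
})
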