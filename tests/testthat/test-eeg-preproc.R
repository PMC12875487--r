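make_rec <- function(data, fs = 500, layout = NULL) {
  layout <- layout %||% musictrf::make_layout(nrow(data))
  eeg_recording(data, fs, rownames(layout), layout)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the bandpass removes DC, keeps 15 Hz, and crushes 45 Hz", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)
  mk <- function(x) make_rec(rbind(x, x, x, x, x, x, x, x), fs)
  dc <- bandpass_and_resample(mk(rep(5, length(t))))
  expect_lt(mean(abs(dc$data[1, 100:900])), 0.05) # < 1% of the 5 uV offset
  s15 <- bandpass_and_resample(mk(sin(2 * pi * 15 * t)))
  mid <- 200:800
  amp15 <- sqrt(2) * sqrt(mean(s15$data[1, mid]^2))
  expect_lt(abs(amp15 - 1), 0.05)
  s45 <- bandpass_and_resample(mk(sin(2 * pi * 45 * t)))
  amp45 <- sqrt(2) * sqrt(mean(s45$data[1, mid]^2))
  expect_lt(amp45, 0.2) # > 80% attenuation from the twice-applied order-3 filter
  expect_equal(s15$fs, 100)
  expect_error(bandpass_and_resample(mk(t), fs_out = 1000),
               class = "config_error")
})

test_that("a planted high-variance channel is flagged, identical channels are not", {
  withr::with_seed(15, {
    n_ok <- 0
    for (rep in 1:20) {
      x <- matrix(rnorm(16 * 800), 16)
      bad_i <- sample(16, 1)
      x[bad_i, ] <- x[bad_i, ] * 20
      rec <- make_rec(x, 100)
      bads <- detect_bad_channels(rec)
      if (rec$channel_names[bad_i] %in% bads) n_ok <- n_ok + 1
      expect_lte(length(bads), 4) # a few chance flags at most
    }
    expect_gte(n_ok, 20)
    same <- make_rec(matrix(rep(rnorm(500), each = 16), 16), 100)
    expect_length(detect_bad_channels(same), 0)
  })
})

test_that("raising the threshold never flags additional channels", {
  withr::with_seed(16, {
    x <- matrix(rnorm(16 * 600), 16)
    x[3, ] <- x[3, ] * 8
    x[9, ] <- x[9, ] + 10
    rec <- make_rec(x, 100)
    prev <- detect_bad_channels(rec, z = 2)
    for (z in c(2.75, 4, 8)) {
      cur <- detect_bad_channels(rec, z = z)
      expect_true(all(cur %in% prev))
      prev <- cur
    }
  })
})

test_that("re-referencing subtracts the reference-ring mean exactly", {
  layout <- make_layout(16)
  withr::with_seed(17, {
    x <- matrix(rnorm(16 * 300), 16)
    rec <- eeg_recording(x, 100, rownames(layout), layout)
    refd <- rereference(rec)
    ref_set <- c("F9", "F10", "P9", "P10", "Iz")
    expect_equal(max(abs(colMeans(refd$data[ref_set, ]))), 0,
                 tolerance = 1e-12)
    # zero reference channels: identity
    x0 <- x
    x0[match(ref_set, rownames(layout)), ] <- 0
    r0 <- rereference(eeg_recording(x0, 100, rownames(layout), layout))
    expect_equal(unname(r0$data), x0)
    # common-mode constant: all-zero output
    rc <- rereference(eeg_recording(matrix(3, 16, 50), 100,
                                    rownames(layout), layout))
    expect_equal(max(abs(rc$data)), 0)
    expect_error(rereference(eeg_recording(x, 100,
                                           sprintf("C%02d", 1:16), layout)),
                 class = "config_error")
  })
})

test_that("interpolation recovers a smooth spatial field from neighbors", {
  layout <- make_layout(64)
  grad <- layout[, "x"] * 0.1 # linear gradient across the scalp, per mm
  x <- matrix(rep(grad, 100), 64)
  # an interior electrode whose neighborhood is most symmetric (smallest
  # neighbor-centroid offset); neighbor-mean interpolation is unbiased on a
  # linear field exactly to that offset
  D <- as.matrix(stats::dist(layout))
  asym <- sapply(seq_len(64), function(i) {
    nb <- which(D[i, ] <= 18 & seq_len(64) != i)
    sqrt(sum((colMeans(layout[nb, , drop = FALSE]) - layout[i, ])^2))
  })
  ch <- which.min(asym)
  rec <- eeg_recording(x, 100, rownames(layout), layout,
                       bad_channels = rownames(layout)[ch])
  out <- interpolate_bads(rec, radius_mm = 18, max_iter = 1)
  step <- 0.1 * 18 # field change across one neighborhood radius
  expect_lt(abs(out$data[ch, 1] - grad[ch]), 0.1 * step)
  expect_length(out$bad_channels, 0)
  # no bad channels: identity
  rec2 <- eeg_recording(x, 100, rownames(layout), layout)
  expect_equal(interpolate_bads(rec2, max_iter = 1)$data, rec2$data)
  # isolated channel: error
  far <- layout
  far[5, ] <- c(500, 500, 500)
  rec3 <- eeg_recording(x, 100, rownames(layout), far,
                        bad_channels = rownames(layout)[5])
  expect_error(interpolate_bads(rec3), class = "interpolation_error")
})

test_that("the full preprocessing chain is deterministic", {
  withr::with_seed(18, {
    layout <- make_layout(16)
    x <- matrix(rnorm(16 * 2000), 16)
    rec <- eeg_recording(x, 500, rownames(layout), layout)
    a <- preprocess_eeg(rec)
    b <- preprocess_eeg(rec)
    expect_identical(a$data, b$data)
    expect_true(all(is.finite(a$data)))
  })
})
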