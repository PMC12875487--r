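toy_eeg_melody <- function(n_notes = 20, ioi = 0.6, n_ch = 8, seed = 1) {
  withr::with_seed(seed, {
    m <- toy_melody(seq(0, by = ioi, length.out = n_notes),
                    rep(60:63, length.out = n_notes))
    n_samp <- round((max(m$notes$onset) + 1) * 100)
    layout <- make_layout(n_ch)
    rec <- eeg_recording(matrix(rnorm(n_ch * n_samp), n_ch), 100,
                         rownames(layout), layout)
    list(m = m, rec = rec, layout = layout)
  })
}

test_that("epoching skips boundary notes and baseline-corrects exactly", {
  te <- toy_eeg_melody()
  es <- epoch_melody(te$rec, te$m)
  # first note (onset 0) under-runs the -100 ms window; last note's +500 ms
  # over-runs the recording tail depending on length
  expect_lte(dim(es$epochs)[1], n_notes(te$m))
  expect_equal(dim(es$epochs)[1] + es$n_skipped, n_notes(te$m))
  expect_false(1 %in% es$info$note_index)
  bsel <- es$times_ms >= -50 & es$times_ms <= 0
  bl <- apply(es$epochs[, , bsel, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(bl)), 1e-9)
  # constant channel: all-zero epochs after baseline correction
  rec2 <- te$rec
  rec2$data[3, ] <- 42
  es2 <- epoch_melody(rec2, te$m)
  expect_equal(max(abs(es2$epochs[, 3, ])), 0)
})

test_that("an extreme-amplitude trial is rejected, identical trials are kept", {
  withr::with_seed(23, {
    n_hit <- 0
    for (rep in 1:20) {
      te <- toy_eeg_melody(seed = 300 + rep)
      es <- epoch_melody(te$rec, te$m)
      k <- sample(dim(es$epochs)[1], 1)
      planted <- es$info$note_index[k]
      es$epochs[k, , ] <- es$epochs[k, , ] * 20
      out <- reject_trials(es)
      if (out$n_rejected >= 1 && !planted %in% out$info$note_index) {
        n_hit <- n_hit + 1
      }
    }
    expect_gte(n_hit, 20) # detection on every seed at this amplitude
    # identical trials: nothing rejected
    te <- toy_eeg_melody(seed = 999)
    es <- epoch_melody(te$rec, te$m)
    for (i in seq_len(dim(es$epochs)[1])) es$epochs[i, , ] <- es$epochs[2, , ]
    expect_equal(reject_trials(es)$n_rejected, 0)
    expect_error(reject_trials(epoch_melody(te$rec, toy_melody(
      c(0, 0.5, 1), c(60, 62, 64)
    ))), class = "config_error") # fewer than 10 trials
  })
})

test_that("quantile labels follow the within-melody definition", {
  te <- toy_eeg_melody(n_notes = 12, seed = 7)
  es <- epoch_melody(te$rec, te$m)
  # craft surprises 1..n for the epochs that survived
  info <- data.frame(melody_id = te$m$id, note_index = 1:12,
                     St = as.numeric(1:12), Sp = as.numeric(12:1))
  es10 <- es
  keep <- es$info$note_index %in% 2:11 # exactly 10 trials
  es10$epochs <- es$epochs[keep, , , drop = FALSE]
  es10$info <- es$info[keep, , drop = FALSE]
  qs <- quantile_split(es10, info, dimension = "St", q = 0.2)
  hi <- es10$info$note_index[qs$info$quantile == "highS"]
  lo <- es10$info$note_index[qs$info$quantile == "lowS"]
  expect_identical(sort(hi), c(10L, 11L))
  expect_identical(sort(lo), c(2L, 3L))
  # ties: first by note order get lowS, last highS
  info$St <- 1
  qt <- quantile_split(es10, info, dimension = "St", q = 0.2)
  expect_identical(qt$info$note_index[qt$info$quantile == "lowS"], c(2L, 3L))
  expect_error(quantile_split(es10, info, q = 0.7), class = "config_error")
})

test_that("the exact null yields no spuriously significant clusters", {
  withr::with_seed(41, {
    layout <- make_layout(32)
    adj <- channel_adjacency(layout)
    a <- random_erps(12, 32, 46)
    res <- cluster_permutation(a, a, adj, n_perm = 200, seed = 3)
    expect_true(is.null(res$clusters) || nrow(res$clusters) == 0)
    # a ≡ b: all differences zero, t undefined -> treated as 0
    b <- a + array(rnorm(length(a), 0, 1e-12), dim(a))
    res2 <- cluster_permutation(a, b, adj, n_perm = 200, seed = 3)
    expect_true(is.null(res2$clusters) || all(res2$clusters$p > 0.05) ||
                  nrow(res2$clusters) == 0)
  })
})

test_that("a planted spatiotemporal effect produces an overlapping cluster", {
  withr::with_seed(43, {
    layout <- make_layout(64)
    adj <- channel_adjacency(layout)
    n_sub <- 24
    times <- seq(-50, 400, by = 10)
    a <- random_erps(n_sub, 64, length(times))
    b <- random_erps(n_sub, 64, length(times))
    # a contiguous 10-electrode patch grown from the best-connected electrode
    hub <- which.max(vapply(adj, length, 0L))
    ch_set <- hub
    while (length(ch_set) < 10) {
      ch_set <- unique(c(ch_set, unlist(adj[ch_set])))
    }
    ch_set <- ch_set[1:10]
    t_set <- which(times >= 240 & times <= 370)
    a[, ch_set, t_set] <- a[, ch_set, t_set] + 2
    res <- cluster_permutation(a, b, adj, n_perm = 300, times_ms = times,
                               seed = 5)
    expect_gt(nrow(res$clusters), 0)
    top <- res$clusters[1, ]
    expect_lt(top$p, 0.05)
    expect_equal(top$polarity, 1)
    hit <- which(res$labels == top$id, arr.ind = TRUE)
    overlap <- mean(t_set %in% unique(hit[, 2]))
    expect_gte(overlap, 0.5)
  })
})

test_that("permutation results are deterministic and reorder-invariant", {
  withr::with_seed(47, {
    layout <- make_layout(16)
    adj <- channel_adjacency(layout)
    a <- random_erps(10, 16, 20)
    b <- random_erps(10, 16, 20)
    b[, 1:4, 8:14] <- b[, 1:4, 8:14] - 1.5
    r1 <- cluster_permutation(a, b, adj, n_perm = 150, seed = 9)
    r2 <- cluster_permutation(a, b, adj, n_perm = 150, seed = 9)
    expect_identical(r1$clusters, r2$clusters)
    expect_identical(r1$null_max, r2$null_max)
    # permute channels consistently: same p values
    perm <- sample(16)
    inv <- order(perm)
    adj_p <- lapply(perm, function(i) inv[adj[[i]]])
    r3 <- cluster_permutation(a[, perm, , drop = FALSE],
                              b[, perm, , drop = FALSE], adj_p,
                              n_perm = 150, seed = 9)
    expect_equal(sort(r3$clusters$mass), sort(r1$clusters$mass))
    expect_equal(sort(r3$clusters$p), sort(r1$clusters$p))
  })
})
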