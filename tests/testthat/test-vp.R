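toy_features <- function(seed = 1, n = 200) {
  withr::with_seed(seed, {
    v <- matrix(0, n, 3, dimnames = list(NULL, c("onset", "St", "ioi")))
    idx <- sort(sample(n, 12))
    v[idx, "onset"] <- 1
    v[idx, "St"] <- rnorm(12)^2 + 0.1
    v[idx, "ioi"] <- runif(12, 100, 900)
    feature_matrix(v, 100, "toy")
  })
}

test_that("onset-shuffling permutes amplitudes in place", {
  fm <- toy_features()
  sh <- shuffle_features(fm, "St", seed = 4)
  idx <- which(fm$values[, "St"] != 0)
  expect_identical(which(sh$values[, "St"] != 0), idx)
  expect_setequal(sh$values[idx, "St"], fm$values[idx, "St"])
  expect_false(identical(sh$values[, "St"], fm$values[, "St"]))
  # untouched columns
  expect_identical(sh$values[, "onset"], fm$values[, "onset"])
  expect_identical(sh$values[, "ioi"], fm$values[, "ioi"])
  # RMS is permutation-invariant
  expect_equal(sqrt(mean(sh$values[, "St"]^2)),
               sqrt(mean(fm$values[, "St"]^2)))
  # determinism and seed sensitivity
  expect_identical(shuffle_features(fm, "St", seed = 4)$values, sh$values)
  expect_false(identical(shuffle_features(fm, "St", seed = 5)$values,
                         sh$values))
})

test_that("constant columns and misuse are handled per contract", {
  fm <- toy_features()
  fm$values[fm$values[, "onset"] != 0, "onset"] <- 1
  sh <- shuffle_features(fm, "onset", seed = 2)
  expect_identical(sh$values[, "onset"], fm$values[, "onset"])
  expect_error(shuffle_features(fm, "spectral_flux"), class = "config_error")
  fm2 <- fm
  colnames(fm2$values)[3] <- "spectral_flux"
  expect_error(shuffle_features(fm2, "spectral_flux"),
               class = "config_error")
})

test_that("delta r is an elementwise antisymmetric difference", {
  withr::with_seed(3, {
    mk <- function(r) {
      structure(list(r = r, model_tag = "x", melody_ids = c("a", "b"),
                     channel_names = c("c1", "c2")),
                class = "accuracy_table")
    }
    r1 <- array(runif(2 * 2 * 2), c(2, 2, 2))
    r2 <- array(runif(2 * 2 * 2), c(2, 2, 2))
    expect_equal(delta_r(mk(r1), mk(r1))$dr, r1 - r1)
    d12 <- delta_r(mk(r1), mk(r2))$dr
    d21 <- delta_r(mk(r2), mk(r1))$dr
    expect_equal(d12, -d21)
    expect_error(delta_r(mk(r1), mk(r1[, , 1, drop = FALSE])),
                 class = "alignment_error")
  })
})

test_that("ROI selection keeps the top fraction with deterministic ties", {
  withr::with_seed(5, {
    r <- array(rnorm(3 * 4 * 64), c(3, 4, 64))
    at <- structure(list(r = r, model_tag = "full",
                         melody_ids = paste0("m", 1:4),
                         channel_names = sprintf("E%02d", 1:64)),
                    class = "accuracy_table")
    roi <- select_roi(at, 0.25)
    expect_length(roi, 3)
    expect_length(roi[[1]], 16)
    for (s in 1:3) {
      m <- apply(r[s, , , drop = FALSE], 3, mean)
      expect_equal(sort(m[roi[[s]]], decreasing = TRUE),
                   sort(m, decreasing = TRUE)[1:16])
    }
    # all-equal accuracies: first 16 channels in order
    at$r[] <- 0.3
    expect_identical(select_roi(at, 0.25)[[1]], 1:16)
    expect_error(select_roi(at, 0), class = "config_error")
  })
})

test_that("the W statistic matches the hand-computed signed-rank sum", {
  tab <- data.frame(
    subject = rep(c("S01", "S02", "S03"), 1),
    melody = "m1", condition = "real", model = "timing",
    dr = c(1, 2, 3)
  )
  gs <- suppressWarnings(group_stats(tab))
  w <- gs$wilcoxon[gs$wilcoxon$contrast == "timing|real > 0", ]
  expect_equal(w$W, 6) # all three positive ranks: 1 + 2 + 3
})

test_that("identically zero delta r is non-significant everywhere", {
  tab <- expand.grid(subject = sprintf("S%02d", 1:8),
                     melody = paste0("m", 1:4),
                     condition = c("real", "shuffled"),
                     model = c("timing", "pitch"))
  tab$dr <- 0
  gs <- suppressWarnings(group_stats(tab))
  expect_true(all(gs$wilcoxon$p > 0.5))
  expect_true(is.null(gs$lrt) || all(is.na(gs$lrt$p) | gs$lrt$p > 0.5))
})

test_that("a planted timing-only effect is detected with the right sign", {
  withr::with_seed(31, {
    n_sub <- 24
    tab <- expand.grid(subject = sprintf("S%02d", seq_len(n_sub)),
                       melody = paste0("m", 1:6),
                       condition = c("real", "shuffled"),
                       model = c("timing", "pitch"))
    eff <- ifelse(tab$condition == "real" & tab$model == "timing", 0.004, 0)
    subj_noise <- rnorm(n_sub, 0, 0.001)[as.integer(tab$subject)]
    tab$dr <- eff + subj_noise + rnorm(nrow(tab), 0, 0.002)
    gs <- group_stats(tab)
    expect_lt(gs$lrt$p[gs$lrt$term == "condition:model"], 0.05)
    wr <- gs$wilcoxon
    expect_lt(wr$p[wr$contrast == "timing|real > 0"], 0.05)
    expect_gt(wr$p[wr$contrast == "pitch|shuffled > 0"], 0.05)
  })
})
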