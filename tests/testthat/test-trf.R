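# helpers shared by the TRF tests: a small synthetic study with known
# generative weights
tiny_study <- function(n_mel = 4, n = 400, n_feat = 2, n_ch = 3, seed = 1,
                       noise_gt = 0.3, noise_sub = 0.8) {
  withr::with_seed(seed, {
    win <- lag_window(-50, 400, 100)
    fms <- list()
    for (i in seq_len(n_mel)) {
      v <- matrix(rnorm(n * n_feat) * rbinom(n * n_feat, 1, 0.06), n, n_feat,
                  dimnames = list(NULL, paste0("f", seq_len(n_feat))))
      fms[[paste0("m", i)]] <- normalize_features(
        feature_matrix(v, 100, paste0("m", i))
      )
    }
    X <- lapply(fms, build_design, window = win)
    K <- ncol(X[[1]])
    wstar <- matrix(rnorm(K * n_ch), K, n_ch) * 0.2
    gt <- list()
    sub <- list()
    for (i in names(fms)) {
      mu <- X[[i]] %*% wstar
      gt[[i]] <- eeg_recording(t(mu + rnorm(length(mu), 0, noise_gt)), 100)
      sub[[i]] <- eeg_recording(t(mu + rnorm(length(mu), 0, noise_sub)), 100)
    }
    list(win = win, fms = fms, X = X, wstar = wstar, gt = gt, sub = sub)
  })
}

test_that("the lag window and design matrix implement the shift convention", {
  win <- lag_window(-50, 400, 100)
  expect_equal(win$n_lags, 46)
  v <- matrix(0, 200, 1, dimnames = list(NULL, "imp"))
  v[100, 1] <- 1
  X <- build_design(feature_matrix(v, 100), win)
  expect_equal(ncol(X), 46)
  col <- X[, "imp@100"]
  expect_equal(which(col != 0), 110L)
  # negative lag: the EEG precedes the feature
  expect_equal(which(X[, "imp@-50"] != 0), 95L)
  # all-zero feature gives all-zero columns
  v2 <- cbind(v, dead = 0)
  X2 <- build_design(feature_matrix(v2, 100), win)
  expect_equal(max(abs(X2[, 47:92])), 0)
  expect_error(build_design(feature_matrix(v, 90), win),
               class = "config_error")
})

test_that("ridge at tiny lambda recovers noiseless weights; huge lambda shrinks", {
  st <- tiny_study(n_mel = 2, n = 500, seed = 3, noise_gt = 0, noise_sub = 0)
  X <- do.call(rbind, st$X)
  Y <- X %*% st$wstar
  fit <- fit_ridge(X, Y, 1e-8)
  ls_fit <- qr.solve(crossprod(X) + 1e-12 * diag(ncol(X)), crossprod(X, Y))
  expect_lt(max(abs(fit$weights - st$wstar)) / max(abs(st$wstar)), 1e-4)
  expect_lt(max(abs(fit$weights - ls_fit)) / max(abs(ls_fit)), 1e-4)
  big <- fit_ridge(X, Y, 1e12)
  expect_lt(sqrt(sum(big$weights^2)), 1e-6 * sqrt(sum(fit$weights^2)))
  expect_error(fit_ridge(X * NA, Y, 1), class = "data_error")
})

test_that("a duplicated feature column splits its weight additively", {
  withr::with_seed(4, {
    X <- matrix(rnorm(300 * 5), 300, 5)
    w <- rnorm(5)
    Y <- X %*% w
    lam <- 1e-7 # the shared-variance identity is exact in the small-penalty
    base <- fit_ridge(X, Y, lam) # limit; at finite lambda the pair sees an
    Xd <- cbind(X, X[, 3])       # effective penalty of lambda/2
    dup <- fit_ridge(Xd, Y, lam)
    expect_equal(dup$weights[3] + dup$weights[6], base$weights[3],
                 tolerance = 1e-6)
    # and the duplicates share the weight equally
    expect_equal(dup$weights[3], dup$weights[6], tolerance = 1e-5)
  })
})

test_that("cross-validation matches an explicit fit-and-predict oracle", {
  st <- tiny_study(seed = 7)
  lambdas <- c(0.01, 1, 100)
  cv <- cross_validate(st$fms, st$sub, st$gt, lambdas = lambdas,
                       window = st$win)
  for (lam in lambdas) {
    rs <- c()
    for (t_ in names(st$fms)) {
      tr <- setdiff(names(st$fms), t_)
      fitX <- do.call(rbind, st$X[tr])
      fitY <- do.call(rbind, lapply(tr, function(i) t(st$sub[[i]]$data)))
      fit <- fit_ridge(fitX, fitY, lam)
      pred <- st$X[[t_]] %*% fit$weights
      for (c_ in seq_len(ncol(pred))) {
        rs <- c(rs, cor(pred[, c_], st$gt[[t_]]$data[c_, ]))
      }
    }
    expect_equal(unname(cv$mean_r_by_lambda[as.character(lam)]), mean(rs),
                 tolerance = 1e-8)
  }
  expect_true(cv$lambda %in% lambdas)
  expect_error(cross_validate(st$fms[1:2], st$sub, st$gt, window = st$win),
               class = "config_error")
})

test_that("accuracy is invariant to affine rescaling of the ground truth", {
  st <- tiny_study(seed = 9)
  cv1 <- cross_validate(st$fms, st$sub, st$gt, lambdas = 1, window = st$win)
  gt2 <- lapply(st$gt, function(r) {
    r$data <- r$data * 7 - 3
    r
  })
  cv2 <- cross_validate(st$fms, st$sub, gt2, lambdas = 1, window = st$win)
  expect_equal(cv1$r, cv2$r, tolerance = 1e-10)
})

test_that("ground truth independent of the stimulus yields near-zero accuracy", {
  st <- tiny_study(seed = 11)
  withr::with_seed(12, {
    gt0 <- lapply(st$gt, function(r) {
      r$data <- matrix(rnorm(length(r$data)), nrow(r$data))
      r
    })
  })
  cv <- cross_validate(st$fms, st$sub, gt0, lambdas = 1, window = st$win)
  se <- sd(as.vector(cv$r)) / sqrt(length(cv$r))
  expect_lt(abs(mean(cv$r)), 3 * se + 0.02)
})

test_that("super-subject averaging behaves as a sample mean", {
  st <- tiny_study(n_mel = 3, seed = 13)
  one <- build_super_subject(list(st$sub))
  expect_equal(one[["m1"]]$data, st$sub[["m1"]]$data)
  neg <- lapply(st$sub, function(r) {
    r$data <- -r$data
    r
  })
  zero <- build_super_subject(list(st$sub, neg))
  expect_equal(max(abs(zero[["m2"]]$data)), 0)
  # noise shrinks as 1/sqrt(n)
  withr::with_seed(14, {
    n_sub <- 16
    subs <- lapply(seq_len(n_sub), function(s) {
      lapply(st$gt, function(r) {
        r$data <- r$data * 0 + rnorm(length(r$data))
        r
      })
    })
    ss <- build_super_subject(subs)
    expect_equal(sd(ss[["m1"]]$data), 1 / sqrt(n_sub), tolerance = 0.1)
  })
})

test_that("repetition averaging commutes with the engine's inputs", {
  st <- tiny_study(n_mel = 3, seed = 15)
  reps <- st$sub
  dup <- st$sub[["m1"]]
  dup$data <- dup$data + 1 # same melody, second presentation
  reps_list <- c(st$sub, list(dup))
  names(reps_list) <- c(names(st$sub), "m1")
  avg <- average_repetitions(reps_list)
  expect_equal(avg[["m1"]]$data, st$sub[["m1"]]$data + 0.5)
  expect_named(avg, names(st$sub))
})

test_that("planted kernels are recovered from synthetic EEG at high SNR", {
  withr::with_seed(19, {
    corpus <- generate_corpus(4, n_notes = 40, temperature = 1, seed = 33)
    names(corpus) <- vapply(corpus, `[[`, "", "id")
    fms <- lapply(corpus, function(m) {
      normalize_features(event_regressors(m, fs = 100))
    })
    layout <- make_layout(16)
    spec <- generative_spec(active_features = c("onset", "ioi"), snr = 20,
                            n_subjects = 1, latency_jitter_ms = 0,
                            gain_sd = 0, layout = layout, seed = 5)
    sim <- generate_eeg(fms, spec)
    win <- lag_window()
    X <- do.call(rbind, lapply(fms, build_design, window = win))
    Y <- do.call(rbind, lapply(sim$eeg[[1]], function(r) t(r$data)))
    fit <- fit_ridge(X, Y, 1, window = win,
                     feature_names = colnames(fms[[1]]$values))
    arr <- trf_weights_array(fit)
    for (fi in seq_along(sim$kernels[[1]])) {
      got <- as.vector(arr[, fi, ])
      want <- as.vector(sim$kernels[[1]][[fi]])
      expect_gt(cor(got, want), 0.95)
    }
  })
})
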