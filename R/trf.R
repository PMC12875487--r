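# Forward (encoding) temporal response functions: multivariate lagged ridge
# regression, leave-one-melody-out cross-validation, and prediction accuracy
# against a group-average "super-subject" EEG.
#
# The cross-validation engine exploits two structural facts to stay fast:
# the design matrices depend only on the stimuli (so Gram matrices and their
# per-fold eigendecompositions are shared across subjects), and Pearson
# correlations between predictions and the ground truth need only quadratic
# forms of the test-fold design (so no per-lambda explicit predictions).

#' TRF lag window
#'
#' @param t_min,t_max lag span in ms (defaults -50 and +400; negative lags
#'   mean the EEG precedes the feature).
#' @param fs sampling rate (default 100 Hz).
#' @return list with `t_min`, `t_max`, `fs`, `lag_samples`, `lags_ms`,
#'   `n_lags` (46 at the defaults).
#' @export
lag_window <- function(t_min = -50, t_max = 400, fs = 100) {
  lag_samples <- seq(round(t_min / 1000 * fs), round(t_max / 1000 * fs))
  list(t_min = t_min, t_max = t_max, fs = fs, lag_samples = lag_samples,
       lags_ms = lag_samples / fs * 1000, n_lags = length(lag_samples))
}

#' Build the lagged design matrix for one melody
#'
#' One column per (feature, lag) pair: the column for lag `l` holds the
#' feature delayed by `l` samples (zero-padded at the edges), so that
#' `EEG(t) ~ sum_l w_l x(t - l)`.
#'
#' @param fm a [feature_matrix()].
#' @param window a [lag_window()] at the same sampling rate.
#' @return numeric matrix samples x (features * n_lags); column names are
#'   `feature@lag_ms`.
#' @export
build_design <- function(fm, window) {
  if (abs(fm$fs - window$fs) > 1e-9) {
    stop_config("feature matrix and lag window sampling rates differ")
  }
  x <- fm$values
  n <- nrow(x)
  nf <- ncol(x)
  nl <- window$n_lags
  X <- matrix(0, n, nf * nl)
  cn <- character(nf * nl)
  for (fi in seq_len(nf)) {
    for (li in seq_len(nl)) {
      l <- window$lag_samples[li]
      col <- (fi - 1L) * nl + li
      if (l >= 0) {
        if (l < n) X[(1 + l):n, col] <- x[seq_len(n - l), fi]
      } else {
        if (-l < n) X[seq_len(n + l), col] <- x[(1 - l):n, fi]
      }
      cn[col] <- sprintf("%s@%g", colnames(x)[fi], window$lags_ms[li])
    }
  }
  colnames(X) <- cn
  X
}

#' Closed-form ridge regression with unpenalized intercept
#'
#' Solves `Y ~ X w + b` per channel with an identity-scaled penalty on `w`
#' (the intercept enters through centering and is not shrunk).
#'
#' @param X design matrix (samples x predictors).
#' @param Y response matrix (samples x channels).
#' @param lambda ridge parameter (> 0, or 0 for plain least squares).
#' @param window optional [lag_window()] stored on the model.
#' @param feature_names optional feature labels stored on the model.
#' @return object of class `trf_model`: `weights` (predictors x channels),
#'   `bias` (per channel), `lambda`, `window`, `feature_names`.
#' @export
fit_ridge <- function(X, Y, lambda, window = NULL, feature_names = NULL) {
  if (!all(is.finite(X)) || !all(is.finite(Y))) {
    stop_data("non-finite values in ridge inputs")
  }
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop_config("X and Y sample counts differ")
  mx <- colMeans(X)
  my <- colMeans(Y)
  Xc <- sweep(X, 2L, mx)
  Yc <- sweep(Y, 2L, my)
  A <- crossprod(Xc)
  diag(A) <- diag(A) + lambda
  W <- solve(A, crossprod(Xc, Yc))
  structure(
    list(weights = W, bias = my - drop(crossprod(mx, W)), lambda = lambda,
         window = window, feature_names = feature_names),
    class = "trf_model"
  )
}

#' @export
print.trf_model <- function(x, ...) {
  cat(sprintf("<trf_model> %d predictors x %d channels, lambda=%g\n",
              nrow(x$weights), ncol(x$weights), x$lambda))
  invisible(x)
}

#' Reshape TRF weights to channels x features x lags
#'
#' @param model a `trf_model` fitted on a [build_design()] matrix.
#' @param n_features,n_lags dimensions (taken from the stored metadata if
#'   available).
#' @return 3-D array channels x features x lags.
#' @export
trf_weights_array <- function(model, n_features = NULL, n_lags = NULL) {
  n_lags <- n_lags %||% model$window$n_lags
  n_features <- n_features %||% (nrow(model$weights) / n_lags)
  arr <- array(0, c(ncol(model$weights), n_features, n_lags))
  for (fi in seq_len(n_features)) {
    idx <- (fi - 1L) * n_lags + seq_len(n_lags)
    arr[, fi, ] <- t(model$weights[idx, , drop = FALSE])
  }
  dimnames(arr) <- list(colnames(model$weights),
                        model$feature_names %||% seq_len(n_features), NULL)
  arr
}

#' Group-average ground-truth EEG ("super-subject")
#'
#' Sample-wise mean across subjects, per melody; subjects missing a melody
#' are skipped in that melody's average.
#'
#' @param eeg_all_subjects list over subjects, each a named list of
#'   [eeg_recording()] keyed by melody id.
#' @return named list of [eeg_recording()].
#' @export
build_super_subject <- function(eeg_all_subjects) {
  ids <- unique(unlist(lapply(eeg_all_subjects, names)))
  out <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    recs <- Filter(Negate(is.null),
                   lapply(eeg_all_subjects, function(s) s[[id]]))
    if (!length(recs)) stop_data(paste("no subject has melody", id))
    n <- min(vapply(recs, function(r) ncol(r$data), 0L))
    acc <- Reduce(`+`, lapply(recs, function(r) r$data[, seq_len(n)]))
    tmpl <- recs[[1L]]
    out[[id]] <- eeg_recording(acc / length(recs), tmpl$fs,
                               tmpl$channel_names, tmpl$positions)
  }
  out
}

#' Average repeated presentations of the same melody
#'
#' @param recs list of [eeg_recording()] whose names may repeat (one entry
#'   per presentation); repetitions are averaged sample-wise.
#' @return named list with one averaged recording per distinct melody.
#' @export
average_repetitions <- function(recs) {
  ids <- unique(names(recs))
  stats::setNames(lapply(ids, function(id) {
    grp <- recs[names(recs) == id]
    if (length(grp) == 1L) return(grp[[1L]])
    n <- min(vapply(grp, function(r) ncol(r$data), 0L))
    acc <- Reduce(`+`, lapply(grp, function(r) r$data[, seq_len(n)]))
    eeg_recording(acc / length(grp), grp[[1L]]$fs, grp[[1L]]$channel_names,
                  grp[[1L]]$positions)
  }), ids)
}

# ---- cross-validation engine ------------------------------------------------

# Two-part cache for the cross-validation engine.
#
# stimulus_cache: everything that depends only on the regressors -- per
# melody the design matrix, Gram, and column sums; per fold the
# eigendecomposition of the centered training Gram and the test-fold
# quadratic form in the eigenbasis. Reusable across subjects, lambdas, and
# any simulation that redraws only the EEG.
stimulus_cache <- function(features, window, X = NULL, ids = NULL) {
  ids <- ids %||% names(features)
  if (is.null(X)) X <- lapply(features, build_design, window = window)
  G <- lapply(X, crossprod)
  h <- lapply(X, colSums)
  n <- vapply(X, nrow, 0L)
  folds <- lapply(seq_along(ids), function(t_) {
    tr <- setdiff(seq_along(ids), t_)
    N <- sum(n[tr])
    hsum <- Reduce(`+`, h[tr])
    Gtr <- Reduce(`+`, G[tr]) - tcrossprod(hsum) / N
    eg <- eigen(Gtr, symmetric = TRUE)
    V <- eg$vectors
    d <- pmax(eg$values, 0)
    St <- G[[t_]] - tcrossprod(h[[t_]]) / n[[t_]]
    list(test = t_, train = tr, V = V, d = d, N = N, hsum = hsum,
         S_tilde = crossprod(V, St %*% V))
  })
  list(ids = ids, X = X, G = G, h = h, n = n, folds = folds, window = window)
}

# design_cache = stimulus cache + ground-truth projections per fold
design_cache <- function(features, ground_truth, window, stim = NULL) {
  if (is.null(stim)) stim <- stimulus_cache(features, window)
  ids <- stim$ids
  # EEG shorter than the padded feature matrix: trim designs and redo the
  # stimulus-side quantities on the common support
  n_gt <- vapply(ids, function(id) ncol(ground_truth[[id]]$data), 0L)
  if (any(n_gt < stim$n)) {
    Xtrim <- lapply(seq_along(ids), function(i) {
      stim$X[[i]][seq_len(min(n_gt[i], stim$n[i])), , drop = FALSE]
    })
    names(Xtrim) <- ids
    stim <- stimulus_cache(window = window, X = Xtrim, ids = ids)
  }
  Ygt <- lapply(ids, function(id) {
    t(ground_truth[[id]]$data)[seq_len(stim$n[[id]]), , drop = FALSE]
  })
  names(Ygt) <- ids
  gy <- lapply(Ygt, colSums)
  for (fi in seq_along(stim$folds)) {
    fo <- stim$folds[[fi]]
    t_ <- fo$test
    cyt <- crossprod(stim$X[[t_]], Ygt[[t_]]) -
      outer(stim$h[[t_]], gy[[t_]] / stim$n[[t_]])
    stim$folds[[fi]]$cy_tilde <- crossprod(fo$V, cyt)
    stim$folds[[fi]]$var_y <- colSums(Ygt[[t_]]^2) - gy[[t_]]^2 / stim$n[[t_]]
  }
  stim$n_channels <- ncol(Ygt[[1L]])
  stim
}

# Per-subject leave-one-melody-out accuracies for every lambda, given a
# design cache. Returns r: lambdas x melodies x channels.
cv_accuracies <- function(cache, eeg_subject, lambdas) {
  ids <- cache$ids
  K <- ncol(cache$X[[1L]])
  C <- cache$n_channels
  b <- lapply(ids, function(id) {
    Ys <- t(eeg_subject[[id]]$data)[seq_len(cache$n[[id]]), , drop = FALSE]
    list(xy = crossprod(cache$X[[id]], Ys), ysum = colSums(Ys))
  })
  names(b) <- ids
  r <- array(NA_real_, c(length(lambdas), length(ids), C))
  for (fi in seq_along(cache$folds)) {
    fo <- cache$folds[[fi]]
    xy <- Reduce(`+`, lapply(b[fo$train], `[[`, "xy"))
    ysum <- Reduce(`+`, lapply(b[fo$train], `[[`, "ysum"))
    bc <- xy - outer(fo$hsum, ysum / fo$N)
    bt <- crossprod(fo$V, bc) # K x C in the eigenbasis
    for (li in seq_along(lambdas)) {
      wt <- bt / (fo$d + lambdas[li])
      num <- colSums(wt * fo$cy_tilde)
      den <- colSums(wt * (fo$S_tilde %*% wt))
      rr <- num / sqrt(pmax(den, 1e-300) * pmax(fo$var_y, 1e-300))
      rr[den <= 0 | fo$var_y <= 0] <- 0
      r[li, fo$test, ] <- pmin(pmax(rr, -1), 1)
    }
  }
  r
}

#' Default ridge parameter grid (decades from 1e-4 to 1e8)
#' @export
default_lambda_grid <- function() 10^seq(-4, 8)

#' Leave-one-melody-out TRF cross-validation for one subject
#'
#' For each held-out melody, a TRF is trained on the subject's remaining
#' melodies (all conditions pooled), and the prediction of the held-out
#' melody is correlated per channel with the ground-truth (super-subject)
#' EEG. The ridge parameter is chosen to maximize the mean correlation over
#' channels and folds (one lambda for the subject), unless `lambda_fixed`
#' is given.
#'
#' @param features named list of normalized [feature_matrix()] per melody.
#' @param eeg_subject named list of [eeg_recording()] per melody (repeated
#'   presentations must be averaged first, see [average_repetitions()]).
#' @param eeg_ground_truth named list of [eeg_recording()] per melody.
#' @param lambdas ridge grid (default [default_lambda_grid()]).
#' @param window a [lag_window()].
#' @param lambda_fixed optional single lambda, skipping selection.
#' @param cache optional precomputed internal design cache (for repeated
#'   calls across subjects).
#' @return list: `r` (melodies x channels matrix of Pearson correlations at
#'   the chosen lambda), `lambda`, `mean_r_by_lambda`.
#' @export
cross_validate <- function(features, eeg_subject, eeg_ground_truth,
                           lambdas = default_lambda_grid(),
                           window = lag_window(), lambda_fixed = NULL,
                           cache = NULL) {
  if (length(features) < 3L) stop_config("need at least 3 melodies")
  ids <- names(features)
  if (!all(ids %in% names(eeg_subject)) ||
      !all(ids %in% names(eeg_ground_truth))) {
    stop_config("melody keys differ across features, subject EEG, ground truth")
  }
  if (is.null(cache)) {
    cache <- design_cache(features, eeg_ground_truth, window)
  }
  use_lambdas <- if (is.null(lambda_fixed)) lambdas else lambda_fixed
  r <- cv_accuracies(cache, eeg_subject, use_lambdas)
  mean_r <- apply(r, 1L, mean)
  li <- which.max(mean_r)
  out_r <- r[li, , , drop = TRUE]
  dim(out_r) <- c(length(ids), cache$n_channels)
  dimnames(out_r) <- list(ids, eeg_ground_truth[[1L]]$channel_names)
  list(r = out_r, lambda = use_lambdas[li],
       mean_r_by_lambda = stats::setNames(mean_r, use_lambdas))
}

#' Cross-validated TRF accuracies for a whole study
#'
#' Runs [cross_validate()] for every subject against the shared ground
#' truth, reusing the stimulus-side computations across subjects.
#'
#' @inheritParams cross_validate
#' @param eeg_by_subject list over subjects of named per-melody recording
#'   lists.
#' @param lambda_fixed optional per-subject numeric vector (or single
#'   value) of fixed lambdas.
#' @param model_tag label stored on the result.
#' @param stim optional precomputed stimulus-side cache (internal; lets
#'   simulations that redraw only the EEG reuse the design eigensystem).
#' @return object of class `accuracy_table`: `r` (subjects x melodies x
#'   channels), `lambda` (per subject), `model_tag`, `melody_ids`,
#'   `channel_names`.
#' @export
trf_study <- function(features, eeg_by_subject, eeg_ground_truth,
                      lambdas = default_lambda_grid(),
                      window = lag_window(), lambda_fixed = NULL,
                      model_tag = "full", stim = NULL) {
  cache <- design_cache(features, eeg_ground_truth, window, stim = stim)
  ns <- length(eeg_by_subject)
  ids <- names(features)
  C <- cache$n_channels
  r <- array(NA_real_, c(ns, length(ids), C),
             dimnames = list(NULL, ids, eeg_ground_truth[[1L]]$channel_names))
  lam <- numeric(ns)
  if (!is.null(lambda_fixed)) lambda_fixed <- rep_len(lambda_fixed, ns)
  for (s in seq_len(ns)) {
    cv <- cross_validate(features, eeg_by_subject[[s]], eeg_ground_truth,
                         lambdas, window,
                         lambda_fixed = lambda_fixed[s], cache = cache)
    r[s, , ] <- cv$r
    lam[s] <- cv$lambda
  }
  structure(
    list(r = r, lambda = lam, model_tag = model_tag, melody_ids = ids,
         channel_names = eeg_ground_truth[[1L]]$channel_names),
    class = "accuracy_table"
  )
}

#' @export
print.accuracy_table <- function(x, ...) {
  cat(sprintf(
    "<accuracy_table '%s'> %d subjects x %d melodies x %d channels, mean r=%.4f\n",
    x$model_tag, dim(x$r)[1], dim(x$r)[2], dim(x$r)[3], mean(x$r)
  ))
  invisible(x)
}
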