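# Note-locked event-related potentials: epoching with baseline correction,
# SD-based trial rejection, within-melody surprise-quantile labelling, and
# paired cluster-based permutation testing over channels x time.

#' Extract note-locked epochs from a melody-aligned recording
#'
#' One epoch per note whose full window lies inside the recording (boundary
#' notes are skipped and counted). Each epoch is baseline-corrected by
#' subtracting the per-trial/channel mean over the baseline window.
#'
#' @param eeg an [eeg_recording()] aligned to the melody (sample 1 = melody
#'   onset), typically at 100 Hz.
#' @param m the [melody()].
#' @param window_ms epoch span relative to note onset (default -100..500).
#' @param baseline_ms baseline window (default -50..0).
#' @return object of class `epoch_set`: `epochs` (trials x channels x
#'   samples), `times_ms`, `info` (melody, condition, note_index, onset_s),
#'   `n_skipped`, `fs`, `channel_names`.
#' @export
epoch_melody <- function(eeg, m, window_ms = c(-100, 500),
                         baseline_ms = c(-50, 0)) {
  fs <- eeg$fs
  rel <- seq(round(window_ms[1] / 1000 * fs), round(window_ms[2] / 1000 * fs))
  times_ms <- rel / fs * 1000
  bsel <- times_ms >= baseline_ms[1] & times_ms <= baseline_ms[2]
  n_samp <- ncol(eeg$data)
  keep <- list()
  info <- list()
  for (i in seq_len(n_notes(m))) {
    ctr <- round(m$notes$onset[i] * fs) + 1L
    idx <- ctr + rel
    if (idx[1] < 1L || idx[length(idx)] > n_samp) next
    ep <- eeg$data[, idx, drop = FALSE]
    ep <- ep - rowMeans(ep[, bsel, drop = FALSE])
    keep[[length(keep) + 1L]] <- ep
    info[[length(info) + 1L]] <- data.frame(
      melody = m$id, condition = m$condition, note_index = i,
      onset_s = m$notes$onset[i]
    )
  }
  n_kept <- length(keep)
  epochs <- array(0, c(n_kept, nrow(eeg$data), length(rel)))
  for (k in seq_len(n_kept)) epochs[k, , ] <- keep[[k]]
  structure(
    list(epochs = epochs, times_ms = times_ms,
         info = if (n_kept) do.call(rbind, info) else NULL,
         n_skipped = n_notes(m) - n_kept, fs = fs,
         channel_names = eeg$channel_names,
         window_ms = window_ms, baseline_ms = baseline_ms),
    class = "epoch_set"
  )
}

#' Concatenate epoch sets (e.g. over melodies)
#' @param ... `epoch_set` objects with identical windows and channels.
#' @return a single `epoch_set`.
#' @export
bind_epochs <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) &&
      !inherits(sets[[1L]], "epoch_set")) {
    sets <- sets[[1L]]
  }
  base <- sets[[1L]]
  base$epochs <- do.call(abind_first, lapply(sets, `[[`, "epochs"))
  base$info <- do.call(rbind, lapply(sets, `[[`, "info"))
  base$n_skipped <- sum(vapply(sets, `[[`, 0L, "n_skipped"))
  base
}

abind_first <- function(...) {
  arrs <- list(...)
  ns <- vapply(arrs, function(a) dim(a)[1], 0L)
  out <- array(0, c(sum(ns), dim(arrs[[1L]])[2], dim(arrs[[1L]])[3]))
  at <- 0L
  for (a in arrs) {
    if (dim(a)[1] > 0) out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Reject high-variance trials
#'
#' Removes trials whose SD (across all samples and channels) exceeds the
#' mean trial SD by more than `z` times the SD of the trial-SD
#' distribution; the scan is applied twice (rejection can unmask further
#' outliers).
#'
#' @param es an `epoch_set` with >= 10 trials.
#' @param z threshold (default 2.5).
#' @return `epoch_set` with offending trials dropped; the count removed is
#'   stored as `n_rejected`. Warns (`data_quality_warning`) when more than
#'   half the trials go.
#' @export
reject_trials <- function(es, z = 2.5) {
  n0 <- dim(es$epochs)[1]
  if (n0 < 10L) stop_config("need at least 10 trials")
  keep <- rep(TRUE, n0)
  for (pass in 1:2) {
    sds <- apply(es$epochs[keep, , , drop = FALSE], 1L, stats::sd)
    bad <- sds > mean(sds) + z * stats::sd(sds)
    if (!any(bad)) break
    keep[which(keep)[bad]] <- FALSE
  }
  if (sum(!keep) > n0 / 2) {
    warn_data_quality("more than 50% of trials rejected")
  }
  es$epochs <- es$epochs[keep, , , drop = FALSE]
  es$info <- es$info[keep, , drop = FALSE]
  es$n_rejected <- sum(!keep)
  es
}

#' Label trials by within-melody surprise quantiles
#'
#' Per melody, the notes whose surprise falls in the top `q` fraction are
#' labelled `highS`, the bottom `q` fraction `lowS`, the rest `mid`. Ties
#' break by note order.
#'
#' @param es an `epoch_set`.
#' @param info an `info_estimates` table ([estimate_information()]).
#' @param dimension `"St"` (timing) or `"Sp"` (pitch).
#' @param q quantile fraction in (0, 0.5] (default 0.20).
#' @return `epoch_set` with a `quantile` column added to `info`; trials
#'   with undefined surprise are labelled `mid`.
#' @export
quantile_split <- function(es, info, dimension = c("St", "Sp"), q = 0.20) {
  dimension <- match.arg(dimension)
  if (q <= 0 || q > 0.5) stop_config("q must be in (0, 0.5]")
  es$info$quantile <- "mid"
  for (id in unique(es$info$melody)) {
    tri <- which(es$info$melody == id)
    mi <- info[info$melody_id == id, ]
    s <- mi[[dimension]][match(es$info$note_index[tri], mi$note_index)]
    def <- which(!is.na(s))
    k <- max(1L, floor(q * length(def)))
    ord <- def[order(s[def], def)] # ascending, ties by note order
    es$info$quantile[tri[ord[seq_len(k)]]] <- "lowS"
    es$info$quantile[tri[rev(ord)[seq_len(k)]]] <- "highS"
  }
  es
}

#' Average epochs into a subject-level ERP
#'
#' @param es an `epoch_set` (with quantile labels if `quantile` is given).
#' @param quantile,condition optional filters on the trial labels.
#' @param trim_ms window to keep (default -50..400 ms).
#' @return list: `erp` (channels x samples), `times_ms`, `n_trials`.
#' @export
subject_erp <- function(es, quantile = NULL, condition = NULL,
                        trim_ms = c(-50, 400)) {
  sel <- rep(TRUE, nrow(es$info))
  if (!is.null(quantile)) sel <- sel & es$info$quantile == quantile
  if (!is.null(condition)) sel <- sel & es$info$condition == condition
  tsel <- es$times_ms >= trim_ms[1] & es$times_ms <= trim_ms[2] + 1e-9
  x <- es$epochs[sel, , tsel, drop = FALSE]
  erp <- apply(x, c(2, 3), mean)
  list(erp = erp, times_ms = es$times_ms[tsel], n_trials = sum(sel))
}

#' Channel adjacency from electrode positions
#'
#' @param positions channels x 3 matrix (mm).
#' @param radius_mm neighborhood radius (default 18; on the synthetic
#'   64-channel layout this gives a median of 6-8 neighbors).
#' @return list of integer neighbor-index vectors, one per channel.
#' @export
channel_adjacency <- function(positions, radius_mm = 18) {
  D <- as.matrix(stats::dist(positions))
  lapply(seq_len(nrow(D)), function(i) {
    which(D[i, ] <= radius_mm & seq_len(ncol(D)) != i)
  })
}

#' Paired cluster-based permutation test over channels x time
#'
#' Computes a paired t statistic per (channel, timepoint) between two
#' subject-level ERP conditions, thresholds it at the `alpha_cluster`
#' point-wise tail, clusters suprathreshold points by spatiotemporal
#' adjacency (discarding clusters spanning fewer than `min_neighbors`
#' distinct electrodes, in the observed data and in every permutation
#' alike), and compares each cluster's summed t (mass) to a sign-flipping
#' Monte Carlo null of the maximum absolute cluster mass.
#'
#' @param erp_a,erp_b arrays subjects x channels x timepoints (paired).
#' @param adjacency neighbor list from [channel_adjacency()].
#' @param n_perm Monte Carlo iterations (default 1000).
#' @param alpha_cluster point-wise threshold per tail (default 0.025).
#' @param alpha_report cluster-level significance level (default 0.05).
#' @param min_neighbors minimum electrode extent of a reportable cluster
#'   (default 3).
#' @param times_ms optional timepoint labels propagated to the output.
#' @param seed integer.
#' @return object of class `cluster_result`: data frame `clusters`
#'   (id, polarity, mass, p, n_points, t_start_ms, t_end_ms), plus
#'   `labels` (channels x time cluster ids), `tmat`, `t_crit`, `null_max`.
#' @export
cluster_permutation <- function(erp_a, erp_b, adjacency, n_perm = 1000L,
                                alpha_cluster = 0.025, alpha_report = 0.05,
                                min_neighbors = 3L, times_ms = NULL,
                                seed = 1L) {
  stopifnot(identical(dim(erp_a), dim(erp_b)))
  n_sub <- dim(erp_a)[1]
  if (n_sub < 6L) warn_power("fewer than 6 subjects; permutation test weak")
  n_ch <- dim(erp_a)[2]
  n_t <- dim(erp_a)[3]
  D <- matrix(erp_a - erp_b, n_sub, n_ch * n_t) # points channel-fastest
  m <- colMeans(D)
  s <- apply(D, 2L, stats::sd)
  tvec <- ifelse(s > 0, m / (s / sqrt(n_sub)), 0)
  tmat <- matrix(tvec, n_ch, n_t)
  t_crit <- stats::qt(1 - alpha_cluster, df = n_sub - 1)
  obs <- find_clusters_cpp(tmat, t_crit, adjacency, as.integer(min_neighbors))
  signs <- with_seed(seed, {
    matrix(sample(c(-1L, 1L), n_perm * n_sub, replace = TRUE), n_perm, n_sub)
  })
  null_max <- perm_null_max_mass_cpp(D, signs, t_crit, adjacency,
                                     n_ch, n_t, as.integer(min_neighbors))
  clus <- NULL
  if (length(obs$mass)) {
    p <- vapply(obs$mass, function(ms) {
      mean(null_max >= abs(ms))
    }, 0)
    span <- t(vapply(seq_along(obs$mass), function(i) {
      tp <- which(apply(obs$labels == i, 2L, any))
      range(tp)
    }, c(0, 0)))
    clus <- data.frame(
      id = seq_along(obs$mass), polarity = obs$polarity,
      mass = obs$mass, p = p,
      n_points = vapply(seq_along(obs$mass),
                        function(i) sum(obs$labels == i), 0),
      t_start = span[, 1], t_end = span[, 2]
    )
    if (!is.null(times_ms)) {
      clus$t_start_ms <- times_ms[clus$t_start]
      clus$t_end_ms <- times_ms[clus$t_end]
    }
    clus <- clus[order(clus$p, -abs(clus$mass)), ]
  }
  structure(
    list(clusters = clus, labels = obs$labels, tmat = tmat, t_crit = t_crit,
         null_max = null_max, alpha_report = alpha_report,
         times_ms = times_ms),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  if (is.null(x$clusters) || !nrow(x$clusters)) {
    cat("<cluster_result> no suprathreshold clusters\n")
  } else {
    sig <- sum(x$clusters$p < x$alpha_report)
    cat(sprintf("<cluster_result> %d clusters, %d significant at p < %g\n",
                nrow(x$clusters), sig, x$alpha_report))
    print(utils::head(x$clusters, 5), row.names = FALSE)
  }
  invisible(x)
}
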