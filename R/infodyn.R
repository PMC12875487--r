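# Note-by-note information dynamics: surprise and entropy for the pitch and
# timing viewpoints, from a combination of a short-term model (built online
# from the unfolding melody) and a long-term model (trained on the other
# cross-validation folds, optionally plus a pretraining corpus, and -- in the
# "both+" configuration -- updated online by the test melody as well).

viewpoint_alphabets <- function(melodies) {
  vps <- lapply(melodies, derive_viewpoints)
  list(
    cpitch = sort(unique(unlist(lapply(vps, function(v) v$cpitch$symbols)))),
    ioi_ratio = sort(unique(stats::na.omit(unlist(
      lapply(vps, function(v) v$ioi_ratio$symbols)
    ))))
  )
}

# Surprise/entropy for one melody's one viewpoint given a (possibly NULL)
# LTM. STM starts empty and learns online; with ltm_update=TRUE the LTM also
# absorbs each note after prediction ("+" configurations).
info_one_viewpoint <- function(symbols, alphabet, ltm, max_order, bias,
                               ltm_update = TRUE) {
  n <- length(symbols)
  S <- rep(NA_real_, n)
  E <- rep(NA_real_, n)
  stm <- ppm_new(alphabet, max_order)
  run <- character(0)
  for (k in seq_len(n)) {
    s <- symbols[k]
    if (is.na(s)) { run <- character(0); next }
    p_stm <- ppm_predict(stm, run)
    p <- if (is.null(ltm)) p_stm else {
      combine_stm_ltm(p_stm, ppm_predict(ltm, run), bias = bias)
    }
    S[k] <- -log2(p[[s]])
    E[k] <- entropy_bits(p)
    stm <- ppm_observe(stm, run, s)
    if (!is.null(ltm) && ltm_update) ltm <- ppm_observe(ltm, run, s)
    run <- c(run, s)
  }
  list(S = S, E = E)
}

#' Note-by-note surprise and entropy for a melody corpus
#'
#' For each melody, held out under seed-deterministic k-fold resampling, the
#' long-term model (LTM) is trained on the melodies of the other folds (plus
#' an optional pretraining corpus), the short-term model (STM) is built
#' incrementally from the held-out melody alone, and their predictions are
#' combined by entropy weighting. Surprise is `-log2 P(symbol)` of the
#' combined distribution and entropy its Shannon entropy, computed
#' independently for the pitch viewpoint (`Sp`, `Ep`) and the
#' IOI-ratio timing viewpoint (`St`, `Et`; undefined for notes 1-2).
#'
#' @param corpus list of [melody()] objects.
#' @param folds number of resampling folds (default 10). `folds = 1` trains
#'   the LTM on nothing, i.e. STM-only estimates.
#' @param max_order PPM context bound (default 10).
#' @param bias entropy-weighting exponent for [combine_stm_ltm()].
#' @param pretrain_corpus optional list of melodies always included in LTM
#'   training (the "pretrained" variant).
#' @param ltm_mode `"both+"` (default: STM + LTM, LTM updated online within
#'   the test melody) or `"both"` (LTM frozen during the test melody).
#' @param seed integer; fixes the fold assignment.
#' @return data frame with columns `melody_id, condition, note_index,
#'   onset_s, Sp, Ep, St, Et` (class `info_estimates`).
#' @export
estimate_information <- function(corpus, folds = 10L, max_order = 10L,
                                 bias = 2, pretrain_corpus = NULL,
                                 ltm_mode = c("both+", "both"),
                                 seed = 1L) {
  ltm_mode <- match.arg(ltm_mode)
  n_mel <- length(corpus)
  if (folds < 1L) stop_config("folds must be >= 1")
  if (folds > n_mel) stop_config("more folds than melodies")
  alpha <- viewpoint_alphabets(c(corpus, pretrain_corpus))
  fold_of <- with_seed(seed, sample(rep_len(seq_len(folds), n_mel)))
  vps <- lapply(corpus, derive_viewpoints)
  pre_vps <- if (is.null(pretrain_corpus)) list() else {
    lapply(pretrain_corpus, derive_viewpoints)
  }
  out <- vector("list", n_mel)
  for (f in seq_len(folds)) {
    test_idx <- which(fold_of == f)
    train_idx <- which(fold_of != f)
    train_pitch <- c(
      lapply(pre_vps, function(v) v$cpitch$symbols),
      lapply(vps[train_idx], function(v) v$cpitch$symbols)
    )
    train_time <- c(
      lapply(pre_vps, function(v) v$ioi_ratio$symbols),
      lapply(vps[train_idx], function(v) v$ioi_ratio$symbols)
    )
    for (i in test_idx) {
      # fresh LTM per melody so online "+" updates never leak across test
      # melodies of the same fold
      if (folds == 1L) {
        ltm_p <- NULL
        ltm_t <- NULL
      } else {
        ltm_p <- ppm_fit(train_pitch, max_order, alphabet = alpha$cpitch)
        ltm_t <- ppm_fit(train_time, max_order, alphabet = alpha$ioi_ratio)
      }
      m <- corpus[[i]]
      v <- vps[[i]]
      upd <- ltm_mode == "both+"
      ip <- info_one_viewpoint(v$cpitch$symbols, alpha$cpitch, ltm_p,
                               max_order, bias, ltm_update = upd)
      it <- info_one_viewpoint(v$ioi_ratio$symbols, alpha$ioi_ratio, ltm_t,
                               max_order, bias, ltm_update = upd)
      out[[i]] <- data.frame(
        melody_id = m$id, condition = m$condition,
        note_index = seq_len(n_notes(m)), onset_s = m$notes$onset,
        Sp = ip$S, Ep = ip$E, St = it$S, Et = it$E
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("info_estimates", "data.frame")
  res
}

#' Per-melody mean surprise/entropy summary
#'
#' @param info an `info_estimates` table from [estimate_information()].
#' @return data frame with one row per melody: mean `Sp`, `Ep`, `St`, `Et`
#'   over defined notes, plus the melody condition.
#' @export
summarize_information <- function(info) {
  ids <- unique(info$melody_id)
  do.call(rbind, lapply(ids, function(id) {
    x <- info[info$melody_id == id, ]
    data.frame(
      melody_id = id, condition = x$condition[1],
      Sp = mean(x$Sp, na.rm = TRUE), Ep = mean(x$Ep, na.rm = TRUE),
      St = mean(x$St, na.rm = TRUE), Et = mean(x$Et, na.rm = TRUE)
    )
  }))
}

#' Write information estimates to a tab-separated table
#'
#' @param info `info_estimates` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_information <- function(info, path) {
  utils::write.table(info, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
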