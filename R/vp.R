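# Variance partitioning: reduced models whose regressor amplitudes are
# permuted across note onsets, prediction-accuracy differences (delta r),
# ROI channel selection, and group-level statistics.

#' Feature sets behind the five standard reduced models
#'
#' Named list mapping each reduced-model label (`highlevel`, `timing`,
#' `pitch`, `ioi`, `ipi`) to the regressor columns it randomizes.
#' @export
REDUCED_MODEL_SETS <- list(
  highlevel = c("St", "Et", "Sp", "Ep"),
  timing = c("St", "Et"),
  pitch = c("Sp", "Ep"),
  ioi = "ioi",
  ipi = "ipi"
)

#' Temporally randomize event regressors
#'
#' For each named column, the impulse amplitudes are permuted uniformly at
#' random across that melody's note onsets; the onset sample positions (and
#' every other column) are untouched. This preserves the regressor's value
#' distribution and the stimulus timing while destroying the note-to-value
#' assignment — the construction behind the "reduced" models.
#'
#' @param fm a [feature_matrix()].
#' @param features_to_shuffle character vector of event-column names.
#' @param seed integer.
#' @return a [feature_matrix()] with permuted amplitudes.
#' @export
shuffle_features <- function(fm, features_to_shuffle, seed = 1L) {
  v <- fm$values
  missing <- setdiff(features_to_shuffle, colnames(v))
  if (length(missing)) {
    stop_config(paste("features absent:", paste(missing, collapse = ", ")))
  }
  continuous <- c("spectral_flux", "envelope", "env_derivative")
  if (any(features_to_shuffle %in% continuous)) {
    stop_config("continuous acoustic columns cannot be onset-shuffled")
  }
  with_seed(seed, {
    for (f in features_to_shuffle) {
      idx <- which(v[, f] != 0)
      if (length(idx) > 1L) v[idx, f] <- v[sample(idx), f]
    }
  })
  feature_matrix(v, fm$fs, fm$melody_id, normalized = fm$normalized)
}

#' Reduced-model feature sets for a melody list
#'
#' Applies [shuffle_features()] per melody (amplitudes never cross
#' melodies), with per-melody seeds derived from `seed`.
#'
#' @param features named list of [feature_matrix()].
#' @param features_to_shuffle column names to randomize.
#' @param seed integer.
#' @return named list of shuffled [feature_matrix()].
#' @export
reduce_features <- function(features, features_to_shuffle, seed = 1L) {
  out <- features
  for (id in names(features)) {
    out[[id]] <- shuffle_features(features[[id]], features_to_shuffle,
                                  seed = derive_seed(seed, id))
  }
  out
}

#' Prediction-accuracy difference between full and reduced models
#'
#' @param full,reduced `accuracy_table` objects with matching dimensions.
#' @return object of class `delta_r`: `dr` (subjects x melodies x channels,
#'   `full$r - reduced$r`), plus the two model tags.
#' @export
delta_r <- function(full, reduced) {
  if (!identical(dim(full$r), dim(reduced$r))) {
    stop_alignment("accuracy tables have different dimensions")
  }
  structure(
    list(dr = full$r - reduced$r, full_tag = full$model_tag,
         reduced_tag = reduced$model_tag, melody_ids = full$melody_ids,
         channel_names = full$channel_names),
    class = "delta_r"
  )
}

#' Select the top-accuracy region of interest per subject
#'
#' Channels are ranked per subject by full-model accuracy averaged over all
#' melodies (both conditions pooled), and the top `fraction` are returned.
#' The ROI therefore depends only on the full model, never on condition or
#' regressor set. Ties break by channel order.
#'
#' @param full an `accuracy_table` for the full model.
#' @param fraction fraction of channels to keep (default 0.25).
#' @return list (one element per subject) of channel index vectors.
#' @export
select_roi <- function(full, fraction = 0.25) {
  if (fraction <= 0 || fraction > 1) stop_config("fraction must be in (0, 1]")
  n_ch <- dim(full$r)[3]
  k <- ceiling(fraction * n_ch)
  lapply(seq_len(dim(full$r)[1]), function(s) {
    m <- apply(full$r[s, , , drop = FALSE], 3L, mean)
    order(-m, seq_len(n_ch))[seq_len(k)]
  })
}

#' Tidy per-subject delta-r table over ROI channels
#'
#' @param dr a `delta_r` object.
#' @param roi per-subject channel indices from [select_roi()].
#' @param conditions named character vector mapping melody id to condition.
#' @param model label for the reduced model.
#' @return long data frame: subject, melody, condition, model, dr (averaged
#'   over the subject's ROI channels).
#' @export
delta_r_table <- function(dr, roi, conditions, model = dr$reduced_tag) {
  ns <- dim(dr$dr)[1]
  rows <- list()
  for (s in seq_len(ns)) {
    for (mi in seq_along(dr$melody_ids)) {
      id <- dr$melody_ids[mi]
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sprintf("S%02d", s), melody = id,
        condition = conditions[[id]], model = model,
        dr = mean(dr$dr[s, mi, roi[[s]]])
      )
    }
  }
  do.call(rbind, rows)
}

#' Group-level statistics on delta-r tables
#'
#' Combines (i) paired Wilcoxon signed-rank contrasts on per-subject means
#' and (ii) a linear mixed model `dr ~ Condition * Model` with random
#' intercepts for subject and melody, tested by likelihood-ratio chi-square
#' on nested fits, with Tukey-adjusted follow-up contrasts (emmeans).
#'
#' @param tab long data frame from [delta_r_table()] (possibly several
#'   models row-bound together): columns subject, melody, condition, model,
#'   dr.
#' @return list of class `group_stats`: `wilcoxon` (data frame of paired
#'   and one-sample W tests), `lrt` (chi-square tests for Condition, Model,
#'   and their interaction), `tukey` (emmeans pairwise contrasts), `n_subjects`.
#' @export
group_stats <- function(tab) {
  tab$condition <- factor(tab$condition)
  tab$model <- factor(tab$model)
  n_sub <- length(unique(tab$subject))
  if (n_sub < 5L) warn_power("fewer than 5 subjects; group tests underpowered")
  subj_mean <- function(cond = NULL, model = NULL) {
    x <- tab
    if (!is.null(cond)) x <- x[x$condition == cond, ]
    if (!is.null(model)) x <- x[x$model == model, ]
    tapply(x$dr, x$subject, mean)
  }
  wx <- list()
  safe_wilcox <- function(x, y = NULL, ...) {
    d <- if (is.null(y)) x else x - y
    if (all(d == 0)) {
      return(list(statistic = c(W = 0), p.value = 1))
    }
    if (is.null(y)) {
      stats::wilcox.test(x, ..., exact = FALSE)
    } else {
      stats::wilcox.test(x, y, paired = TRUE, ..., exact = FALSE)
    }
  }
  add_wx <- function(label, test) {
    wx[[length(wx) + 1L]] <<- data.frame(
      contrast = label, W = unname(test$statistic), p = test$p.value
    )
  }
  for (md in levels(tab$model)) {
    for (cd in levels(tab$condition)) {
      v <- subj_mean(cd, md)
      add_wx(sprintf("%s|%s > 0", md, cd),
             safe_wilcox(v, alternative = "greater"))
    }
    if (nlevels(tab$condition) == 2L) {
      a <- subj_mean(levels(tab$condition)[1L], md)
      b <- subj_mean(levels(tab$condition)[2L], md)
      common <- intersect(names(a), names(b))
      add_wx(sprintf("%s: %s vs %s", md, levels(tab$condition)[1L],
                     levels(tab$condition)[2L]),
             safe_wilcox(a[common], b[common]))
    }
  }
  wilcoxon <- do.call(rbind, wx)
  two_models <- nlevels(tab$model) >= 2L
  two_conds <- nlevels(tab$condition) >= 2L
  # random-effects structure adapts to what the data can identify
  re <- paste(c(
    if (length(unique(tab$subject)) > 1L) "(1 | subject)",
    if (length(unique(tab$melody)) > 1L) "(1 | melody)"
  ), collapse = " + ")
  ctl <- lme4::lmerControl(check.conv.singular = "ignore",
                           calc.derivs = FALSE)
  fit <- function(rhs) {
    fml <- stats::as.formula(paste("dr ~", rhs, "+", re))
    suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = tab, REML = FALSE, control = ctl)
    ))
  }
  lrt_row <- function(term, full, null) {
    a <- suppressMessages(stats::anova(null, full))
    data.frame(term = term, chisq = a$Chisq[2], df = a$Df[2],
               p = a$`Pr(>Chisq)`[2])
  }
  safe_tukey <- function(model, spec) {
    tryCatch(
      as.data.frame(emmeans::contrast(
        suppressMessages(emmeans::emmeans(model, spec)),
        method = "pairwise", adjust = "tukey"
      )),
      error = function(e) NULL
    )
  }
  lrt <- NULL
  tukey <- NULL
  if (two_models && two_conds && nzchar(re)) {
    m_full <- fit("condition * model")
    m_nomodint <- fit("condition + model")
    m_nocond <- fit("model")
    m_nomod <- fit("condition")
    lrt <- rbind(
      lrt_row("condition", m_nomodint, m_nomod),
      lrt_row("model", m_nomodint, m_nocond),
      lrt_row("condition:model", m_full, m_nomodint)
    )
    tukey <- safe_tukey(m_full, ~ model | condition)
  } else if (two_conds && nzchar(re)) {
    m_full <- fit("condition")
    m_null <- fit("1")
    lrt <- lrt_row("condition", m_full, m_null)
    tukey <- safe_tukey(m_full, ~condition)
  }
  structure(
    list(wilcoxon = wilcoxon, lrt = lrt, tukey = tukey, n_subjects = n_sub),
    class = "group_stats"
  )
}

#' @export
print.group_stats <- function(x, ...) {
  cat("Group-level delta-r statistics (", x$n_subjects, "subjects )\n")
  cat("\nWilcoxon signed-rank:\n")
  print(x$wilcoxon, row.names = FALSE)
  cat("\nLikelihood-ratio tests (mixed model):\n")
  print(x$lrt, row.names = FALSE)
  cat("\nTukey-adjusted contrasts:\n")
  print(x$tukey, row.names = FALSE)
  invisible(x)
}
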