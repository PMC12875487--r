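# Orchestration: a run configuration with the analysis defaults, a one-call
# synthetic study generator, and the end-to-end pipeline that turns a study
# into tidy result tables (information estimates, TRF accuracies, variance
# partitioning, ERP cluster statistics).

#' Run configuration with analysis defaults
#'
#' Collects every tunable of the pipeline with defaults matching the
#' reference analysis: 1-30 Hz zero-phase Butterworth, 100 Hz, lag window
#' -50..400 ms, ridge grid 1e-4..1e8 by decades, 25% ROI, 20% surprise
#' quantiles, 1000 permutations.
#'
#' @param ... overrides for any default field.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # fixture
    n_real = 10L, n_shuffled = 4L, n_subjects = 20L, n_notes = 60L,
    n_channels = 64L, snr = 1, temperature = 0.35,
    use_acoustic = TRUE, n_bands = 16L, audio_sr = 16000,
    active_real = c("onset", "ioi", "St", "Et"),
    active_shuffled = c("onset", "ioi"),
    # infodyn
    folds = 10L, max_order = 10L, bias = 2,
    # preprocessing
    bp_low = 1, bp_high = 30, fs = 100, bad_z = 2.75, interp_radius_mm = 18,
    ref_labels = c("F9", "F10", "P9", "P10", "Iz"),
    # TRF / variance partitioning
    t_min_ms = -50, t_max_ms = 400, lambdas = 10^seq(-4, 8),
    roi_fraction = 0.25, reselect_lambda = FALSE, n_randomizations = 1L,
    reduced_models = c("highlevel", "timing", "pitch", "ioi", "ipi"),
    include_envelope = FALSE, include_ioi_next = FALSE,
    # ERP
    quantile = 0.20, n_perm = 1000L, reject_z = 2.5, min_neighbors = 3L,
    erp_dimension = "St",
    # output
    out_dir = NULL, figures = FALSE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop_config(paste("unknown config fields:", paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  structure(cfg, class = c("run_config", "list"))
}

#' Read or write a run configuration as YAML
#'
#' @param path file path.
#' @param cfg a [run_config()].
#' @return `read_run_config` returns a [run_config()]; the writer returns
#'   `path` invisibly. Configurations round-trip losslessly.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

feature_columns <- function(cfg) {
  c("onset",
    if (cfg$use_acoustic) "spectral_flux",
    "ioi", "ipi",
    if (cfg$include_ioi_next) "ioi_next",
    if (cfg$include_envelope) c("envelope", "env_derivative"),
    "Sp", "St", "Ep", "Et")
}

#' Generate a complete synthetic study
#'
#' Builds the whole fixture in one call: a structured corpus with shuffled
#' controls, information estimates, the per-melody regressor bank, and
#' multi-subject synthetic EEG in which (by default) acoustic onset, IOI
#' and the timing-information features drive responses to real melodies
#' while shuffled melodies evoke acoustic/IOI responses only.
#'
#' @param cfg a [run_config()].
#' @return list: `melodies` (named list), `conditions`, `info`, `features`
#'   (normalized per melody), `sim` (output of [generate_eeg()]), `layout`.
#' @export
make_fixture_study <- function(cfg = run_config()) {
  corpus <- make_study_corpus(
    n_structured = cfg$n_real, n_shuffled = cfg$n_shuffled,
    temperature = cfg$temperature, n_notes = cfg$n_notes,
    seed = derive_seed(cfg$seed, "corpus")
  )
  melodies <- c(corpus$melodies, corpus$shuffled)
  names(melodies) <- vapply(melodies, `[[`, "", "id")
  conditions <- vapply(melodies, `[[`, "", "condition")
  info <- estimate_information(melodies, folds = min(cfg$folds, length(melodies)),
                               max_order = cfg$max_order, bias = cfg$bias,
                               seed = derive_seed(cfg$seed, "infodyn"))
  features <- lapply(names(melodies), function(id) {
    m <- melodies[[id]]
    ev <- event_regressors(m, info[info$melody_id == id, ], fs = cfg$fs,
                           include_ioi_next = cfg$include_ioi_next)
    ac <- NULL
    if (cfg$use_acoustic || cfg$include_envelope) {
      ac <- acoustic_regressors(synthesize_audio(m, sr = cfg$audio_sr),
                                fs_out = cfg$fs, n_bands = cfg$n_bands)
    }
    combine_features(ev, ac, columns = feature_columns(cfg))
  })
  names(features) <- names(melodies)
  layout <- make_layout(cfg$n_channels)
  spec <- generative_spec(
    active_features = list(real = cfg$active_real,
                           shuffled = cfg$active_shuffled,
                           synthetic = cfg$active_real),
    snr = cfg$snr, n_subjects = cfg$n_subjects, layout = layout,
    t_min_ms = cfg$t_min_ms, t_max_ms = cfg$t_max_ms,
    seed = derive_seed(cfg$seed, "eeg")
  )
  sim <- generate_eeg(features, spec, conditions = conditions)
  list(melodies = melodies, conditions = conditions, info = info,
       features = features, sim = sim, layout = layout)
}

write_tsv <- function(x, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  utils::write.table(x, file.path(dir, name), sep = "\t", row.names = FALSE,
                     quote = FALSE)
}

#' Run the full analysis pipeline
#'
#' Stages: preprocess every recording, build the super-subject ground
#' truth, fit the full TRF model and every configured reduced model with
#' leave-one-melody-out cross-validation, compute delta-r tables over the
#' top-accuracy ROI, run the group statistics, and run the surprise-
#' quantile ERP contrast with cluster permutation. When `cfg$out_dir` is
#' set, tidy tables and a provenance log are written there.
#'
#' @param cfg a [run_config()].
#' @param study optional study list from [make_fixture_study()]; generated
#'   from `cfg` when omitted.
#' @return list with `accuracy` (per model), `delta` (long table),
#'   `stats_highlevel`, `stats_timing_pitch`, `stats_ioi_ipi`, `erp`
#'   (cluster results per condition), `roi`, `info_summary`, `study`.
#' @export
run_pipeline <- function(cfg = run_config(), study = NULL) {
  if (is.null(study)) study <- make_fixture_study(cfg)
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  info_summary <- summarize_information(study$info)
  write_tsv(study$info, out_dir, "information_estimates.tsv")
  write_tsv(info_summary, out_dir, "information_summary.tsv")

  # ---- preprocessing -------------------------------------------------------
  eeg <- lapply(study$sim$eeg, function(subj) {
    lapply(subj, function(rec) {
      preprocess_eeg(rec, low = cfg$bp_low, high = cfg$bp_high,
                     fs_out = cfg$fs, z = cfg$bad_z,
                     ref_labels = cfg$ref_labels,
                     radius_mm = cfg$interp_radius_mm)
    })
  })
  gt <- build_super_subject(eeg)

  # ---- TRF: full + reduced models -----------------------------------------
  window <- lag_window(cfg$t_min_ms, cfg$t_max_ms, cfg$fs)
  full <- trf_study(study$features, eeg, gt, lambdas = cfg$lambdas,
                    window = window, model_tag = "full")
  roi <- select_roi(full, cfg$roi_fraction)
  lam_fixed <- if (cfg$reselect_lambda) NULL else full$lambda
  accuracy <- list(full = full)
  delta_tabs <- list()
  for (mod in cfg$reduced_models) {
    feats_to_shuffle <- REDUCED_MODEL_SETS[[mod]]
    # one randomization by default; more are averaged on the accuracy scale
    reds <- lapply(seq_len(cfg$n_randomizations), function(k) {
      red_features <- reduce_features(
        study$features, feats_to_shuffle,
        seed = derive_seed(cfg$seed, paste0(mod, k))
      )
      trf_study(red_features, eeg, gt, lambdas = cfg$lambdas,
                window = window, lambda_fixed = lam_fixed,
                model_tag = paste0("reduced:", mod))
    })
    red <- reds[[1L]]
    if (length(reds) > 1L) {
      red$r <- Reduce(`+`, lapply(reds, `[[`, "r")) / length(reds)
    }
    accuracy[[mod]] <- red
    delta_tabs[[mod]] <- delta_r_table(delta_r(full, red), roi,
                                       study$conditions, model = mod)
  }
  delta <- do.call(rbind, delta_tabs)
  rownames(delta) <- NULL
  write_tsv(delta, out_dir, "delta_r.tsv")
  acc_long <- do.call(rbind, lapply(names(accuracy), function(tag) {
    a <- accuracy[[tag]]
    data.frame(model = tag,
               subject = sprintf("S%02d", seq_len(dim(a$r)[1])),
               mean_r = apply(a$r, 1L, mean), lambda = a$lambda)
  }))
  write_tsv(acc_long, out_dir, "accuracy.tsv")

  # ---- group statistics ----------------------------------------------------
  stats_highlevel <- if ("highlevel" %in% names(delta_tabs)) {
    group_stats(delta_tabs$highlevel)
  }
  stats_timing_pitch <- if (all(c("timing", "pitch") %in% names(delta_tabs))) {
    group_stats(rbind(delta_tabs$timing, delta_tabs$pitch))
  }
  stats_ioi_ipi <- if (all(c("ioi", "ipi") %in% names(delta_tabs))) {
    group_stats(rbind(delta_tabs$ioi, delta_tabs$ipi))
  }

  # ---- ERP: surprise-quantile contrast ------------------------------------
  adjacency <- channel_adjacency(study$layout, cfg$interp_radius_mm)
  erp_res <- list()
  for (cond in intersect(c("real", "shuffled"), unique(study$conditions))) {
    ids <- names(study$conditions)[study$conditions == cond]
    erps_hi <- NULL
    erps_lo <- NULL
    for (s in seq_along(eeg)) {
      sets <- lapply(ids, function(id) {
        epoch_melody(eeg[[s]][[id]], study$melodies[[id]])
      })
      es <- bind_epochs(sets)
      es <- reject_trials(es, cfg$reject_z)
      es <- quantile_split(es, study$info, dimension = cfg$erp_dimension,
                           q = cfg$quantile)
      hi <- subject_erp(es, quantile = "highS")
      lo <- subject_erp(es, quantile = "lowS")
      if (is.null(erps_hi)) {
        nt <- length(hi$times_ms)
        nc <- nrow(hi$erp)
        erps_hi <- array(0, c(length(eeg), nc, nt))
        erps_lo <- array(0, c(length(eeg), nc, nt))
        times_ms <- hi$times_ms
      }
      erps_hi[s, , ] <- hi$erp
      erps_lo[s, , ] <- lo$erp
    }
    erp_res[[cond]] <- cluster_permutation(
      erps_hi, erps_lo, adjacency, n_perm = cfg$n_perm,
      min_neighbors = cfg$min_neighbors, times_ms = times_ms,
      seed = derive_seed(cfg$seed, paste0("perm", cond))
    )
    if (!is.null(erp_res[[cond]]$clusters)) {
      write_tsv(erp_res[[cond]]$clusters, out_dir,
                sprintf("erp_clusters_%s.tsv", cond))
    }
  }

  # ---- provenance + reports -----------------------------------------------
  if (!is.null(out_dir)) {
    # hash the analysis settings, not the run-specific output location
    cfg_core <- cfg
    cfg_core$out_dir <- NULL
    tmp <- tempfile(fileext = ".yaml")
    yaml::write_yaml(unclass(cfg_core), tmp)
    report <- list(
      seed = cfg$seed,
      package_version = as.character(utils::packageVersion("musictrf")),
      config_md5 = unname(tools::md5sum(tmp)),
      n_subjects = length(eeg),
      n_melodies = length(study$melodies),
      lrt_highlevel = if (!is.null(stats_highlevel)) stats_highlevel$lrt,
      lrt_timing_pitch = if (!is.null(stats_timing_pitch)) {
        stats_timing_pitch$lrt
      },
      lrt_ioi_ipi = if (!is.null(stats_ioi_ipi)) stats_ioi_ipi$lrt
    )
    jsonlite::write_json(report, file.path(out_dir, "group_stats.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    write_run_config(cfg, file.path(out_dir, "config.yaml"))
    if (isTRUE(cfg$figures)) pipeline_figures(accuracy, delta, out_dir)
  }
  list(accuracy = accuracy, delta = delta, roi = roi,
       stats_highlevel = stats_highlevel,
       stats_timing_pitch = stats_timing_pitch,
       stats_ioi_ipi = stats_ioi_ipi, erp = erp_res,
       info_summary = info_summary, study = study, eeg = eeg,
       ground_truth = gt)
}

# Optional vector figures (requires ggplot2); every figure is backed by a
# table already on disk.
pipeline_figures <- function(accuracy, delta, out_dir) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) return(invisible(NULL))
  g <- ggplot2::ggplot(delta,
                       ggplot2::aes(x = model, y = dr, color = condition)) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_se,
                          position = ggplot2::position_dodge(0.4)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(y = "delta r (full - reduced)", x = "reduced model")
  ggplot2::ggsave(file.path(out_dir, "delta_r.pdf"), g, width = 6, height = 4)
  invisible(NULL)
}
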