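# End-to-end orchestration: simulate -> preprocess -> features -> JM ->
# LOSO train/diagnose -> evaluation report, with every artifact written to
# a run directory alongside the resolved configuration.

#' Pipeline run configuration
#'
#' Bundles the stage selection and the per-stage settings into one
#' serializable object. `load_run_config(save_run_config(cfg))` returns an
#' identical configuration.
#'
#' @param sim a [sim_config()].
#' @param filter a [filter_spec()].
#' @param fnn an [fnn_spec()].
#' @param feature_sets subset of `c("classic", "wavelet", "pac")`.
#' @param pac_phase_freqs,pac_amp_freqs PAC comodulogram grid.
#' @param pac_window_epochs epochs per PAC analysis window.
#' @param threshold amplitude threshold for the counting features.
#' @param prevalences prevalence values for the unbiased PPV report.
#' @param ci_level level for the metric confidence intervals.
#' @param prob_ci_level level for mean-probability and credible intervals.
#' @param seed global seed (splits, permutations).
#' @param out_dir run directory (created if missing).
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), filter = filter_spec(),
                       fnn = fnn_spec(),
                       feature_sets = c("classic", "wavelet", "pac"),
                       pac_phase_freqs = seq(2, 30, by = 2),
                       pac_amp_freqs = seq(30, 350, by = 10),
                       pac_window_epochs = 8, threshold = 0.01,
                       prevalences = c(0.01, 0.03), ci_level = 0.95,
                       prob_ci_level = 0.999, seed = 1L,
                       out_dir = tempfile("pacemg_run_")) {
  feature_sets <- match.arg(feature_sets, several.ok = TRUE)
  structure(list(sim = sim, filter = filter, fnn = fnn,
                 feature_sets = feature_sets,
                 pac_phase_freqs = as.numeric(pac_phase_freqs),
                 pac_amp_freqs = as.numeric(pac_amp_freqs),
                 pac_window_epochs = as.integer(pac_window_epochs),
                 threshold = threshold,
                 prevalences = as.numeric(prevalences),
                 ci_level = ci_level, prob_ci_level = prob_ci_level,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Save a run configuration as JSON
#'
#' @param cfg a [run_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass_deep(cfg), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Load a run configuration saved by [save_run_config()]
#'
#' @param path JSON path.
#' @return A [run_config()] identical to the saved one.
#' @export
load_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- do.call(sim_config, raw$sim[!names(raw$sim) %in% "duration_range"])
  sim$duration_range <- as.numeric(raw$sim$duration_range)
  filt <- filter_spec(raw$filter$band, raw$filter$order,
                      raw$filter$zero_phase)
  fnn <- do.call(fnn_spec, raw$fnn)
  run_config(sim = sim, filter = filt, fnn = fnn,
             feature_sets = raw$feature_sets,
             pac_phase_freqs = raw$pac_phase_freqs,
             pac_amp_freqs = raw$pac_amp_freqs,
             pac_window_epochs = raw$pac_window_epochs,
             threshold = raw$threshold, prevalences = raw$prevalences,
             ci_level = raw$ci_level, prob_ci_level = raw$prob_ci_level,
             seed = raw$seed, out_dir = raw$out_dir)
}

#' Extract feature tables from a cohort
#'
#' Applies the preprocessing chain (band-pass, bad-channel removal,
#' 500 ms epoching) to every recording and computes the requested feature
#' sets on the pooled epochs.
#'
#' @param cohort an `emg_cohort`.
#' @param cfg a [run_config()].
#' @param verbose print stage progress.
#' @return Named list of feature tables (subset of classic/wavelet/pac).
#' @export
cohort_features <- function(cohort, cfg = run_config(), verbose = FALSE) {
  sets <- list()
  epochs <- vector("list", length(cohort$recordings))
  for (i in seq_along(cohort$recordings)) {
    rec <- cohort$recordings[[i]]
    rec <- emg_bandpass(rec, cfg$filter)
    rec <- drop_bad_channels(rec)
    epochs[[i]] <- segment_epochs(rec)
  }
  pooled <- bind_epochs(epochs)
  if (verbose) message(sprintf("pooled %d epochs", nrow(pooled$x)))
  if ("classic" %in% cfg$feature_sets) {
    sets$classic <- classic_features(pooled, threshold = cfg$threshold)
    if (verbose) message("classic features done")
  }
  if ("wavelet" %in% cfg$feature_sets) {
    sets$wavelet <- wavelet_feature_table(pooled)
    if (verbose) message("wavelet features done")
  }
  if ("pac" %in% cfg$feature_sets) {
    sets$pac <- pac_features(pooled, cfg$pac_phase_freqs, cfg$pac_amp_freqs,
                             window_epochs = cfg$pac_window_epochs)
    if (verbose) message("pac features done")
  }
  sets
}

#' Run the complete pipeline
#'
#' Simulate -> preprocess -> features -> JM separability -> LOSO
#' train/diagnose -> evaluation report. All artifacts (manifest, feature
#' tables, JM table, per-subject diagnoses, metrics report, resolved
#' config) are written under `cfg$out_dir`.
#'
#' @param cfg a [run_config()].
#' @param verbose print stage progress.
#' @return List with `manifest`, `features`, `jm`, `runs`, `metrics`,
#'   `out_dir` (invisibly returns the same).
#' @export
run_pipeline <- function(cfg = run_config(), verbose = FALSE) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  save_run_config(cfg, file.path(cfg$out_dir, "config.json"))
  cohort <- simulate_cohort(cfg$sim)
  write_manifest(cohort, file.path(cfg$out_dir, "manifest.json"))
  if (verbose) message("cohort simulated")
  sets <- cohort_features(cohort, cfg, verbose)
  for (nm in names(sets))
    write_feature_table(sets[[nm]],
                        file.path(cfg$out_dir, sprintf("features_%s.csv", nm)))
  # JM separability per LOSO dataset (training rows), one row per dataset
  jm_rows <- list()
  runs <- list()
  metrics <- list()
  for (nm in names(sets)) {
    tab <- sets[[nm]]
    ds <- make_loso_datasets(tab, seed = cfg$seed)
    jm_rows[[nm]] <- vapply(ds, function(d)
      featureset_jm(tab, rows = d$idx_train)$jm_aggregate, 1)
    run <- run_loso(tab, spec = cfg$fnn, seed = cfg$seed, verbose = verbose)
    runs[[nm]] <- run
    cm <- confusion_metrics(run$confusion)
    n_case <- run$confusion$TP + run$confusion$FN
    n_ctrl <- run$confusion$TN + run$confusion$FP
    d <- dor(cm$Se, cm$Sp)
    metrics[[nm]] <- list(
      Se = cm$Se * 100, Sp = cm$Sp * 100, Acc = cm$Acc * 100,
      Se_ci = wald_ci(run$confusion$TP, n_case, cfg$ci_level),
      Sp_ci = wald_ci(run$confusion$TN, n_ctrl, cfg$ci_level),
      Acc_ci = wald_ci(run$confusion$TP + run$confusion$TN,
                       run$confusion$N, cfg$ci_level),
      DOR = d$dor, DOR_infinite = d$infinite,
      unbiased_PPV = setNames(
        vapply(cfg$prevalences, function(p)
          unbiased_ppv(cm$Se, cm$Sp, p) * 100, 1),
        paste0("prev_", cfg$prevalences)),
      subject_mean_prob_ci = lapply(run$results, function(r)
        mean_prob_ci(r$epoch_probs, cfg$prob_ci_level)),
      subject_credible_interval = lapply(run$results, function(r)
        beta_credible_interval(sum(r$epoch_probs >= 0.5),
                               length(r$epoch_probs),
                               level = cfg$prob_ci_level)))
    jsonlite::write_json(
      list(feature_set = nm, summary = run$summary,
           confusion = unclass(run$confusion)),
      file.path(cfg$out_dir, sprintf("diagnosis_%s.json", nm)),
      dataframe = "rows", digits = NA, auto_unbox = TRUE)
    if (verbose) message(sprintf("%s: subject accuracy %.3f", nm,
                                 run$subject_accuracy))
  }
  jm_tab <- as.data.frame(jm_rows)
  utils::write.csv(jm_tab, file.path(cfg$out_dir, "jm.csv"),
                   row.names = FALSE)
  # cross-feature-set statistics where more than one set was computed
  stats <- list()
  if (ncol(jm_tab) >= 2 && nrow(jm_tab) >= 2)
    stats$friedman <- friedman_rank_test(as.matrix(jm_tab))
  jsonlite::write_json(list(metrics = metrics, stats = stats),
                       file.path(cfg$out_dir, "metrics.json"),
                       digits = NA, auto_unbox = TRUE, null = "null",
                       force = TRUE)
  out <- list(manifest = cohort$manifest, features = sets, jm = jm_tab,
              runs = runs, metrics = metrics, out_dir = cfg$out_dir)
  invisible(out)
}
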