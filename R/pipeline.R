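#' Configuration for an end-to-end simulated experiment
#'
#' Bundles the design, per-condition knowledge parameters, EEG synthesis
#' and TMR settings, and the master seed. For sleep conditions the
#' transfer-structure knowledge of each participant is modulated by the
#' dose of congruent ("transfer") cues delivered during the nap:
#' the core-knowledge log-odds shift is
#' `cue_boost * (n_transfer_cues - ref_cues)`, so more reactivation of the
#' congruent category produces better transfer, anchored at the
#' condition's nominal parameters for a typical cue count.
#'
#' @param design design name or `experiment_design` (default `"exp2"`).
#' @param params per-condition `knowledge_params`.
#' @param nap_minutes nap opportunity for sleep conditions (default 120;
#'   scale down for quick runs).
#' @param synth a `synth_params` for EEG generation.
#' @param tmr a `tmr_config`.
#' @param cue_boost log-odds of core knowledge added per transfer cue
#'   (default 0.017).
#' @param ref_cues reference transfer-cue count at which the condition's
#'   nominal parameters apply. Default `NULL` uses `0.33 * nap_minutes`,
#'   the typical target-cue dose per nap minute under the default
#'   synthesis, TMR and sleep-depth-variability parameters (about 40
#'   cues for a 2-h nap), so the anchor tracks the nap length.
#' @param wake_bias_max per-participant sleep-depth variability: each
#'   sleep participant's wake bias is drawn uniformly from
#'   `[0, wake_bias_max]` (see [nap_profile()]; default 0.3).
#' @param eeg simulate EEG + TMR for sleep conditions? (default TRUE)
#' @param n_eeg_analysis how many sleep participants get the full
#'   cue-locked TFR/cluster analysis (default 8; it is the slowest stage).
#' @param evoked_amplitude amplitude (microvolts) of the theta-band
#'   sound-evoked burst injected after played cues, so target-vs-sham
#'   contrasts carry a detectable effect (0 disables).
#' @param master_seed master RNG seed.
#' @param output_dir optional directory for the results bundle.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(design = "exp2",
                              params = NULL,
                              nap_minutes = 120,
                              synth = synth_params(),
                              tmr = tmr_config(),
                              cue_boost = 0.017,
                              ref_cues = NULL,
                              wake_bias_max = 0.3,
                              eeg = TRUE,
                              n_eeg_analysis = 8,
                              evoked_amplitude = 8,
                              master_seed = 1,
                              output_dir = NULL) {
  if (!inherits(design, "experiment_design"))
    design <- experiment_design(design)
  params <- params %||% default_condition_params(design)
  ref_cues <- ref_cues %||% (0.33 * nap_minutes)
  structure(list(design = design, params = params,
                 nap_minutes = nap_minutes, synth = synth, tmr = tmr,
                 cue_boost = cue_boost, ref_cues = ref_cues,
                 wake_bias_max = wake_bias_max, eeg = eeg,
                 n_eeg_analysis = n_eeg_analysis,
                 evoked_amplitude = evoked_amplitude,
                 master_seed = master_seed, output_dir = output_dir),
            class = "experiment_config")
}

# inject a short theta burst after each played (non-sham) cue, emulating
# the sound-evoked power increase
inject_evoked <- function(record, log, amplitude, f0 = 6,
                          window = c(0.3, 1.0)) {
  if (amplitude <= 0) return(record)
  fs <- record$srate
  onsets <- log$onset[log$kind %in% c("target", "control")]
  dur <- window[2] - window[1]
  w <- spindle_waveform(fs, f0, dur, amplitude)
  for (on in onsets) {
    i0 <- floor((on + window[1]) * fs) + 1L
    idx <- i0:(i0 + length(w) - 1L)
    idx <- idx[idx <= nrow(record$signals)]
    record$signals[idx, "Fz"] <- record$signals[idx, "Fz"] + w[seq_along(idx)]
    record$signals[idx, "Cz"] <- record$signals[idx, "Cz"] +
      0.8 * w[seq_along(idx)]
  }
  record
}

#' Run an end-to-end simulated experiment
#'
#' Executes the full pipeline for the configured design: simulate sleep
#' EEG and closed-loop TMR cueing for sleep-condition participants,
#' modulate their transfer knowledge by delivered cue dose, generate the
#' behavioral cohort, score all tasks, and fit the structure-match and
#' condition-comparison analyses. All randomness derives from
#' `master_seed`, so identical configs give identical bundles.
#'
#' @param cfg an `experiment_config`.
#' @return A `results_bundle` list: `cohort`, `sleep` (per-participant
#'   sleep/cue table or NULL), `scores` (per-participant data.frame),
#'   `analyses` (selection / arrangement-beta / transfer-accuracy
#'   condition models, per-condition group structure tests, cue-dose
#'   models), `eeg` (cluster analysis of target-vs-sham TFR contrasts, if
#'   run), `config`, `manifest` (when written to disk).
#' @export
run_experiment <- function(cfg = experiment_config()) {
  stopifnot(inherits(cfg, "experiment_config"))
  design <- cfg$design
  conds <- design$conditions
  n_total <- sum(conds$n)
  condition <- rep(conds$condition, conds$n)
  sleep_flag <- rep(conds$sleep, conds$n)

  sleep_tab <- NULL
  params_by_participant <- NULL
  tfr_contrasts <- list()
  cue_logs <- list()

  if (cfg$eeg && any(sleep_flag)) {
    idx_sleep <- which(sleep_flag)
    rows <- list()
    params_by_participant <- vector("list", n_total)
    n_eeg_done <- 0L
    for (i in idx_sleep) {
      sd_i <- child_seed(cfg$master_seed, 5000 + i)
      # participants differ in sleep depth: restless sleepers get fewer cues
      set.seed(child_seed(sd_i, 4))
      wb <- runif(1, 0, cfg$wake_bias_max)
      h <- generate_hypnogram(cfg$nap_minutes, profile = nap_profile(wb),
                              seed = sd_i)
      sp <- cfg$synth
      sp$seed <- child_seed(sd_i, 1)
      rec <- synthesize_eeg(h, sp)
      log <- run_tmr(rec, h, cfg$tmr)
      counts <- tally_cues_by_stage(log, h)
      congruent <- grepl("congruent$", condition[i]) &&
        !grepl("incongruent$", condition[i])
      n_target <- sum(counts["target", ])
      n_transfer <- if (congruent) n_target else 0L
      kp <- cfg$params[[condition[i]]]
      kp$p_core <- plogis(qlogis(kp$p_core) +
                            cfg$cue_boost * (n_transfer - cfg$ref_cues))
      params_by_participant[[i]] <- kp
      rows[[length(rows) + 1L]] <- data.frame(
        index = i, condition = condition[i],
        total_sleep_min = total_sleep_time(h),
        n2_min = stage_minutes(h)[["N2"]], n3_min = stage_minutes(h)[["N3"]],
        n_target = n_target, n_control = sum(counts["control", ]),
        n_sham = sum(counts["sham", ]),
        n_target_n2 = counts["target", "N2"],
        n_target_n3 = counts["target", "N3"],
        n_transfer = n_transfer)
      cue_logs[[as.character(i)]] <- log
      if (n_eeg_done < cfg$n_eeg_analysis &&
          sum(log$kind == "target") >= 5 && sum(log$kind == "sham") >= 5) {
        rec2 <- inject_evoked(rec, log, cfg$evoked_amplitude)
        pre <- preprocess(rec2)
        eps <- epoch_around_cues(pre, log)
        if (!is.null(eps$target) && !is.null(eps$sham) &&
            eps$target$kept >= 3 && eps$sham$kept >= 3) {
          tfr_t <- morlet_tfr(eps$target)
          tfr_s <- morlet_tfr(eps$sham)
          tfr_contrasts[[length(tfr_contrasts) + 1L]] <-
            tfr_t$power - tfr_s$power
          n_eeg_done <- n_eeg_done + 1L
        }
      }
    }
    sleep_tab <- do.call(rbind, rows)
  }

  cohort <- generate_cohort(design, cfg$params,
                            master_seed = cfg$master_seed,
                            params_by_participant = params_by_participant)
  p <- cohort$participants
  sel_acc <- vapply(cohort$selection, selection_accuracy, 0, core_ids = 0:2)
  rdms <- lapply(cohort$arrangement, rdm_from_coords)
  betas <- vapply(seq_len(n_total), function(i)
    participant_structure_regression(rdms[[i]], cohort$true_transfer,
                                     cohort$visual)$beta_structure, 0)
  scores <- data.frame(id = p$id, condition = p$condition,
                       excluded = p$excluded,
                       phase1_accuracy = cohort$phase1_accuracy,
                       transfer_accuracy = cohort$transfer_accuracy,
                       selection_accuracy = sel_acc,
                       selection_k = round(sel_acc * 3),
                       beta_structure = betas)

  inc <- !scores$excluded
  baseline <- design$baseline
  analyses <- list()
  analyses$selection <- condition_model(
    scores$selection_k[inc], scores$condition[inc], baseline, "logistic")
  analyses$arrangement <- condition_model(
    scores$beta_structure[inc], scores$condition[inc], baseline, "linear")
  analyses$transfer_mf <- condition_model(
    scores$transfer_accuracy[inc], scores$condition[inc], baseline,
    "linear",
    covariates = data.frame(phase1 = scores$phase1_accuracy[inc]))
  analyses$group_structure <- lapply(
    setNames(conds$condition, conds$condition), function(cc) {
      sel <- inc & scores$condition == cc
      if (sum(sel) < 2) return(NULL)  # too few participants to aggregate
      group_structure_test(rdms[sel], cohort$true_transfer,
                           seed = child_seed(cfg$master_seed, 777))
    })

  if (!is.null(sleep_tab)) {
    st <- sleep_tab
    st$selection_k <- scores$selection_k[st$index]
    st$excluded <- scores$excluded[st$index]
    stk <- st[!st$excluded, ]
    analyses$cue_dose <- glm(
      cbind(selection_k, 3 - selection_k) ~ n_transfer + total_sleep_min,
      family = binomial(), data = stk)
    analyses$cue_dose_stage <- glm(
      cbind(selection_k, 3 - selection_k) ~ n_target_n2 + n_target_n3 +
        total_sleep_min,
      family = binomial(), data = stk)
  }

  eeg_res <- NULL
  if (length(tfr_contrasts) >= 2) {
    freqs <- seq(4, 30, by = 0.5)
    eeg_res <- cluster_permutation(tfr_contrasts, n_perm = 500,
                                   seed = child_seed(cfg$master_seed, 888),
                                   freqs = freqs,
                                   times = seq(-3, 3, by = 0.005))
  }

  bundle <- structure(list(cohort = cohort, sleep = sleep_tab,
                           scores = scores, analyses = analyses,
                           eeg = eeg_res, cue_logs = cue_logs,
                           config = cfg, manifest = NULL),
                      class = "results_bundle")
  if (!is.null(cfg$output_dir)) bundle <- write_bundle(bundle, cfg$output_dir)
  bundle
}

#' @export
print.results_bundle <- function(x, ...) {
  cat(sprintf("results_bundle: design %s, %d participants, seed %d\n",
              x$config$design$name, nrow(x$scores), x$config$master_seed))
  agg <- aggregate(selection_accuracy ~ condition, x$scores, mean)
  print(agg)
  invisible(x)
}

#' Write / read an experiment config as YAML
#'
#' Serializes the scalar fields of an `experiment_config` (design name,
#' per-condition knowledge parameters, synthesis, TMR and pipeline
#' settings) so runs can be declared in a config file.
#'
#' @param cfg an `experiment_config`.
#' @param path YAML file path.
#' @export
write_config_yaml <- function(cfg, path) {
  obj <- list(schema = "tmrstruct/config/v1",
              design = cfg$design$name,
              params = lapply(cfg$params, unclass),
              nap_minutes = cfg$nap_minutes,
              synth = unclass(cfg$synth),
              tmr = unclass(cfg$tmr),
              cue_boost = cfg$cue_boost, ref_cues = cfg$ref_cues,
              wake_bias_max = cfg$wake_bias_max,
              eeg = cfg$eeg, n_eeg_analysis = cfg$n_eeg_analysis,
              evoked_amplitude = cfg$evoked_amplitude,
              master_seed = cfg$master_seed)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!identical(obj$schema, "tmrstruct/config/v1"))
    stop("schema mismatch: not a tmrstruct/config/v1 file")
  experiment_config(
    design = obj$design,
    params = lapply(obj$params, function(p) do.call(knowledge_params, p)),
    nap_minutes = obj$nap_minutes,
    synth = do.call(synth_params, obj$synth[setdiff(names(obj$synth),
                                                    character(0))]),
    tmr = do.call(tmr_config, obj$tmr),
    cue_boost = obj$cue_boost, ref_cues = obj$ref_cues,
    wake_bias_max = obj$wake_bias_max,
    eeg = obj$eeg, n_eeg_analysis = obj$n_eeg_analysis,
    evoked_amplitude = obj$evoked_amplitude,
    master_seed = obj$master_seed)
}

#' Write a results bundle to disk with a hashed manifest
#'
#' Writes the cohort tables, scores, sleep/cue table, cue logs, analysis
#' summaries and config (JSON/CSV) under `dir`, plus `manifest.json`
#' listing every file with its MD5 hash, the master seed, and the config
#' hash.
#'
#' @param bundle a `results_bundle`.
#' @param dir output directory.
#' @return The bundle with its `manifest` slot filled.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_csv(bundle$cohort, dir)
  write.csv(bundle$scores, file.path(dir, "scores.csv"), row.names = FALSE)
  if (!is.null(bundle$sleep))
    write.csv(bundle$sleep, file.path(dir, "sleep.csv"), row.names = FALSE)
  for (nm in names(bundle$cue_logs))
    write_cue_log(bundle$cue_logs[[nm]],
                  file.path(dir, sprintf("cue_log_p%s.csv", nm)),
                  summary_json = FALSE)
  summarize_cm <- function(cm) list(
    coefficients = as.data.frame(cm$coefficients),
    model_test = cm$model_test)
  res <- list(
    schema = "tmrstruct/results/v1",
    selection_model = summarize_cm(bundle$analyses$selection),
    arrangement_model = summarize_cm(bundle$analyses$arrangement),
    group_structure = lapply(bundle$analyses$group_structure, function(g) {
      if (is.null(g)) return(NULL)
      list(group_r = g$group_r, null_threshold = g$null_threshold,
           bootstrap_ci = g$bootstrap_ci, significant = g$significant)
    }))
  jsonlite::write_json(res, file.path(dir, "analyses.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg_json <- file.path(dir, "config.json")
  cfg_small <- bundle$config
  cfg_small$design <- cfg_small$design$name
  cfg_small$output_dir <- NULL
  jsonlite::write_json(lapply(cfg_small, function(x)
    if (is.function(x)) NULL else x), cfg_json, auto_unbox = TRUE,
    force = TRUE, digits = NA)
  files <- setdiff(list.files(dir, full.names = TRUE), file.path(dir, "manifest.json"))
  manifest <- list(schema = "tmrstruct/manifest/v1",
                   master_seed = bundle$config$master_seed,
                   config_hash = unname(tools::md5sum(cfg_json)),
                   files = data.frame(
                     file = basename(files),
                     md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  bundle$manifest <- manifest
  bundle
}
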