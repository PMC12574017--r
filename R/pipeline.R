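#' Default pipeline configuration
#'
#' All tunable parameters of the simulation/decoding pipeline with their
#' defaults: the three speed presets and 20 trials per movement per session,
#' the 300-ms/30-Hz MAV front end, the 0.2 MKF threshold, the C-LSTM
#' hyperparameters, and the 7-condition x 2-algorithm x 6-fold offline
#' design.
#'
#' @return nested named list of class `emgdecode_config`.
#' @export
default_config <- function() {
  cfg <- list(
    seed = 1L,
    generator = list(
      n_channels = 32L, fs_emg = 1000, fs_kin = 30,
      baseline_noise_sd = 0.22, position_gain = 0.45, velocity_gain = 0.35,
      cocontraction_gain = 1.0, cc_trial_sd = 0.4,
      tracking_error_scale = 0, baseline_drift_sd = 0,
      line_amp = 0.15, trial_gain_sd = 0.15
    ),
    session = list(
      trials_per_movement = 20L, rest_s = 2
    ),
    preprocessing = list(
      hp_order = 6L, hp_cut = 15, lp_order = 2L, lp_cut = 375,
      notch_freqs = c(60, 120, 180), notch_q = 30,
      window_s = 0.3, rate_hz = 30
    ),
    kalman = list(
      mkf_threshold = 0.2, mkf_rescale = TRUE, steady_state = FALSE
    ),
    clstm = list(
      window_len = 10L, conv1_filters = 10L, conv1_kernel = 32L,
      conv1_stride = 1L, conv2_filters = 10L, conv2_kernel = 16L,
      conv2_stride = 4L, lstm_hidden = 40L, fc_sizes = 64L,
      lr = 2e-4, momentum = 0.9, max_epochs = 1000L, patience = 5L,
      batch_size = 64L, window_stride = 1L
    ),
    experiment = list(
      n_participants = 8L, mixing_jitter_sd = 0.15,
      n_folds = 6L, n_train = 12L, n_val = 2L,
      trials_per_condition = 12L, fold_mode = "subsample",
      algorithms = c("kf", "clstm"),
      conditions = c("S", "M", "F", "S+M", "S+F", "M+F", "All"),
      test_speeds = c("slow", "medium", "fast"),
      metrics = c("intended_rmse", "unintended_rmse", "windowed_rmse", "lmaj"),
      alpha = 0.05
    )
  )
  class(cfg) <- "emgdecode_config"
  cfg
}

validate_against <- function(user, defaults, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      stop("unknown configuration key: ", full)
    }
    d <- defaults[[key]]
    u <- user[[key]]
    if (is.list(d) && !is.list(u)) stop("configuration key ", full,
                                        " must be a section")
    if (is.list(d)) {
      validate_against(u, d, full)
    } else if (is.numeric(d) && !is.numeric(u)) {
      stop("configuration key ", full, " must be numeric")
    } else if (is.character(d) && !is.character(u)) {
      stop("configuration key ", full, " must be character")
    }
  }
  invisible(TRUE)
}

merge_config <- function(user, defaults) {
  for (key in names(user)) {
    defaults[[key]] <- if (is.list(defaults[[key]]) && is.list(user[[key]])) {
      merge_config(user[[key]], defaults[[key]])
    } else user[[key]]
  }
  defaults
}

#' Load and validate a YAML pipeline configuration
#'
#' Fills unspecified keys with the [default_config()] values, type-checks
#' the provided ones and rejects unknown keys by name. An empty file yields
#' the full defaults.
#'
#' @param path YAML file path.
#' @return validated `emgdecode_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- default_config()
  validate_against(user, unclass(defaults))
  cfg <- merge_config(user, unclass(defaults))
  class(cfg) <- "emgdecode_config"
  cfg
}

#' Write a configuration to YAML
#'
#' @param cfg an `emgdecode_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a feature series as CSV with a JSON channel-map sidecar
#'
#' Columns `t`, `f_0001` ... `f_0528`; the sidecar (`<path>.json`) records
#' the fixed feature ordering (single-ended channels first, then channel
#' pairs in lexicographic order) plus the frame rate and window.
#'
#' @param features a `feature_series`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_series <- function(features, path) {
  stopifnot(inherits(features, "feature_series"))
  df <- data.frame(t = features$t, features$f)
  names(df) <- c("t", sprintf("f_%04d", seq_len(ncol(features$f))))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(rate_hz = features$rate_hz, window_s = features$window_s,
         channel_map = features$channel_map),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a raw recording as a plain-text container
#'
#' Writes a directory mirroring the container layout used for raw signals:
#' `emg.csv` (t plus one column per channel), `kinematics.csv` (t plus the
#' three DOF positions), `labels.csv` (per-frame active_dof, phase,
#' trial_id) and `attributes.json` (fs_emg, fs_kin, seed, speed).
#'
#' @param rec an `emg_recording` with its generating kinematics attached.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_recording_csv <- function(rec, dir) {
  stopifnot(inherits(rec, "emg_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  emg <- data.frame(t = rec$t, rec$v)
  names(emg) <- c("t", sprintf("ch_%02d", seq_len(ncol(rec$v))))
  utils::write.csv(emg, file.path(dir, "emg.csv"), row.names = FALSE)
  kin <- rec$kin
  kdf <- data.frame(t = kin$t, kin$x)
  names(kdf) <- c("t", paste0("dof_", 1:3))
  utils::write.csv(kdf, file.path(dir, "kinematics.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(t = kin$t, active_dof = kin$active_dof, phase = kin$phase,
               trial_id = kin$trial_id),
    file.path(dir, "labels.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(fs_emg = rec$fs, fs_kin = kin$fs, seed = rec$seed_used,
         speed = kin$speed),
    file.path(dir, "attributes.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Save and load fitted decoders
#'
#' A `kalman_model` or `clstm_model` is serialized to an RDS file with a
#' JSON sidecar (`<path>.json`) describing its type, dimensions and (for
#' the C-LSTM) the full architecture configuration, so a saved model is
#' inspectable without loading it.
#'
#' @param model a `kalman_model` or `clstm_model`.
#' @param path output file path.
#' @return `path`, invisibly (for `save_decoder`); the model (for
#'   `load_decoder`).
#' @export
save_decoder <- function(model, path) {
  meta <- if (inherits(model, "kalman_model")) {
    list(type = "kalman", d = model$d, p = model$p,
         ridge_lambda = model$ridge_lambda)
  } else if (inherits(model, "clstm_model")) {
    list(type = "clstm", config = unclass(model$cfg),
         trained = isTRUE(model$trained))
  } else stop("not a kalman_model or clstm_model")
  saveRDS(model, path)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_decoder
#' @export
load_decoder <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, c("kalman_model", "clstm_model"))) {
    stop("file does not contain a saved decoder")
  }
  model
}

#' Write an outcome grid as tidy CSV
#'
#' Long format with columns participant, algorithm, train_condition,
#' test_speed, metric, value.
#'
#' @param cells data.frame of grid cells (with a `participant` column).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_outcome_csv <- function(cells, path) {
  out <- data.frame(participant = cells$participant,
                    algorithm = cells$algorithm,
                    train_condition = cells$condition,
                    test_speed = cells$test_speed %||% NA,
                    metric = cells$metric, value = cells$value)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Run the full offline pipeline
#'
#' Executes simulate -> preprocess -> train/decode -> evaluate -> stats for
#' `n_participants` synthetic participants and writes tidy CSV outputs plus
#' a JSON run manifest (config hash, master seed, per-stage checksums and
#' durations) under `out_dir`. Per-participant intermediates are cached on
#' disk and reused when re-running with an unchanged configuration, so only
#' stages downstream of a change are recomputed.
#'
#' @param config an `emgdecode_config` (default [default_config()]).
#' @param out_dir output directory.
#' @param resume reuse cached per-participant results when the configuration
#'   hash matches (default TRUE).
#' @param verbose print stage progress.
#' @return the manifest list, invisibly; outputs are written to `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = "results/pipeline",
                         resume = TRUE, verbose = TRUE) {
  stopifnot(inherits(config, "emgdecode_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cache_dir <- file.path(out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)
  hash <- config_hash(config)
  say <- function(...) if (verbose) message(...)

  ex <- config$experiment
  manifest <- list(config_hash = hash, seed = config$seed,
                   package_version = as.character(utils::packageVersion("emgdecode")),
                   started = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   stages = list())
  save_config(config, file.path(out_dir, "resolved_config.yaml"))

  nch <- config$generator$n_channels
  clstm_cfg <- if ("clstm" %in% ex$algorithms) {
    do.call(clstm_config,
            c(list(p = nch + nch * (nch - 1) / 2, d = 3, seed = config$seed),
              config$clstm))
  } else NULL
  conditions <- compose_training_conditions(ex$trials_per_condition,
                                            conditions = ex$conditions)
  fold_plan <- make_fold_plan(
    n_trials = config$session$trials_per_movement, n_train = ex$n_train,
    n_folds = ex$n_folds, n_val = ex$n_val, seed = config$seed,
    mode = ex$fold_mode)

  all_cells <- list(); all_folds <- list(); all_agg <- list()
  for (i in seq_len(ex$n_participants)) {
    pseed <- derive_seed(config$seed, 100L + i)
    cache <- file.path(cache_dir, sprintf("grid_p%02d_%s.rds", i, hash))
    t0 <- Sys.time()
    if (resume && file.exists(cache)) {
      say("participant ", i, ": cached")
      grid <- readRDS(cache)
    } else {
      say("participant ", i, ": simulate + preprocess + grid")
      datasets <- simulate_participant(
        pseed, trials_per_movement = config$session$trials_per_movement,
        rest_s = config$session$rest_s,
        gen_args = config$generator,
        mixing_jitter_sd = ex$mixing_jitter_sd,
        window_s = config$preprocessing$window_s,
        rate_hz = config$preprocessing$rate_hz)
      grid <- run_offline_grid(datasets, conditions,
                               algorithms = ex$algorithms,
                               fold_plan = fold_plan, clstm_cfg = clstm_cfg,
                               metrics = ex$metrics,
                               test_speeds = ex$test_speeds,
                               rate_hz = config$preprocessing$rate_hz)
      saveRDS(grid, cache)
    }
    manifest$stages[[sprintf("participant_%02d", i)]] <-
      list(seed = pseed, cache = basename(cache),
           seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
    grid$cells$participant <- i
    grid$folds$participant <- i
    agg <- aggregate_across_speeds(grid)
    agg$participant <- i
    all_cells[[i]] <- grid$cells; all_folds[[i]] <- grid$folds
    all_agg[[i]] <- agg
  }
  cells <- do.call(rbind, all_cells)
  folds <- do.call(rbind, all_folds)
  agg <- do.call(rbind, all_agg)

  write_outcome_csv(cells, file.path(out_dir, "grid_cells.csv"))
  utils::write.csv(folds, file.path(out_dir, "grid_folds.csv"), row.names = FALSE)
  utils::write.csv(agg, file.path(out_dir, "aggregated.csv"), row.names = FALSE)

  # group statistics: one ANOVA per algorithm per metric over conditions
  stats_rows <- list(); posthoc_rows <- list()
  for (alg in unique(agg$algorithm)) {
    for (met in unique(agg$metric)) {
      sub <- agg[agg$algorithm == alg & agg$metric == met, ]
      groups <- split(sub$value, sub$condition)
      groups <- groups[lengths(groups) >= 2]
      if (length(groups) < 2) next
      ad_p <- if (min(lengths(groups)) >= 5) {
        vapply(groups, function(g) anderson_darling_normality(g)$p_value,
               numeric(1))
      } else NA_real_
      an <- oneway_anova(groups)
      stats_rows[[length(stats_rows) + 1L]] <- data.frame(
        algorithm = alg, metric = met, F = an$F, p = an$p_value,
        df1 = an$df1, df2 = an$df2,
        min_ad_normality_p = suppressWarnings(min(ad_p)),
        stringsAsFactors = FALSE)
      if (!is.na(an$p_value) && an$p_value < ex$alpha) {
        ph <- posthoc_sidak_ttests(groups, alpha = ex$alpha)
        ph$algorithm <- alg; ph$metric <- met
        posthoc_rows[[length(posthoc_rows) + 1L]] <- ph
      }
    }
  }
  if (length(stats_rows)) {
    utils::write.csv(do.call(rbind, stats_rows),
                     file.path(out_dir, "anova.csv"), row.names = FALSE)
  }
  if (length(posthoc_rows)) {
    utils::write.csv(do.call(rbind, posthoc_rows),
                     file.path(out_dir, "posthoc.csv"), row.names = FALSE)
  }

  outputs <- list.files(out_dir, pattern = "\\.(csv|yaml)$", full.names = TRUE)
  manifest$outputs <- lapply(stats::setNames(outputs, basename(outputs)),
                             function(f) unname(tools::md5sum(f)))
  manifest$finished <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("pipeline complete: ", out_dir)
  invisible(manifest)
}
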