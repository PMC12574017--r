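#' The seven training-speed conditions
#'
#' Single-speed conditions (S, M, F), the three two-speed mixes (S+M, S+F,
#' M+F) and the all-speed condition. Every condition trains on the same
#' total number of trials per movement (`trials_per_condition`, default 12),
#' drawn equally from each contributing speed (12 = 6+6 = 4+4+4), so
#' conditions differ only in speed composition, not data quantity.
#'
#' @param trials_per_condition training trials per movement in every
#'   condition (must be divisible by the number of speeds in each requested
#'   condition; default 12).
#' @param conditions names of the conditions to compose (default all seven).
#' @param n_available optional named vector of trials per movement available
#'   for each speed; an informative error is raised if any condition would
#'   need more.
#' @return a named list of conditions, each a list with `name`, `speeds` and
#'   `per_speed` (trials per movement drawn from each speed).
#' @export
compose_training_conditions <- function(trials_per_condition = 12,
                                        conditions = c("S", "M", "F", "S+M",
                                                       "S+F", "M+F", "All"),
                                        n_available = NULL) {
  defs <- list(
    S     = "slow",
    M     = "medium",
    F     = "fast",
    `S+M` = c("slow", "medium"),
    `S+F` = c("slow", "fast"),
    `M+F` = c("medium", "fast"),
    All   = c("slow", "medium", "fast")
  )
  unknown <- setdiff(conditions, names(defs))
  if (length(unknown)) stop("unknown condition(s): ",
                            paste(unknown, collapse = ", "))
  defs <- defs[conditions]
  conditions <- lapply(names(defs), function(nm) {
    speeds <- defs[[nm]]
    if (trials_per_condition %% length(speeds) != 0) {
      stop("trials_per_condition (", trials_per_condition,
           ") is not divisible by the ", length(speeds),
           " speeds of condition ", nm)
    }
    per <- trials_per_condition %/% length(speeds)
    if (!is.null(n_available)) {
      short <- speeds[n_available[speeds] < per]
      if (length(short)) {
        stop("condition ", nm, " needs ", per, " trials/movement from ",
             paste(short, collapse = ", "), " but only ",
             paste(n_available[short], collapse = ", "), " available")
      }
    }
    list(name = nm, speeds = speeds,
         per_speed = stats::setNames(rep(per, length(speeds)), speeds))
  })
  names(conditions) <- names(defs)
  conditions
}

#' Cross-validation fold plan
#'
#' For each fold and each (speed, movement) cell, selects `n_train` training
#' and `n_trials - n_train` testing trials out of the `n_trials` collected,
#' with a seeded shuffle. The default mode draws an independent shuffled
#' 12/8 split per fold (repeated random subsampling); `mode = "partition"`
#' rotates test blocks through a single shuffle so test sets are (nearly)
#' disjoint across folds. The last `n_val` training trials of each cell are
#' flagged as the C-LSTM validation trials.
#'
#' @param n_trials trials per movement collected per speed (default 20).
#' @param n_train training trials per movement per fold (default 12).
#' @param n_folds folds (default 6).
#' @param n_val validation trials flagged among the training set
#'   (default 2).
#' @param speeds,movements the grid the plan covers.
#' @param seed shuffle seed.
#' @param mode `"subsample"` (default) or `"partition"`.
#' @return object of class `fold_plan`: nested list
#'   `folds[[f]][[speed]][[movement]]` with integer fields `train`, `val`,
#'   `test` (ordinal trial indices 1..n_trials within that cell).
#' @export
make_fold_plan <- function(n_trials = 20, n_train = 12, n_folds = 6,
                           n_val = 2,
                           speeds = c("slow", "medium", "fast"),
                           movements = 1:6, seed = 1,
                           mode = c("subsample", "partition")) {
  mode <- match.arg(mode)
  if (n_folds < 1) stop("n_folds must be at least 1")
  stopifnot(n_train < n_trials, n_val < n_train)
  n_test <- n_trials - n_train

  folds <- vector("list", n_folds)
  counter <- 0L
  base_perm <- list()
  if (mode == "partition") {
    for (s in speeds) for (m in movements) {
      counter <- counter + 1L
      set.seed(derive_seed(seed, counter))
      base_perm[[paste(s, m)]] <- sample(n_trials)
    }
  }
  for (f in seq_len(n_folds)) {
    folds[[f]] <- stats::setNames(lapply(speeds, function(s) {
      stats::setNames(lapply(movements, function(m) {
        if (mode == "subsample") {
          counter <<- counter + 1L
          set.seed(derive_seed(seed, counter))
          perm <- sample(n_trials)
        } else {
          perm0 <- base_perm[[paste(s, m)]]
          rot <- ((f - 1L) * n_test) %% n_trials
          perm <- perm0[(seq_len(n_trials) + rot - 1L) %% n_trials + 1L]
        }
        test <- perm[seq_len(n_test)]
        train <- perm[(n_test + 1L):n_trials]
        list(train = train,
             val = train[(n_train - n_val + 1L):n_train],
             test = test)
      }), paste0("m", movements))
    }), speeds)
  }
  out <- list(folds = folds, n_trials = n_trials, n_train = n_train,
              n_test = n_test, n_folds = n_folds, n_val = n_val,
              speeds = speeds, movements = movements, seed = seed,
              mode = mode)
  class(out) <- "fold_plan"
  out
}

#' Simulate and preprocess one synthetic participant
#'
#' Generates one training session per speed (trial order, trial gains and
#' EMG noise all derived from `participant_seed`), renders the EMG through
#' the forward model with participant-specific mixing (a multiplicative
#' jitter of the common mixing matrix, emulating electrode placement and
#' anatomy differences), and runs the full preprocessing chain.
#'
#' @param participant_seed integer seed identifying the participant.
#' @param trials_per_movement trials of each movement per session
#'   (default 20).
#' @param speeds speeds to simulate (default all three).
#' @param rest_s inter-trial rest, seconds.
#' @param gen_args named list of [generator_config()] overrides.
#' @param mixing_jitter_sd relative spread of the per-participant mixing
#'   jitter (default 0.15).
#' @param window_s,rate_hz MAV parameters.
#' @return named list (per speed) of aligned datasets: the fields of
#'   [align_features_to_kinematics()] plus `trial_table`.
#' @export
simulate_participant <- function(participant_seed, trials_per_movement = 20,
                                 speeds = c("slow", "medium", "fast"),
                                 rest_s = 2, gen_args = list(),
                                 mixing_jitter_sd = 0.15,
                                 window_s = 0.3, rate_hz = 30) {
  base_args <- modifyList(list(seed = 1L), gen_args)
  base_cfg <- do.call(generator_config, base_args)

  set.seed(derive_seed(participant_seed, 3L))
  jit <- matrix(pmax(0.2, 1 + rnorm(length(base_cfg$mixing), 0, mixing_jitter_sd)),
                nrow(base_cfg$mixing), ncol(base_cfg$mixing))
  args_p <- modifyList(base_args, list(mixing = base_cfg$mixing * jit,
                                       seed = participant_seed))
  fspec <- filter_spec(fs = base_cfg$fs_emg)

  out <- lapply(stats::setNames(speeds, speeds), function(sp) {
    cfg_p <- do.call(generator_config,
                     modifyList(args_p, list(seed = derive_seed(participant_seed,
                                                                match(sp, c("slow", "medium", "fast"))))))
    kin <- generate_session(sp, trials_per_movement, rest_s = rest_s,
                            fs_kin = cfg_p$fs_kin, seed = cfg_p$seed)
    raw <- emg_forward_model(kin, cfg_p)
    ds <- preprocess_recording(raw, fspec, window_s = window_s,
                               rate_hz = rate_hz)
    ds$trial_table <- attr(kin, "trial_table")
    ds
  })
  attr(out, "participant_seed") <- participant_seed
  out
}

# Map ordinal per-movement trial indices to global trial ids of a session.
ordinal_to_trial_ids <- function(trial_table, movement, ordinals) {
  ids <- trial_table$trial_id[trial_table$movement == movement]
  ids[ordinals[ordinals <= length(ids)]]
}

# Assemble the training frames of one condition for one fold.
# Validation trials (for the C-LSTM) are flagged per movement across the
# condition's speeds, so mixed conditions with one trial per speed still
# retain training trials. Returns Z, X, blocks (unique across speeds),
# val_blocks.
assemble_training_set <- function(datasets, condition, fold, n_val_frac) {
  movements <- unique(datasets[[condition$speeds[1]]]$trial_table$movement)
  total <- sum(unlist(condition$per_speed))
  n_val_m <- min(total - 1L, max(1L, round(total * n_val_frac)))

  sel <- list()    # per speed: selected global trial ids
  offset <- stats::setNames(rep(0L, length(condition$speeds)), condition$speeds)
  off <- 0L
  for (sp in condition$speeds) {
    offset[[sp]] <- off
    off <- off + max(datasets[[sp]]$block_id, na.rm = TRUE) + 1L
    sel[[sp]] <- integer(0)
  }
  val_blocks <- integer(0)
  for (m in movements) {
    ids_m <- list()
    for (sp in condition$speeds) {
      ds <- datasets[[sp]]
      count <- condition$per_speed[[sp]]
      ords <- fold[[sp]][[paste0("m", m)]]$train[seq_len(count)]
      ids <- ordinal_to_trial_ids(ds$trial_table, m, ords)
      sel[[sp]] <- c(sel[[sp]], ids)
      ids_m[[sp]] <- ids + offset[[sp]]
    }
    pooled <- unlist(ids_m, use.names = FALSE)
    # rotate which trials serve as validation across movements so that in
    # mixed conditions no single speed is systematically held out
    rot <- (match(m, movements) + seq_len(n_val_m) - 1L) %% length(pooled) + 1L
    val_blocks <- c(val_blocks, pooled[rot])
  }
  Zs <- list(); Xs <- list(); blks <- list()
  for (sp in condition$speeds) {
    ds <- datasets[[sp]]
    keep <- which(ds$block_id %in% sel[[sp]])
    Zs[[sp]] <- ds$Z[keep, , drop = FALSE]
    Xs[[sp]] <- ds$X[keep, , drop = FALSE]
    blks[[sp]] <- ds$block_id[keep] + offset[[sp]]
  }
  list(Z = do.call(rbind, Zs), X = do.call(rbind, Xs),
       blocks = unlist(blks), val_blocks = val_blocks)
}

# Extract per-trial test predictions for one fitted decoder on one speed.
# With clamp = TRUE predictions saturate at the [-1, 1] kinematic range
# (the virtual hand has joint limits, so out-of-range commands saturate).
predict_test_trials <- function(predict_fun, ds, fold_cell, speed,
                                clamp = TRUE) {
  trials <- list()
  for (m in unique(ds$trial_table$movement)) {
    ords <- fold_cell[[paste0("m", m)]]$test
    ids <- ordinal_to_trial_ids(ds$trial_table, m, ords)
    for (id in ids) {
      keep <- which(ds$block_id == id)
      pred <- predict_fun(ds$Z[keep, , drop = FALSE])
      if (clamp) {
        pred[pred > 1] <- 1
        pred[pred < -1] <- -1
      }
      dof <- ds$trial_table$dof[ds$trial_table$trial_id == id]
      trials[[length(trials) + 1L]] <-
        trial_prediction(pred, ds$X[keep, , drop = FALSE], dof,
                         trial_id = id, speed = speed)
    }
  }
  trials
}

cell_metrics <- function(trials, metrics, rate_hz = 30) {
  vals <- c()
  if ("intended_rmse" %in% metrics)
    vals["intended_rmse"] <- intended_rmse(trials)
  if ("unintended_rmse" %in% metrics)
    vals["unintended_rmse"] <- unintended_rmse(trials)
  if ("windowed_rmse" %in% metrics)
    vals["windowed_rmse"] <- windowed_rmse(trials)
  if ("lmaj" %in% metrics) {
    per_trial <- vapply(trials, function(tr) {
      lmaj(tr$pred[, tr$active_dof], fs = rate_hz)
    }, numeric(1))
    vals["lmaj"] <- median(per_trial)
  }
  vals
}

#' Run the offline training-condition x algorithm x test-speed grid
#'
#' For every fold of the plan and every (condition, algorithm) pair, trains
#' a decoder on that fold's training trials (composed across speeds per the
#' condition) and evaluates it on the fold's held-out test trials of each
#' test speed. With the full design (7 conditions x 2 algorithms x 3 test
#' speeds) this produces the 42 outcome cells per participant. Cells whose
#' training fails are marked failed and the grid is still returned.
#'
#' @param datasets per-speed aligned datasets from [simulate_participant()].
#' @param conditions from [compose_training_conditions()].
#' @param algorithms subset of `c("kf", "clstm")`.
#' @param fold_plan a [make_fold_plan()].
#' @param clstm_cfg a [clstm_config()] for the C-LSTM cells.
#' @param metrics metrics to compute per cell.
#' @param test_speeds speeds to evaluate on (default all three).
#' @param mkf_threshold if nonzero, KF predictions additionally pass through
#'   [apply_mkf_threshold()] (default 0: plain KF, as in the offline
#'   analysis).
#' @param clamp_predictions saturate predictions at the [-1, 1] kinematic
#'   range before scoring (default FALSE: offline metrics score the raw
#'   decoder output; the virtual hand's joint limits apply online only).
#' @param rate_hz feature frame rate (for jerk scaling).
#' @param verbose print progress.
#' @return object of class `outcome_grid`: list with `folds` (per-fold
#'   long data.frame: algorithm, condition, test_speed, fold, metric,
#'   value, failed) and `cells` (fold-averaged data.frame).
#' @export
run_offline_grid <- function(datasets, conditions, algorithms = c("kf", "clstm"),
                             fold_plan, clstm_cfg = NULL,
                             metrics = c("intended_rmse", "unintended_rmse",
                                         "windowed_rmse", "lmaj"),
                             test_speeds = c("slow", "medium", "fast"),
                             mkf_threshold = 0, clamp_predictions = FALSE,
                             rate_hz = 30, verbose = FALSE) {
  stopifnot(inherits(fold_plan, "fold_plan"))
  algorithms <- match.arg(algorithms, c("kf", "clstm"), several.ok = TRUE)
  test_speeds <- intersect(test_speeds, names(datasets))
  if (is.null(clstm_cfg) && "clstm" %in% algorithms) {
    clstm_cfg <- clstm_config(p = ncol(datasets[[1]]$Z))
  }
  n_val_frac <- fold_plan$n_val / fold_plan$n_train

  rows <- list()
  for (f in seq_len(fold_plan$n_folds)) {
    fold <- fold_plan$folds[[f]]
    for (cd in conditions) {
      tr_set <- assemble_training_set(datasets, cd, fold, n_val_frac)
      for (alg in algorithms) {
        predict_fun <- NULL
        failed <- FALSE
        fit_err <- tryCatch({
          if (alg == "kf") {
            model <- fit_kalman(tr_set$Z, tr_set$X, blocks = tr_set$blocks)
            predict_fun <- function(Zt) {
              ph <- run_kalman(model, Zt)
              if (mkf_threshold > 0) apply_mkf_threshold(ph, mkf_threshold) else ph
            }
          } else {
            net <- build_clstm(clstm_cfg)
            net <- train_clstm(net, tr_set$Z, tr_set$X,
                               val = tr_set$val_blocks, blocks = tr_set$blocks)
            predict_fun <- function(Zt) predict_clstm(net, Zt)
          }
          NULL
        }, error = function(e) conditionMessage(e))
        if (!is.null(fit_err)) {
          failed <- TRUE
          if (verbose) message("  [fold ", f, " ", cd$name, " ", alg,
                               "] training failed: ", fit_err)
        }
        for (sp in test_speeds) {
          vals <- stats::setNames(rep(NA_real_, length(metrics)), metrics)
          if (!failed) {
            trials <- predict_test_trials(predict_fun, datasets[[sp]],
                                          fold[[sp]], sp,
                                          clamp = clamp_predictions)
            vals <- cell_metrics(trials, metrics, rate_hz)
          }
          rows[[length(rows) + 1L]] <- data.frame(
            algorithm = alg, condition = cd$name, test_speed = sp,
            fold = f, metric = names(vals), value = unname(vals),
            failed = failed, stringsAsFactors = FALSE)
        }
        if (verbose) message("fold ", f, " | ", cd$name, " | ", alg, " done")
      }
    }
  }
  folds_df <- do.call(rbind, rows)
  cells <- aggregate(value ~ algorithm + condition + test_speed + metric,
                     data = folds_df, FUN = mean, na.action = stats::na.omit)
  out <- list(folds = folds_df, cells = cells,
              n_folds = fold_plan$n_folds,
              conditions = vapply(conditions, `[[`, character(1), "name"),
              algorithms = algorithms, test_speeds = test_speeds)
  class(out) <- "outcome_grid"
  out
}

#' @export
print.outcome_grid <- function(x, ...) {
  cat(sprintf("<outcome_grid: %d algorithms x %d conditions x %d test speeds (%d cells/metric), %d folds>\n",
              length(x$algorithms), length(x$conditions),
              length(x$test_speeds),
              length(x$algorithms) * length(x$conditions) * length(x$test_speeds),
              x$n_folds))
  invisible(x)
}

#' Average outcome cells across test speeds
#'
#' Collapses the per-speed cells to one value per (algorithm, condition,
#' metric): the arithmetic mean over the three test speeds, except LMAJ
#' which uses the median across testing conditions.
#'
#' @param grid an `outcome_grid` or its `cells` data.frame.
#' @param require_speeds speeds that must all be present (default the
#'   grid's test speeds).
#' @return data.frame with columns algorithm, condition, metric, value.
#' @export
aggregate_across_speeds <- function(grid, require_speeds = NULL) {
  cells <- if (inherits(grid, "outcome_grid")) grid$cells else grid
  if (is.null(require_speeds)) {
    require_speeds <- if (inherits(grid, "outcome_grid")) grid$test_speeds else
      unique(cells$test_speed)
  }
  missing <- setdiff(require_speeds, unique(cells$test_speed))
  if (length(missing)) stop("missing test speed(s): ",
                            paste(missing, collapse = ", "))
  out <- lapply(split(cells, cells[c("algorithm", "condition", "metric")],
                      drop = TRUE), function(g) {
    if (!all(require_speeds %in% g$test_speed)) {
      stop("missing test speed(s) for ", g$algorithm[1], "/", g$condition[1],
           "/", g$metric[1])
    }
    agg <- if (g$metric[1] == "lmaj") median(g$value) else mean(g$value)
    data.frame(algorithm = g$algorithm[1], condition = g$condition[1],
               metric = g$metric[1], value = agg, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Anderson-Darling normality test (estimated parameters)
#'
#' The case-3 statistic (mean and variance estimated from the sample) with
#' the small-sample correction `A* = A^2 (1 + 0.75/n + 2.25/n^2)` and the
#' standard piecewise p-value approximation.
#'
#' @param values numeric vector, n >= 5, non-degenerate.
#' @return list with `statistic` (corrected A*), `p_value`, `n`.
#' @export
anderson_darling_normality <- function(values) {
  x <- sort(as.numeric(values))
  n <- length(x)
  if (n < 5) stop("need at least 5 observations")
  s <- sd(x)
  if (s == 0) stop("degenerate sample: zero variance")
  z <- (x - mean(x)) / s
  logp <- pnorm(z, log.p = TRUE)
  logq <- pnorm(z, lower.tail = FALSE, log.p = TRUE)
  i <- seq_len(n)
  A2 <- -n - mean((2 * i - 1) * (logp + rev(logq)))
  A <- A2 * (1 + 0.75 / n + 2.25 / n^2)
  p <- if (A > 10) {
    0
  } else if (A < 0.2) {
    1 - exp(-13.436 + 101.14 * A - 223.73 * A^2)
  } else if (A < 0.34) {
    1 - exp(-8.318 + 42.796 * A - 59.938 * A^2)
  } else if (A < 0.6) {
    exp(0.9177 - 4.279 * A - 1.38 * A^2)
  } else {
    exp(1.2937 - 5.709 * A + 0.0186 * A^2)
  }
  list(statistic = A, p_value = min(max(p, 0), 1), n = n)
}

#' One-way analysis of variance across training-speed groups
#'
#' Standard between/within decomposition with `F` on (k-1, N-k) degrees of
#' freedom (pooled variance). Degenerate input (zero within-group variance)
#' is flagged rather than reported as a spurious F.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return list with `F`, `p_value`, `df1`, `df2`, `zero_within`.
#' @export
oneway_anova <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  n_i <- lengths(groups)
  if (any(n_i < 2)) stop("each group needs at least 2 observations")
  values <- unlist(groups)
  k <- length(groups); N <- length(values)
  grand <- mean(values)
  ss_between <- sum(n_i * (vapply(groups, mean, numeric(1)) - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1; df2 <- N - k
  if (ss_within <= .Machine$double.eps * max(ss_between, 1)) {
    return(list(F = NA_real_, p_value = NA_real_, df1 = df1, df2 = df2,
                zero_within = TRUE))
  }
  Fstat <- (ss_between / df1) / (ss_within / df2)
  list(F = Fstat, p_value = pf(Fstat, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, zero_within = FALSE)
}

#' Post-hoc pairwise t-tests with Dunn-Sidak correction
#'
#' Unpaired two-tailed pooled-variance t-tests for every unordered pair of
#' groups, at the Sidak-corrected per-comparison level
#' `alpha' = 1 - (1 - alpha)^(1/m)` for m pairs. `p_sidak` is the
#' equivalently adjusted p-value `1 - (1 - p)^m`.
#'
#' @param groups named list of numeric vectors (>= 2 groups).
#' @param alpha family-wise level (default 0.05).
#' @return data.frame with one row per pair: `group1`, `group2`, `t`, `df`,
#'   `p`, `p_sidak`, `alpha_corrected`, `significant`.
#' @export
posthoc_sidak_ttests <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  pairs <- t(combn(length(groups), 2))
  m <- nrow(pairs)
  alpha_c <- 1 - (1 - alpha)^(1 / m)
  rows <- lapply(seq_len(m), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    xt <- t.test(groups[[i]], groups[[j]], var.equal = TRUE)
    p <- xt$p.value
    data.frame(group1 = names(groups)[i], group2 = names(groups)[j],
               t = unname(xt$statistic), df = unname(xt$parameter),
               p = p, p_sidak = min(1, 1 - (1 - p)^m),
               alpha_corrected = alpha_c,
               significant = p < alpha_c, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
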