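test_that("the design composes 7 conditions, 14 decoders and 42 cells", {
  conds <- compose_training_conditions(12)
  expect_length(conds, 7)
  expect_equal(names(conds), c("S", "M", "F", "S+M", "S+F", "M+F", "All"))
  expect_equal(length(conds) * 2, 14)                    # decoders
  expect_equal(length(conds) * 2 * 3, 42)                # outcome cells

  # every condition trains on the same total trials per movement
  totals <- vapply(conds, function(cd) sum(cd$per_speed), numeric(1))
  expect_true(all(totals == 12))
  expect_equal(conds$`S+F`$per_speed, c(slow = 6, fast = 6))
  expect_equal(conds$All$per_speed, c(slow = 4, medium = 4, fast = 4))

  expect_error(compose_training_conditions(12, conditions = "X+Y"), "unknown condition")
  expect_error(compose_training_conditions(13), "not divisible")
  expect_error(
    compose_training_conditions(12, n_available = c(slow = 20, medium = 20, fast = 5)),
    "fast")
})

test_that("fold plans split 12 train / 8 test per movement with 2 validation trials", {
  plan <- make_fold_plan(seed = 4)
  expect_equal(plan$n_folds, 6)
  for (f in seq_len(plan$n_folds)) {
    for (sp in plan$speeds) {
      for (m in paste0("m", 1:6)) {
        cell <- plan$folds[[f]][[sp]][[m]]
        expect_length(cell$train, 12)
        expect_length(cell$test, 8)
        expect_length(cell$val, 2)
        expect_length(intersect(cell$train, cell$test), 0)
        expect_true(all(cell$val %in% cell$train))
        expect_setequal(c(cell$train, cell$test), 1:20)
      }
    }
  }
  # seeded reproducibility
  expect_identical(make_fold_plan(seed = 4), plan)
})

test_that("test-set coverage across folds matches the fold mode", {
  # subsample mode: each trial appears in test sets with expected multiplicity
  plan <- make_fold_plan(n_trials = 20, n_train = 12, n_folds = 6, seed = 1)
  appearances <- table(unlist(lapply(plan$folds, function(f) f$slow$m1$test)))
  expect_equal(sum(appearances), 6 * 8)
  expect_true(all(appearances <= 6))

  # partition mode: test blocks rotate, so coverage is balanced
  plan2 <- make_fold_plan(n_trials = 20, n_train = 12, n_folds = 6, seed = 1,
                          mode = "partition")
  app2 <- table(factor(unlist(lapply(plan2$folds, function(f) f$slow$m1$test)),
                       levels = 1:20))
  expect_equal(sum(app2), 48)
  expect_lte(max(app2) - min(app2), 1)
})

test_that("a one-cell grid trains and evaluates end to end", {
  datasets <- list()
  for (sp in c("slow", "medium", "fast")) {
    cfg <- tiny_generator(seed = 21)
    kin <- generate_session(sp, 3, seed = 21)
    ds <- preprocess_recording(emg_forward_model(kin, cfg),
                               filter_spec(cfg$fs_emg))
    ds$trial_table <- attr(kin, "trial_table")
    datasets[[sp]] <- ds
  }
  conds <- compose_training_conditions(2, conditions = "S")
  plan <- make_fold_plan(n_trials = 3, n_train = 2, n_folds = 1, n_val = 1,
                         seed = 2)
  g <- run_offline_grid(datasets, conds, algorithms = "kf", fold_plan = plan,
                        test_speeds = "fast",
                        metrics = c("intended_rmse", "lmaj"))
  expect_s3_class(g, "outcome_grid")
  expect_equal(nrow(g$cells), 2)      # 1 condition x 1 algorithm x 1 speed x 2 metrics
  expect_true(all(is.finite(g$cells$value)))
  expect_false(any(g$folds$failed))
})

test_that("speed aggregation uses the mean, except the median for LMAJ", {
  cells <- expand.grid(algorithm = "kf", condition = "S",
                       test_speed = c("slow", "medium", "fast"),
                       metric = c("intended_rmse", "lmaj"),
                       stringsAsFactors = FALSE)
  cells$value <- c(1, 2, 3, 1, 2, 10)
  agg <- aggregate_across_speeds(cells)
  expect_equal(agg$value[agg$metric == "intended_rmse"], 2)
  expect_equal(agg$value[agg$metric == "lmaj"], 2)        # median, not 13/3

  expect_error(aggregate_across_speeds(cells[cells$test_speed != "fast", ],
                                       require_speeds = c("slow", "medium", "fast")),
               "missing test speed")
})

test_that("Anderson-Darling test is calibrated and matches nortest", {
  set.seed(15)
  x <- rnorm(1e4)
  res <- anderson_darling_normality(x)
  expect_gt(res$p_value, 0.05)

  y <- rexp(1e4)
  expect_lt(anderson_darling_normality(y)$p_value, 0.001)

  # independent implementation check on moderate samples
  for (s in 1:5) {
    set.seed(s)
    z <- rnorm(60) + s
    ref <- nortest::ad.test(z)
    mine <- anderson_darling_normality(z)
    expect_equal(mine$statistic, unname(ref$statistic) *
                   (1 + 0.75 / 60 + 2.25 / 60^2), tolerance = 1e-8)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-6)
  }

  expect_error(anderson_darling_normality(rep(1, 10)), "zero variance")
  expect_error(anderson_darling_normality(c(1, 2, 3)), "at least 5")
})

test_that("one-way ANOVA matches brute-force sums of squares and t^2", {
  # textbook 3-group instance, checked against explicit decomposition
  g <- list(c(6.1, 5.8, 6.4, 6.0), c(7.2, 7.0, 6.8, 7.5), c(5.5, 5.9, 5.2))
  res <- oneway_anova(g)
  N <- length(unlist(g)); k <- 3
  grand <- mean(unlist(g))
  ssb <- sum(lengths(g) * (sapply(g, mean) - grand)^2)
  ssw <- sum(unlist(lapply(g, function(v) (v - mean(v))^2)))
  F_ref <- (ssb / (k - 1)) / (ssw / (N - k))
  expect_equal(res$F, F_ref, tolerance = 1e-12)
  expect_equal(res$df1, 2); expect_equal(res$df2, N - 3)
  # agreement with stats::oneway.test under equal variances
  df <- data.frame(y = unlist(g), grp = rep(seq_along(g), lengths(g)))
  ref <- oneway.test(y ~ factor(grp), df, var.equal = TRUE)
  expect_equal(res$F, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)

  # two groups: F equals the square of the pooled two-sample t
  set.seed(16)
  a <- rnorm(10); b <- rnorm(12, 0.5)
  res2 <- oneway_anova(list(a, b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-10)

  # degenerate input is flagged, not reported as a huge F
  res3 <- oneway_anova(list(rep(1, 4), rep(2, 4)))
  expect_true(res3$zero_within)
  expect_true(is.na(res3$F))
  expect_error(oneway_anova(list(1:3)), "at least 2 groups")
})

test_that("Dunn-Sidak post-hoc tests use the corrected per-comparison level", {
  groups <- lapply(1:7, function(i) rnorm(8, mean = 0))
  ph <- posthoc_sidak_ttests(groups)
  expect_equal(nrow(ph), 21)
  expect_equal(ph$alpha_corrected[1], 1 - 0.95^(1 / 21), tolerance = 1e-12)
  expect_equal(ph$alpha_corrected[1], 0.002441, tolerance = 1e-3)

  two <- posthoc_sidak_ttests(list(rnorm(6), rnorm(6)))
  expect_equal(two$alpha_corrected, 0.05)

  set.seed(17)
  x <- rnorm(10, 5, 1)
  same <- list(x, x, x, x)                       # literally identical groups
  ph2 <- posthoc_sidak_ttests(same)
  expect_false(any(ph2$significant))
  expect_true(all(ph2$p_sidak >= ph2$p - 1e-12))
})
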