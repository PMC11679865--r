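quick_cfg <- function(seed = 1L, epochs = 10L) {
  train_config(epochs = epochs, learning_rate = 0.005, seed = seed,
               fitness_epochs = 5L,
               fixed_hyperparams = list(units1 = 8L, units2 = 8L,
                                        dense_units = 8L, dropout = 0.2,
                                        batch_size = 16L))
}

test_that("the shuffled split partitions indices by the 60/20/20 fractions", {
  sp <- split_data(800, seed = 1)
  expect_length(sp$train, 480L)
  expect_length(sp$validation, 160L)
  expect_length(sp$test, 160L)
  for (n in c(10, 37, 101, 800)) {
    sp <- split_data(n, seed = n)
    all_idx <- c(sp$train, sp$validation, sp$test)
    expect_length(all_idx, n)            # totality
    expect_false(any(duplicated(all_idx)))  # disjointness
  }
  expect_identical(split_data(100, seed = 5), split_data(100, seed = 5))
  expect_false(identical(split_data(100, seed = 5)$train,
                         split_data(100, seed = 6)$train))
  expect_error(split_data(2), "at least 3")
})

test_that("the grouped split keeps whole trials together, stratified by class", {
  fs <- build_feature_set(generate_recording(
    synth_config("deap", trials = 16, channels = 4, seed = 3)))
  sp <- split_data_grouped(fs, c(0.5, 0.25, 0.25), seed = 2)
  all_idx <- c(sp$train, sp$validation, sp$test)
  expect_length(all_idx, 320L)
  expect_false(any(duplicated(all_idx)))
  # no trial appears in two sets
  tr <- lapply(sp, function(ix) unique(fs$provenance$trial[ix]))
  expect_length(intersect(tr$train, tr$test), 0L)
  expect_length(intersect(tr$train, tr$validation), 0L)
  # every class is present in every set (4 balanced trials per class)
  for (ix in sp) expect_setequal(unique(fs$class_ids[ix]), 0:3)
})

test_that("an untrained model's validation loss is near ln(K) on balanced classes", {
  fs <- build_feature_set(desk_recording(3))
  sp <- split_data(fs, seed = 3)
  spec <- model_spec(8, 8, 8, 0.2, 4, 384, 8)
  res <- train_model(spec, 16, fs$features[sp$train, , ], fs$class_ids[sp$train],
                     fs$features[sp$validation, , ], fs$class_ids[sp$validation],
                     quick_cfg(3), epochs = 0)
  expect_lt(abs(res$best_val - log(4)), 0.25)
  expect_identical(nrow(res$history), 0L)
})

test_that("training is reproducible and separates high-SNR classes", {
  fs <- build_feature_set(desk_recording(4))
  sp <- split_data(fs, seed = 4)
  spec <- model_spec(8, 8, 8, 0.2, 4, 384, 8)
  args <- list(spec, 16, fs$features[sp$train, , ], fs$class_ids[sp$train],
               fs$features[sp$validation, , ], fs$class_ids[sp$validation],
               quick_cfg(4))
  r1 <- do.call(train_model, args)
  r2 <- do.call(train_model, args)
  expect_identical(r1$history, r2$history)  # same seed, same loss curves
  expect_identical(r1$model$params, r2$model$params)
  # high-SNR synthetic features are learned almost perfectly
  acc <- mean(predict_class(r1$model, fs$features[sp$train, , ]) ==
                fs$class_ids[sp$train])
  expect_gte(acc, 0.9)
  expect_lt(r1$history$train_loss[10], r1$history$train_loss[1])
})

test_that("the swarm fitness is deterministic per configuration and finite on edge specs", {
  fs <- build_feature_set(desk_recording(5))
  sp <- split_data(fs, seed = 5)
  fit <- pso_fitness(fs, sp, quick_cfg(5))
  hp <- list(units1 = 6L, units2 = 5L, dense_units = 4L, dropout = 0.3,
             batch_size = 16L)
  expect_identical(fit(hp), fit(hp))  # same decoded config, same loss
  degenerate <- list(units1 = 1L, units2 = 1L, dense_units = 1L,
                     dropout = 0.1, batch_size = 8L)
  expect_true(is.finite(fit(degenerate)))
  # instrumentation: only train/validation indices were touched
  expect_length(intersect(attr(fit, "used")$indices, sp$test), 0L)
})

test_that("the fixed baseline configuration has computable, finite fitness", {
  rec <- generate_recording(synth_config("deap", trials = 4, channels = 4,
                                         seed = 6))
  fs <- build_feature_set(rec)
  sp <- split_data(fs, seed = 6)
  cfg <- quick_cfg(6); cfg$fitness_epochs <- 2L
  fit <- pso_fitness(fs, sp, cfg)
  expect_true(is.finite(fit(fixed_baseline_hyperparams())))
})

test_that("fixed-parameters mode never invokes the swarm; search modes log every evaluation", {
  fs <- build_feature_set(desk_recording(7))
  cfg <- quick_cfg(7)
  fixed <- run_subject(fs, "fixed_params", cfg = cfg)
  expect_identical(fixed$n_fitness_evals, 0L)
  expect_null(fixed$pso_log)
  expect_null(fixed$loss_trace)
  expect_identical(fixed$best_hyperparams, cfg$fixed_hyperparams)

  prop <- run_subject(fs, "proposed", cfg = cfg,
                      space = default_search_space(units_max = 12,
                                                   batch_max = 32),
                      pso = pso_config(particles = 3L, iterations = 2L,
                                       seed = 8))
  expect_identical(nrow(prop$pso_log), 6L)  # particles x iterations
  expect_identical(prop$n_fitness_evals, sum(!prop$pso_log$cached))
  expect_true(all(diff(prop$loss_trace) <= 1e-12))
  expect_identical(sum(prop$confusion), 32L)  # the 20% test partition
  expect_identical(prop$accuracy,
                   sum(diag(prop$confusion)) / sum(prop$confusion))
})

test_that("segment-level splits leak trial identity; grouped splits do not", {
  # With no class signal (snr = 0) the only usable information is the
  # baseline fingerprint shared by all segments of a trial. The default
  # segment split puts sibling segments in train and test, so accuracy goes
  # far above chance; the grouped split removes the siblings and accuracy
  # falls back to chance. At high SNR the grouped split still scores highly:
  # the class signal itself transfers across trials.
  seg_acc <- numeric(2); grp0_acc <- numeric(2); grp4_acc <- numeric(2)
  for (s in 1:2) {
    cfg16_0 <- synth_config("deap", trials = 16, channels = 8, snr = 0,
                            seed = 30 + s)
    cfg16_4 <- synth_config("deap", trials = 16, channels = 8, snr = 4,
                            seed = 30 + s)
    tc <- quick_cfg(30 + s, epochs = 20L)
    tc$fractions <- c(0.5, 0.25, 0.25)
    fs0 <- build_feature_set(generate_recording(cfg16_0))
    seg_acc[s] <- run_subject(fs0, "fixed_params", cfg = tc)$accuracy
    grp0_acc[s] <- run_subject(fs0, "fixed_params", cfg = tc,
                               split_mode = "trial")$accuracy
    grp4_acc[s] <- run_subject(build_feature_set(generate_recording(cfg16_4)),
                               "fixed_params", cfg = tc,
                               split_mode = "trial")$accuracy
  }
  expect_gte(min(seg_acc), 0.6)   # fingerprint leakage, far above 1/4
  expect_lte(mean(grp0_acc), 0.55)  # chance-level once trials are held out
  expect_gte(min(grp4_acc), 0.9)  # genuine cross-trial class recovery
})

test_that("aggregation computes subject statistics and sums confusions element-wise", {
  r1 <- eval_report("a", matrix(c(8, 2, 2, 8), 2, 2))   # accuracy 0.8
  r2 <- eval_report("b", matrix(c(10, 0, 0, 10), 2, 2)) # accuracy 1.0
  agg <- aggregate_reports(list(r1, r2))
  expect_equal(agg$mean, 0.9)
  expect_equal(agg$max, 1.0)
  expect_equal(agg$min, 0.8)
  expect_equal(agg$std, sd(c(0.8, 1.0)))
  expect_identical(agg$confusion, r1$confusion + r2$confusion)
  expect_identical(sum(agg$confusion), sum(r1$confusion) + sum(r2$confusion))

  single <- aggregate_reports(list(r1))
  expect_identical(single$mean, single$max)
  expect_identical(single$std, 0)
  expect_error(aggregate_reports(list(r1, eval_report("c", diag(3)))),
               "inconsistent")
})
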