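#' Training protocol settings
#'
#' Defaults are the experimental protocol: 150 epochs of Adam at learning rate
#' 0.0001 with categorical cross-entropy, a shuffled 60/20/20
#' train/validation/test split, and full-length training inside the swarm
#' fitness (`fitness_epochs = epochs`; shorten it for desk-scale runs).
#'
#' @param epochs training epochs for the final model.
#' @param learning_rate Adam learning rate.
#' @param fractions train/validation/test fractions summing to 1.
#' @param seed master seed: fixes the split, parameter initialization,
#'   shuffling and dropout masks.
#' @param fitness_epochs epochs used when training inside the PSO fitness.
#' @param fixed_hyperparams hyperparameters of the fixed-parameters ablation
#'   (default [fixed_baseline_hyperparams()]).
#' @return a `train_config`.
#' @export
train_config <- function(epochs = 150L, learning_rate = 1e-4,
                         fractions = c(0.6, 0.2, 0.2), seed = 1L,
                         fitness_epochs = epochs,
                         fixed_hyperparams = fixed_baseline_hyperparams()) {
  stopifnot(epochs >= 1, learning_rate > 0, length(fractions) == 3L,
            abs(sum(fractions) - 1) < 1e-9, all(fractions > 0),
            fitness_epochs >= 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 fractions = fractions, seed = check_seed(seed),
                 fitness_epochs = as.integer(fitness_epochs),
                 fixed_hyperparams = fixed_hyperparams),
            class = "train_config")
}

#' Shuffled 60/20/20 split of example indices
#'
#' A seeded permutation partitioned by the fractions: train and validation
#' take `floor(fraction * n)` examples, the remainder goes to test. The sets
#' are disjoint and their union is `1..n`.
#'
#' @param n number of examples (or a `feature_set`, from which `n` is taken).
#' @param fractions train/validation/test fractions.
#' @param seed permutation seed.
#' @return list of integer index vectors `train`, `validation`, `test`.
#' @export
split_data <- function(n, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  if (inherits(n, "feature_set")) n <- dim(n$features)[1L]
  n <- as.integer(n)
  if (n < 3L) stop("need at least 3 examples to split", call. = FALSE)
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-9)
  perm <- with_seed(check_seed(seed), sample.int(n))
  n_train <- floor(fractions[1L] * n)
  n_val <- floor(fractions[2L] * n)
  list(train = sort(perm[seq_len(n_train)]),
       validation = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[(n_train + n_val + 1L):n]))
}

#' Grouped per-trial split of a feature set
#'
#' Leakage-averse alternative to the default segment-level shuffle: whole
#' trials are assigned to train/validation/test, stratified by class, so no
#' test segment shares a trial (and hence a subtracted baseline window) with
#' a training segment. Within each class the trials are permuted and
#' partitioned by `floor(fraction * trials)` with the remainder going to
#' test.
#'
#' @param fs a `feature_set` (its `provenance` supplies the trial of each
#'   example).
#' @param fractions train/validation/test fractions.
#' @param seed permutation seed.
#' @return list of example-index vectors `train`, `validation`, `test`.
#' @export
split_data_grouped <- function(fs, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(inherits(fs, "feature_set"),
            length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-9)
  trial_class <- vapply(split(fs$class_ids, fs$provenance$trial),
                        function(z) z[1L], 0L)
  trials <- as.integer(names(trial_class))
  sets <- list(train = integer(0), validation = integer(0), test = integer(0))
  with_seed(check_seed(seed), {
    for (cl in unique(trial_class)) {
      tr_cl <- sample(trials[trial_class == cl])
      n <- length(tr_cl)
      n_train <- floor(fractions[1L] * n)
      n_val <- floor(fractions[2L] * n)
      sets$train <- c(sets$train, tr_cl[seq_len(n_train)])
      sets$validation <- c(sets$validation, tr_cl[n_train + seq_len(n_val)])
      sets$test <- c(sets$test, tr_cl[setdiff(seq_len(n), seq_len(n_train + n_val))])
    }
  })
  lapply(sets, function(tr) sort(which(fs$provenance$trial %in% tr)))
}

#' Train a classifier
#'
#' Builds the model from `spec` (seeded initialization) and runs minibatch
#' Adam with categorical cross-entropy, recording per-epoch train and
#' validation loss; validation loss is evaluated in deterministic evaluation
#' mode each epoch.
#'
#' @param spec a [model_spec()].
#' @param batch_size minibatch size.
#' @param x,y training examples (`n x timesteps x channels` array) and
#'   integer class ids 0..K-1.
#' @param x_val,y_val validation set in the same layout.
#' @param cfg a [train_config()].
#' @param epochs override of `cfg$epochs` (0 is allowed and returns the
#'   untrained model with its validation loss).
#' @return list with `model` (trained `psolstm_model`), `history`
#'   (data.frame epoch/train_loss/val_loss) and `best_val` (minimum
#'   validation loss reached).
#' @export
train_model <- function(spec, batch_size, x, y, x_val, y_val, cfg,
                        epochs = cfg$epochs) {
  stopifnot(inherits(spec, "model_spec"), epochs >= 0)
  xb <- aperm(x, c(1L, 3L, 2L))
  xv <- aperm(x_val, c(1L, 3L, 2L))
  with_seed(cfg$seed, {
    model <- build_model(spec)
    fit <- cpp_train(model$params, xb, as.integer(y), xv, as.integer(y_val),
                     spec$attention, as.integer(epochs),
                     as.integer(batch_size), cfg$learning_rate, spec$dropout)
    model$params <- fit$params
    list(model = model,
         history = data.frame(epoch = seq_len(max(epochs, 0)),
                              train_loss = as.numeric(fit$train_loss),
                              val_loss = as.numeric(fit$val_loss)),
         best_val = fit$best_val)
  })
}

#' Swarm fitness: best validation loss of a decoded configuration
#'
#' Returns a closure over the feature set and a fixed split. Each call
#' decodes nothing itself (it receives the decoded hyperparameters from
#' [pso_optimize()] with `decode = TRUE`), builds the model, trains for
#' `cfg$fitness_epochs`, and returns the minimum validation categorical
#' cross-entropy. The closure records every example index it reads in its
#' `used_indices` attribute-environment so leakage of test indices can be
#' asserted by instrumentation.
#'
#' @param fs a [build_feature_set()] result.
#' @param split a [split_data()] result; the same split is reused for every
#'   particle.
#' @param cfg a [train_config()].
#' @param attention build the attention variant (default) or the ablated one.
#' @return function `decoded hyperparameters -> validation loss`, with
#'   environment field `used` accumulating the indices touched.
#' @export
pso_fitness <- function(fs, split, cfg, attention = TRUE) {
  force(fs); force(split); force(cfg); force(attention)
  used <- new.env(parent = emptyenv())
  used$indices <- integer(0)
  f <- function(hp) {
    idx_tr <- split$train
    idx_va <- split$validation
    used$indices <- union(used$indices, c(idx_tr, idx_va))
    spec <- model_spec(hp$units1, hp$units2, hp$dense_units, hp$dropout,
                       num_classes = fs$n_classes,
                       timesteps = dim(fs$features)[2L],
                       channels = dim(fs$features)[3L],
                       attention = attention)
    res <- train_model(spec, hp$batch_size,
                       fs$features[idx_tr, , , drop = FALSE],
                       fs$class_ids[idx_tr],
                       fs$features[idx_va, , , drop = FALSE],
                       fs$class_ids[idx_va],
                       cfg, epochs = cfg$fitness_epochs)
    res$best_val
  }
  attr(f, "used") <- used
  f
}

confusion_matrix <- function(true, pred, k) {
  m <- table(factor(true, levels = 0:(k - 1L)),
             factor(pred, levels = 0:(k - 1L)))
  matrix(as.integer(m), k, k, dimnames = dimnames(m))
}

#' Run the full per-subject experiment
#'
#' `mode = "proposed"` runs the particle swarm over the search space, then
#' retrains from scratch with the best hyperparameters and evaluates once on
#' the held-out test partition. `"no_attention"` is the same protocol with
#' the attention/context path removed. `"fixed_params"` skips the search and
#' trains `cfg$fixed_hyperparams` directly (zero swarm evaluations).
#'
#' @param rec a [subject_recording()] (or an already built `feature_set`).
#' @param mode `"proposed"`, `"no_attention"` or `"fixed_params"`.
#' @param cfg a [train_config()].
#' @param space a [search_space()] (search modes only).
#' @param pso a [pso_config()] (search modes only).
#' @param seed optional master seed overriding `cfg$seed` (the swarm then
#'   uses `seed + 1`).
#' @param split_mode `"segment"` (default: the shuffled segment-level split)
#'   or `"trial"` (grouped per-trial split via [split_data_grouped()], which
#'   keeps whole trials out of the training data).
#' @param feature_args extra arguments to [build_feature_set()].
#' @return an [eval_report()] with extra fields `n_fitness_evals`,
#'   `pso_log` (search modes) and `history` of the final training run.
#' @export
run_subject <- function(rec, mode = c("proposed", "no_attention",
                                      "fixed_params"),
                        cfg = train_config(), space = default_search_space(),
                        pso = pso_config(), seed = NULL,
                        split_mode = c("segment", "trial"),
                        feature_args = list()) {
  mode <- match.arg(mode)
  split_mode <- match.arg(split_mode)
  if (!is.null(seed)) {
    cfg$seed <- check_seed(seed)
    pso$seed <- check_seed(seed + 1)
  }
  fs <- if (inherits(rec, "feature_set")) rec
        else do.call(build_feature_set, c(list(rec), feature_args))
  split <- if (split_mode == "trial") {
    split_data_grouped(fs, cfg$fractions, cfg$seed)
  } else {
    split_data(fs, cfg$fractions, cfg$seed)
  }
  attention <- mode != "no_attention"

  loss_trace <- NULL
  pso_log <- NULL
  n_evals <- 0L
  if (mode == "fixed_params") {
    hp <- cfg$fixed_hyperparams
  } else {
    fit_fn <- pso_fitness(fs, split, cfg, attention = attention)
    opt <- pso_optimize(fit_fn, space, pso, decode = TRUE, cache = TRUE)
    hp <- opt$best_decoded
    loss_trace <- opt$trace
    pso_log <- opt$log
    n_evals <- sum(!opt$log$cached)
    # guard: the fitness must never have touched a test index
    leaked <- intersect(attr(fit_fn, "used")$indices, split$test)
    if (length(leaked)) {
      stop("internal error: fitness read test indices ",
           paste(utils::head(leaked), collapse = ","), call. = FALSE)
    }
  }

  spec <- model_spec(hp$units1, hp$units2, hp$dense_units, hp$dropout,
                     num_classes = fs$n_classes,
                     timesteps = dim(fs$features)[2L],
                     channels = dim(fs$features)[3L],
                     attention = attention)
  final <- train_model(spec, hp$batch_size,
                       fs$features[split$train, , , drop = FALSE],
                       fs$class_ids[split$train],
                       fs$features[split$validation, , , drop = FALSE],
                       fs$class_ids[split$validation],
                       cfg)
  pred <- predict_class(final$model, fs$features[split$test, , , drop = FALSE])
  conf <- confusion_matrix(fs$class_ids[split$test], pred, fs$n_classes)
  rep <- eval_report(fs$subject_id, conf, best_hyperparams = hp,
                     loss_trace = loss_trace, seed = cfg$seed)
  rep$mode <- mode
  rep$n_fitness_evals <- n_evals
  rep$pso_log <- pso_log
  rep$history <- final$history
  rep$split <- split
  rep
}

#' Aggregate per-subject reports
#'
#' @param reports list of [eval_report()]s with a consistent class count.
#' @return an `experiment_result`: `accuracies` (named per subject),
#'   `mean`, `std`, `max`, `min`, and the element-wise summed `confusion`.
#' @export
aggregate_reports <- function(reports) {
  stopifnot(length(reports) >= 1L,
            all(vapply(reports, inherits, TRUE, "eval_report")))
  k <- nrow(reports[[1L]]$confusion)
  if (!all(vapply(reports, function(r) nrow(r$confusion), 0L) == k)) {
    stop("reports have inconsistent class counts", call. = FALSE)
  }
  acc <- vapply(reports, function(r) r$accuracy, 0)
  names(acc) <- vapply(reports, function(r) r$subject_id, "")
  conf <- Reduce(`+`, lapply(reports, function(r) r$confusion))
  structure(list(accuracies = acc,
                 mean = mean(acc),
                 std = if (length(acc) > 1L) sd(acc) else 0,
                 max = max(acc), min = min(acc),
                 confusion = conf,
                 n_subjects = length(acc)),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d subjects: mean %.4f sd %.4f max %.4f min %.4f\n",
              x$n_subjects, x$mean, x$std, x$max, x$min))
  invisible(x)
}

#' Reduced "desk-scale" experiment profile
#'
#' One coherent set of reduced sizes for development, testing and the worked
#' examples: 8 trials x 8 channels of DEAP-geometry synthetic data (full
#' 8064-sample trials, so segment counts match the real layout), LSTM/dense
#' units capped at 16, batch size capped at 32, a 5-particle x 3-iteration
#' swarm, 10-epoch fitness training and a 30-epoch final fit at Adam learning
#' rate 0.005 (the usual scale for models this small; the full-scale default
#' of 0.0001 over 150 epochs is kept in [train_config()]).
#'
#' @param seed master seed used for the generator, split, training and swarm.
#' @param snr generator signal-to-noise ratio (default 4, an easy problem).
#' @return list with `synth` ([synth_config()]), `space`, `pso`, `train`.
#' @export
desk_profile <- function(seed = 1L, snr = 4) {
  list(synth = synth_config("deap", desk_profile = TRUE, snr = snr,
                            seed = seed),
       space = default_search_space(units_max = 16, batch_max = 32),
       pso = pso_config(particles = 5L, iterations = 3L, seed = seed + 1L),
       train = train_config(epochs = 30L, learning_rate = 0.005, seed = seed,
                            fitness_epochs = 10L,
                            fixed_hyperparams = list(
                              units1 = 8L, units2 = 8L, dense_units = 8L,
                              dropout = 0.2, batch_size = 16L)))
}
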