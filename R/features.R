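#' Segment one trial into consecutive non-overlapping windows
#'
#' A 63-s DEAP trial at 128 Hz splits into 21 windows of 3 s (384 samples);
#' a 60-s SEED trial at 200 Hz into 20 windows of 600 samples. The first
#' window is the baseline (see [split_baseline()]).
#'
#' @param trial numeric matrix `channels x samples`.
#' @param sampling_rate samples per second.
#' @param window_seconds window length in seconds (default 3).
#' @param truncate if `TRUE`, a trailing remainder shorter than one window is
#'   dropped; if `FALSE` (default) a non-multiple length is an error.
#' @return list of `channels x window_samples` matrices in temporal order.
#' @export
segment_trial <- function(trial, sampling_rate, window_seconds = 3,
                          truncate = FALSE) {
  stopifnot(is.matrix(trial))
  win <- as.integer(round(window_seconds * sampling_rate))
  n <- ncol(trial)
  rem <- n %% win
  if (rem != 0L && !truncate) {
    stop(sprintf("trial length %d is not a multiple of the %d-sample window (remainder %d)",
                 n, win, rem), call. = FALSE)
  }
  k <- n %/% win
  lapply(seq_len(k), function(s) trial[, ((s - 1L) * win + 1L):(s * win), drop = FALSE])
}

#' Split windows into the baseline and the experimental segments
#'
#' The first 3-s window represents the pre-stimulus (DEAP) or stimulus-onset
#' (SEED) emotional state; the remaining windows are the stimulus-period data.
#'
#' @param segments list of equally shaped windows from [segment_trial()].
#' @return list with elements `baseline` (one matrix) and `experimental`
#'   (the remaining windows, order preserved).
#' @export
split_baseline <- function(segments) {
  if (length(segments) < 2L) {
    stop("need at least 2 segments (baseline + 1 experimental)", call. = FALSE)
  }
  list(baseline = segments[[1L]], experimental = segments[-1L])
}

#' Subtract the baseline window from each experimental window
#'
#' The amplitude change relative to the baseline is the time-domain feature
#' used downstream.
#'
#' @param baseline `channels x window_samples` matrix.
#' @param experimental list of matrices with the baseline's shape.
#' @return list of `experimental[[k]] - baseline`, same order.
#' @export
baseline_subtract <- function(baseline, experimental) {
  lapply(seq_along(experimental), function(k) {
    seg <- experimental[[k]]
    if (!identical(dim(seg), dim(baseline))) {
      stop_shape(sprintf("experimental segment %d", k), dim(baseline), dim(seg))
    }
    seg - baseline
  })
}

#' Z-score features per channel
#'
#' @param features numeric array `examples x timesteps x channels`.
#' @param scope `"per_subject_channel"` fits one mean/sd per channel over all
#'   examples and timesteps; `"train_stats_channel"` is the same computation
#'   restricted to the examples in `fit_index` (leakage-safe: fit on the
#'   training split, apply everywhere via [apply_standardization()]).
#' @param fit_index example indices used to fit the statistics (defaults to
#'   all examples; required meaningfully only for `"train_stats_channel"`).
#' @param epsilon_guard if `TRUE` (default), a constant channel (sd 0) is
#'   mapped to all zeros instead of erroring.
#' @return list with `features` (standardized array) and `stats` (per-channel
#'   `mean` and `sd` vectors, reusable via [apply_standardization()]).
#' @export
standardize_features <- function(features,
                                 scope = c("per_subject_channel",
                                           "train_stats_channel"),
                                 fit_index = NULL, epsilon_guard = TRUE) {
  scope <- match.arg(scope)
  d <- dim(features)
  stopifnot(length(d) == 3L)
  idx <- if (scope == "train_stats_channel" && !is.null(fit_index)) fit_index
         else seq_len(d[1L])
  ch_mean <- numeric(d[3L]); ch_sd <- numeric(d[3L])
  for (ch in seq_len(d[3L])) {
    v <- features[idx, , ch]
    ch_mean[ch] <- mean(v)
    # population sd: the scope is the whole standardization population
    ch_sd[ch] <- sqrt(mean((v - ch_mean[ch])^2))
  }
  if (any(ch_sd == 0)) {
    if (!epsilon_guard) {
      stop("degenerate (constant) channel: sd is zero and the epsilon guard is disabled",
           call. = FALSE)
    }
    ch_sd[ch_sd == 0] <- 1
  }
  stats <- list(mean = ch_mean, sd = ch_sd)
  list(features = apply_standardization(features, stats), stats = stats)
}

#' @rdname standardize_features
#' @param stats fitted statistics returned by [standardize_features()].
#' @export
apply_standardization <- function(features, stats) {
  d <- dim(features)
  for (ch in seq_len(d[3L])) {
    features[, , ch] <- (features[, , ch] - stats$mean[ch]) / stats$sd[ch]
  }
  features
}

#' Map DEAP valence/arousal ratings to a quadrant class
#'
#' Ratings above the threshold are "high"; the four combinations give the
#' classes HVHA, LVHA, LVLA, HVLA (class ids 0-3 in that order). The
#' comparator is configurable because a rating exactly at the threshold must
#' be assigned deterministically: with the default strict comparator, 5 is
#' "low".
#'
#' @param valence,arousal ratings in \[1, 9\] (vectorized).
#' @param threshold split point (default 5).
#' @param comparator `">"` (default; high means strictly above threshold) or
#'   `">="`.
#' @return integer class ids in 0..3, with `levels` attribute
#'   `c("HVHA", "LVHA", "LVLA", "HVLA")`.
#' @export
map_labels_deap <- function(valence, arousal, threshold = 5,
                            comparator = c(">", ">=")) {
  comparator <- match.arg(comparator)
  if (any(valence < 1 | valence > 9) || any(arousal < 1 | arousal > 9)) {
    stop("ratings must lie in [1, 9]", call. = FALSE)
  }
  cmp <- match.fun(comparator)
  hv <- cmp(valence, threshold)
  ha <- cmp(arousal, threshold)
  id <- integer(length(hv))
  id[hv & ha] <- 0L   # HVHA
  id[!hv & ha] <- 1L  # LVHA
  id[!hv & !ha] <- 2L # LVLA
  id[hv & !ha] <- 3L  # HVLA
  structure(id, levels = deap_class_names())
}

#' @rdname map_labels_deap
#' @export
deap_class_names <- function() c("HVHA", "LVHA", "LVLA", "HVLA")

#' Map SEED trial labels \{-1, 0, 1\} to class ids 0..2
#'
#' @param label numeric vector in \{-1, 0, 1\}.
#' @return integer ids (0 negative, 1 neutral, 2 positive) with `levels`
#'   attribute.
#' @export
map_labels_seed <- function(label) {
  if (!all(label %in% c(-1, 0, 1))) stop("SEED labels must be in {-1, 0, 1}", call. = FALSE)
  structure(as.integer(label + 1), levels = seed_class_names())
}

#' @rdname map_labels_seed
#' @export
seed_class_names <- function() c("negative", "neutral", "positive")

#' Build the per-subject feature set
#'
#' Composes [segment_trial()], [split_baseline()], [baseline_subtract()],
#' [standardize_features()] and label mapping over every trial. Each
#' experimental window becomes one training example, oriented
#' `timesteps x channels` so that time is the recurrence axis; a DEAP
#' recording yields 40 trials x 20 windows = 800 examples of 384 x 32.
#'
#' @param rec a [subject_recording()].
#' @param window_seconds segmentation window (default 3 s).
#' @param threshold,comparator DEAP quadrant rule, see [map_labels_deap()].
#' @param standardize `TRUE` (default) to z-score per channel.
#' @param scope standardization scope, see [standardize_features()].
#' @param truncate passed to [segment_trial()].
#' @return a `feature_set`: list with `features` (array `examples x
#'   timesteps x channels`), `class_ids` (integer 0..K-1), `class_names`,
#'   `provenance` (data.frame trial/segment), `n_classes`, `sampling_rate`,
#'   `stats` (standardization statistics or `NULL`).
#' @export
build_feature_set <- function(rec, window_seconds = 3, threshold = 5,
                              comparator = ">", standardize = TRUE,
                              scope = "per_subject_channel",
                              truncate = FALSE) {
  validate_recording(rec)
  d <- dim(rec$data)
  n_trials <- d[1L]
  win <- as.integer(round(window_seconds * rec$sampling_rate))

  per_trial <- d[3L] %/% win - 1L  # experimental windows per trial
  if (per_trial < 1L) stop("trials are too short for baseline + 1 experimental window", call. = FALSE)
  n_ex <- n_trials * per_trial
  features <- array(0, dim = c(n_ex, win, d[2L]))
  prov <- data.frame(trial = integer(n_ex), segment = integer(n_ex))

  if (ncol(rec$labels) >= 2L &&
      all(c("valence", "arousal") %in% colnames(rec$labels))) {
    trial_class <- map_labels_deap(rec$labels[, "valence"],
                                   rec$labels[, "arousal"],
                                   threshold = threshold,
                                   comparator = comparator)
    class_names <- deap_class_names()
  } else {
    trial_class <- map_labels_seed(rec$labels[, 1L])
    class_names <- seed_class_names()
  }

  row <- 1L
  class_ids <- integer(n_ex)
  for (tr in seq_len(n_trials)) {
    segs <- segment_trial(rec$data[tr, , ], rec$sampling_rate,
                          window_seconds, truncate = truncate)
    sp <- split_baseline(segs)
    feats <- baseline_subtract(sp$baseline, sp$experimental)
    for (k in seq_along(feats)) {
      features[row, , ] <- t(feats[[k]])  # -> timesteps x channels
      prov$trial[row] <- tr
      prov$segment[row] <- k
      class_ids[row] <- trial_class[tr]
      row <- row + 1L
    }
  }

  stats <- NULL
  if (standardize) {
    st <- standardize_features(features, scope = scope)
    features <- st$features
    stats <- st$stats
  }
  structure(list(features = features,
                 class_ids = class_ids,
                 class_names = class_names,
                 n_classes = length(class_names),
                 provenance = prov,
                 sampling_rate = rec$sampling_rate,
                 subject_id = rec$subject_id,
                 stats = stats),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  d <- dim(x$features)
  cat(sprintf("<feature_set> %s: %d examples x %d timesteps x %d channels, %d classes\n",
              x$subject_id, d[1], d[2], d[3], x$n_classes))
  cat("  class counts:", paste(sprintf("%s=%d", x$class_names,
        tabulate(x$class_ids + 1L, x$n_classes)), collapse = " "), "\n")
  invisible(x)
}
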