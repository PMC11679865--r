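test_that("3-s segmentation yields the dialect window counts and partitions the trial", {
  # DEAP geometry: 63 s at 128 Hz
  trial <- matrix(rnorm(32 * 8064), 32, 8064)
  segs <- segment_trial(trial, 128)
  expect_length(segs, 21L)
  expect_true(all(vapply(segs, function(s) identical(dim(s), c(32L, 384L)), TRUE)))
  expect_identical(do.call(cbind, segs), trial)  # segmentation is a partition

  # SEED geometry: 60 s at 200 Hz
  segs2 <- segment_trial(matrix(0, 32, 12000), 200)
  expect_length(segs2, 20L)
  expect_identical(dim(segs2[[1]]), c(32L, 600L))

  # exactly one window is the identity
  one <- matrix(rnorm(32 * 384), 32, 384)
  expect_identical(segment_trial(one, 128), list(one))
})

test_that("non-multiple trial lengths error with the remainder, or truncate on request", {
  trial <- matrix(0, 4, 1000)
  expect_error(segment_trial(trial, 128), "remainder 232")
  expect_length(segment_trial(trial, 128, truncate = TRUE), 2L)
})

test_that("baseline split keeps order and requires at least two windows", {
  segs <- lapply(1:21, function(k) matrix(k, 2, 3))
  sp <- split_baseline(segs)
  expect_identical(sp$baseline, segs[[1]])
  expect_length(sp$experimental, 20L)
  expect_identical(sp$experimental[[20]], segs[[21]])
  expect_identical(length(split_baseline(segs[1:2])$experimental), 1L)
  expect_error(split_baseline(segs[1]), "at least 2")
})

test_that("baseline subtraction is element-wise and order preserving", {
  base <- matrix(c(1, 2), 1, 2)
  segs <- list(matrix(c(3, 4), 1, 2), matrix(c(5, 6), 1, 2))
  out <- baseline_subtract(base, segs)
  expect_equal(out[[1]], matrix(c(2, 2), 1, 2))
  expect_equal(out[[2]], matrix(c(4, 4), 1, 2))

  # x - x = 0
  same <- replicate(20, base, simplify = FALSE)
  expect_true(all(vapply(baseline_subtract(base, same),
                         function(m) all(m == 0), TRUE)))
  expect_length(baseline_subtract(base, same), 20L)
  expect_error(baseline_subtract(base, list(matrix(0, 2, 2))), "expected shape")
})

test_that("per-channel constants cancel through baseline subtraction", {
  set.seed(7)
  for (rep in 1:5) {
    trial <- matrix(rnorm(4 * 128 * 6), 4, 128 * 6)
    shift <- rnorm(4)
    shifted <- trial + shift  # recycles per channel (column-major rows)
    f1 <- with(split_baseline(segment_trial(trial, 128, 1)),
               baseline_subtract(baseline, experimental))
    f2 <- with(split_baseline(segment_trial(shifted, 128, 1)),
               baseline_subtract(baseline, experimental))
    expect_equal(f1, f2, tolerance = 1e-12)
  }
})

test_that("standardization gives per-channel mean 0 / sd 1 and reapplies bit-identically", {
  set.seed(11)
  x <- array(rnorm(50 * 12 * 3, mean = 4, sd = 9), c(50, 12, 3))
  st <- standardize_features(x)
  for (ch in 1:3) {
    expect_lt(abs(mean(st$features[, , ch])), 1e-6)
    expect_lt(abs(sqrt(mean((st$features[, , ch])^2)) - 1), 1e-6)
  }
  expect_identical(apply_standardization(x, st$stats), st$features)
})

test_that("constant channels standardize to zero under the epsilon guard, error without", {
  x <- array(rnorm(10 * 4 * 2), c(10, 4, 2))
  x[, , 2] <- 3.14
  st <- standardize_features(x)
  expect_true(all(st$features[, , 2] == 0))
  expect_error(standardize_features(x, epsilon_guard = FALSE), "degenerate")
})

test_that("train-statistics scope fits on the given examples only", {
  set.seed(3)
  x <- array(rnorm(40 * 6 * 2), c(40, 6, 2))
  x[1:20, , 1] <- x[1:20, , 1] + 10  # fit half differs
  st <- standardize_features(x, scope = "train_stats_channel", fit_index = 1:20)
  expect_equal(st$stats$mean[1], mean(x[1:20, , 1]))
  expect_lt(abs(mean(st$features[1:20, , 1])), 1e-6)
  expect_lt(mean(st$features[21:40, , 1]), 0)  # held-out shifted down
})

test_that("valence/arousal threshold rule maps the four quadrants", {
  lv <- function(v, a, ...) attr(map_labels_deap(v, a, ...), "levels")[
    map_labels_deap(v, a, ...) + 1L]
  expect_identical(lv(7, 8), "HVHA")
  expect_identical(lv(3, 8), "LVHA")
  expect_identical(lv(3, 2), "LVLA")
  expect_identical(lv(8, 2), "HVLA")
  # boundary: 5 is "low" under the strict comparator, "high" under >=
  expect_identical(lv(5, 5), "LVLA")
  expect_identical(lv(5, 5, comparator = ">="), "HVHA")
  expect_error(map_labels_deap(0.5, 5), "\\[1, 9\\]")
})

test_that("the quadrant rule partitions the rating square and is monotone", {
  grid <- expand.grid(v = seq(1, 9, by = 0.5), a = seq(1, 9, by = 0.5))
  ids <- map_labels_deap(grid$v, grid$a)
  expect_true(all(ids %in% 0:3))          # total
  expect_length(ids, nrow(grid))          # exactly one class each
  # raising valence never moves a high-valence label back to low
  hv <- ids %in% c(0L, 3L)
  for (a in unique(grid$a)) {
    sel <- grid$a == a
    expect_true(!is.unsorted(hv[sel][order(grid$v[sel])]))
  }
})

test_that("SEED labels map -1/0/1 onto negative/neutral/positive ids", {
  ids <- map_labels_seed(c(-1, 0, 1))
  expect_identical(as.integer(ids), 0:2)
  expect_identical(attr(ids, "levels"), c("negative", "neutral", "positive"))
  expect_error(map_labels_seed(2), "\\{-1, 0, 1\\}")
})

test_that("feature sets have trials x (windows - 1) examples with unique provenance", {
  rec <- desk_recording(seed = 2)
  fs <- build_feature_set(rec)
  expect_identical(dim(fs$features), c(160L, 384L, 8L))  # 8 trials x 20 windows
  expect_identical(fs$n_classes, 4L)
  expect_false(any(duplicated(fs$provenance)))
  expect_identical(fs$class_ids, rep(attr(rec, "true_class"), each = 20L))

  # SEED-dialect reduced geometry: 20 windows -> 19 experimental
  rec2 <- generate_recording(synth_config("seed", trials = 4, channels = 4,
                                          seed = 5))
  fs2 <- build_feature_set(rec2)
  expect_identical(dim(fs2$features), c(76L, 600L, 4L))  # 4 x 19
})

test_that("full-geometry recordings give the printed example counts", {
  fs <- build_feature_set(generate_recording(synth_config("deap", snr = 1,
                                                          seed = 1)))
  expect_identical(dim(fs$features)[1], 800L)  # 40 trials x 20 segments
  fs2 <- build_feature_set(generate_recording(synth_config("seed", snr = 1,
                                                           seed = 1)))
  expect_identical(dim(fs2$features)[1], 855L)  # 45 trials x 19 segments
})

test_that("an all-zero recording yields all-zero features and valid labels", {
  rec <- subject_recording("z", "SYNTHETIC",
                           array(0, c(3, 2, 128 * 9)), 128L,
                           labels = cbind(valence = c(7, 3, 3),
                                          arousal = c(7, 7, 2),
                                          liking = c(5, 5, 5),
                                          dominance = c(5, 5, 5)))
  fs <- build_feature_set(rec)
  expect_true(all(fs$features == 0))
  expect_identical(fs$class_ids, rep(c(0L, 1L, 2L), each = 2L))
})
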