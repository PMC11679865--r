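#' Construct a per-subject EEG recording
#'
#' The canonical in-memory container for one subject's trial tensor. All
#' readers ([read_deap()], [read_seed()], [read_canonical()]) and the
#' synthetic generator return this class.
#'
#' @param subject_id character scalar identifying the subject.
#' @param dataset_tag one of `"DEAP"`, `"SEED"`, `"SYNTHETIC"`. The DEAP and
#'   SEED tags switch on strict dialect validation (shape, sampling rate,
#'   label ranges); `"SYNTHETIC"` accepts any consistent shape.
#' @param data numeric 3-d array, `trials x channels x samples`, microvolt-scale
#'   arbitrary units. Must be finite.
#' @param sampling_rate samples per second (positive integer; 128 for DEAP,
#'   200 for SEED).
#' @param labels numeric matrix `trials x label_dims`. DEAP: four continuous
#'   ratings in \[1, 9\] (valence, arousal, liking, dominance). SEED: one
#'   column in \{-1, 0, 1\}.
#' @param label_names character vector naming the label columns.
#' @param channel_names optional character vector of channel names (length =
#'   `dim(data)[2]`).
#' @return an object of class `subject_recording`.
#' @export
subject_recording <- function(subject_id, dataset_tag, data, sampling_rate,
                              labels, label_names = colnames(labels),
                              channel_names = NULL) {
  dataset_tag <- match.arg(dataset_tag, c("DEAP", "SEED", "SYNTHETIC"))
  labels <- as.matrix(labels)
  if (!is.null(label_names)) colnames(labels) <- label_names
  rec <- structure(list(
    subject_id = as.character(subject_id),
    dataset_tag = dataset_tag,
    data = data,
    sampling_rate = as.integer(sampling_rate),
    labels = labels,
    label_names = label_names,
    channel_names = channel_names
  ), class = "subject_recording")
  validate_recording(rec)
  rec
}

#' Validate a subject recording against its dialect invariants
#'
#' @param rec a `subject_recording`.
#' @return `rec`, invisibly, if valid; otherwise an error.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "subject_recording"))
  d <- dim(rec$data)
  if (length(d) != 3L || any(d < 1L)) {
    stop("data must be a trials x channels x samples array with all dims >= 1",
         call. = FALSE)
  }
  if (anyNA(rec$data) || !all(is.finite(rec$data))) {
    stop("data contains non-finite values", call. = FALSE)
  }
  if (rec$sampling_rate < 1L) stop("sampling_rate must be positive", call. = FALSE)
  if (nrow(rec$labels) != d[1L]) {
    stop_shape("labels", c(d[1L], "*"), dim(rec$labels))
  }
  if (!is.null(rec$channel_names) && length(rec$channel_names) != d[2L]) {
    stop("channel_names length does not match the channel dimension", call. = FALSE)
  }
  if (rec$dataset_tag == "DEAP") {
    if (!identical(d, c(40L, 32L, 8064L))) stop_shape("DEAP data", c(40, 32, 8064), d)
    if (rec$sampling_rate != 128L) stop("DEAP sampling rate must be 128", call. = FALSE)
    if (!identical(dim(rec$labels), c(40L, 4L))) stop_shape("DEAP labels", c(40, 4), dim(rec$labels))
    if (any(rec$labels < 1 | rec$labels > 9)) {
      stop("DEAP ratings must lie in [1, 9]", call. = FALSE)
    }
  } else if (rec$dataset_tag == "SEED") {
    # 15 trials per session, stacked over 1..3 sessions (45 = all three)
    if (d[1L] %% 15L != 0L || d[2L] != 32L || d[3L] != 12000L) {
      stop_shape("SEED data", c("15k", 32, 12000), d)
    }
    if (rec$sampling_rate != 200L) stop("SEED sampling rate must be 200", call. = FALSE)
    if (!all(rec$labels %in% c(-1, 0, 1))) {
      stop("SEED labels must be in {-1, 0, 1}", call. = FALSE)
    }
  }
  invisible(rec)
}

#' @export
print.subject_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<subject_recording> %s [%s]\n", x$subject_id, x$dataset_tag))
  cat(sprintf("  %d trials x %d channels x %d samples @ %d Hz\n",
              d[1], d[2], d[3], x$sampling_rate))
  cat(sprintf("  labels: %d x %d (%s)\n", nrow(x$labels), ncol(x$labels),
              paste(x$label_names %||% colnames(x$labels) %||% "?", collapse = ", ")))
  invisible(x)
}

## ---- python-bridged dialect readers ----------------------------------------

python_bin <- function() {
  py <- getOption("psolstm.python", Sys.which("python"))
  if (!nzchar(py)) stop("no 'python' interpreter found on PATH", call. = FALSE)
  py
}

run_eeg_io <- function(cmd, input, output) {
  script <- system.file("python", "eeg_io.py", package = "psolstm")
  if (!nzchar(script)) stop("bundled eeg_io.py helper not found", call. = FALSE)
  res <- suppressWarnings(
    system2(python_bin(), c(script, cmd, shQuote(input), shQuote(output)),
            stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status") %||% 0L
  if (status != 0L) {
    stop(sprintf("eeg_io %s failed: %s", cmd,
                 paste(res, collapse = " ")), call. = FALSE)
  }
  invisible(NULL)
}

# read a little-endian C-order float64 dump into an R array of `shape`
read_np_bin <- function(path, shape) {
  x <- readBin(path, what = "double", n = prod(shape), size = 8L,
               endian = "little")
  if (length(shape) == 1L) return(x)
  aperm(array(x, dim = rev(shape)), rev(seq_along(shape)))
}

write_np_bin <- function(arr, path) {
  d <- dim(arr) %||% length(arr)
  writeBin(as.double(aperm(arr, rev(seq_along(d)))), path, size = 8L,
           endian = "little")
}

#' Read a DEAP per-subject file
#'
#' Accepts the per-subject container distributed with the dataset: a Python
#' pickle (`.dat`/`.pkl`) or MATLAB file (`.mat`) holding a mapping with
#' entries `data` (40 trials x 40 channels x 8064 samples in the original
#' distribution, or 40 x 32 x 8064 if the peripheral channels were already
#' dropped) and `labels` (40 x 4). Only the 32 EEG channels are kept; the
#' peripheral channels 33-40 (GSR, HR, EMG, ...) are discarded. Also accepts
#' the package's canonical container (`.rds`).
#'
#' @param path path to the per-subject file.
#' @param subject_id subject identifier stored in the result; defaults to the
#'   file name without extension.
#' @return a DEAP-dialect [subject_recording()]: data `40 x 32 x 8064` at
#'   128 Hz, labels `40 x 4` ordered (valence, arousal, liking, dominance).
#' @export
read_deap <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  subject_id <- subject_id %||% sub("\\.[^.]*$", "", basename(path))
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    rec <- read_canonical(path)
    validate_recording(rec)
    if (rec$dataset_tag != "DEAP") stop("canonical file is not DEAP-tagged", call. = FALSE)
    return(rec)
  }
  tmp <- tempfile("deap_io_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  run_eeg_io("read_deap", path, tmp)
  meta <- jsonlite::read_json(file.path(tmp, "meta.json"), simplifyVector = TRUE)
  dshape <- as.integer(meta$data_shape)
  lshape <- as.integer(meta$labels_shape)
  if (length(dshape) != 3L || dshape[1L] != 40L || !(dshape[2L] %in% c(32L, 40L)) ||
      dshape[3L] != 8064L) {
    stop_shape("DEAP data entry", c(40, "32|40", 8064), dshape)
  }
  if (!identical(lshape, c(40L, 4L))) stop_shape("DEAP labels entry", c(40, 4), lshape)
  data <- read_np_bin(file.path(tmp, "data.bin"), dshape)
  if (dshape[2L] == 40L) data <- data[, 1:32, , drop = FALSE]
  labels <- read_np_bin(file.path(tmp, "labels.bin"), lshape)
  subject_recording(subject_id, "DEAP", data, 128L, labels,
                    label_names = c("valence", "arousal", "liking", "dominance"))
}

#' The 62-channel montage used by SEED recordings
#'
#' Electrode names in row order of the ESI NeuroScan 62-channel cap
#' (international 10-20 extended positions) used by the SEED recordings.
#' Serves as the default `montage` argument of [read_seed()]; override it if
#' your files use a different row order.
#'
#' @return character vector of 62 electrode names.
#' @export
seed_montage <- function() {
  c("FP1", "FPZ", "FP2", "AF3", "AF4", "F7", "F5", "F3", "F1", "FZ", "F2",
    "F4", "F6", "F8", "FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6",
    "FT8", "T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8", "TP7", "CP5",
    "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8", "P7", "P5", "P3", "P1",
    "PZ", "P2", "P4", "P6", "P8", "PO7", "PO5", "PO3", "POZ", "PO4", "PO6",
    "PO8", "CB1", "O1", "OZ", "O2", "CB2")
}

#' Read SEED session files into a subject recording
#'
#' Each SEED session file holds 15 trial matrices (`<subject>_eeg1` ..
#' `<subject>_eeg15`), each `62 channels x samples` at 200 Hz with
#' clip-dependent length. The reader selects a 32-channel subset by name (the
#' channel subset matched to the DEAP cap is a required configuration choice,
#' not a built-in default), crops each trial to its middle 60 s (12,000
#' samples; start index `floor((L - 12000) / 2)`), and stacks the sessions in
#' the order given so that three sessions yield the 45-trial layout.
#'
#' @param paths character vector of session file paths (1 or 3 typically).
#' @param channels ordered character vector of exactly 32 channel names to
#'   keep.
#' @param labels numeric vector of per-trial labels in \{-1, 0, 1\}, length 15
#'   (recycled across sessions) or `15 * length(paths)`.
#' @param montage character vector naming the rows of the stored trial
#'   matrices, in order. Defaults to [seed_montage()].
#' @param subject_id subject identifier; defaults from the first file name.
#' @return a SEED-dialect [subject_recording()] with
#'   `15 * length(paths) x 32 x 12000` data.
#' @export
read_seed <- function(paths, channels, labels, montage = seed_montage(),
                      subject_id = NULL) {
  stopifnot(length(paths) >= 1L)
  if (length(channels) != 32L) stop("exactly 32 channel names are required", call. = FALSE)
  missing_ch <- setdiff(channels, montage)
  if (length(missing_ch)) {
    stop("channels not present in the montage: ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }
  if (!all(labels %in% c(-1, 0, 1))) stop("SEED labels must be in {-1, 0, 1}", call. = FALSE)
  subject_id <- subject_id %||% sub("\\.[^.]*$", "", basename(paths[1L]))
  ch_idx <- match(channels, montage)

  trials <- list()
  for (p in paths) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
    tmp <- tempfile("seed_io_")
    dir.create(tmp)
    run_eeg_io("read_seed", p, tmp)
    meta <- jsonlite::read_json(file.path(tmp, "meta.json"), simplifyVector = TRUE)
    tinfo <- meta$trials
    for (k in seq_len(nrow(tinfo))) {
      shape <- as.integer(tinfo$shape[[k]])
      if (length(shape) != 2L || shape[1L] < length(montage)) {
        stop(sprintf("trial '%s': expected >= %d channels, found %d",
                     tinfo$name[k], length(montage), shape[1L]), call. = FALSE)
      }
      L <- shape[2L]
      if (L < 12000L) {
        stop(sprintf("trial '%s' is shorter than 60 s at 200 Hz (%d samples)",
                     tinfo$name[k], L), call. = FALSE)
      }
      m <- read_np_bin(file.path(tmp, tinfo$file[k]), shape)
      start <- floor((L - 12000L) / 2)
      trials[[length(trials) + 1L]] <- m[ch_idx, (start + 1L):(start + 12000L),
                                         drop = FALSE]
    }
    unlink(tmp, recursive = TRUE)
  }
  n <- length(trials)
  data <- array(0, dim = c(n, 32L, 12000L))
  for (k in seq_len(n)) data[k, , ] <- trials[[k]]
  lab <- rep_len(labels, n)
  subject_recording(subject_id, "SEED", data, 200L,
                    matrix(lab, ncol = 1L), label_names = "emotion",
                    channel_names = channels)
}

## ---- canonical container ----------------------------------------------------

CANONICAL_LAYOUT_VERSION <- 1L

#' Write / read the canonical on-disk recording container
#'
#' A single-file container (versioned RDS structure) holding the trial tensor
#' bit-exactly together with its metadata. Layout: a named list with fields
#' `layout_version`, `subject_id`, `dataset_tag`, `sampling_rate`,
#' `label_names`, `channel_names`, `data`, `labels`. `read_canonical()`
#' refuses files with an unknown `layout_version` and files missing the
#' `data` or `labels` fields, and `read_canonical(write_canonical(x)) == x`
#' exactly for the arrays.
#'
#' @param rec a valid [subject_recording()].
#' @param path file path (conventionally `.rds`).
#' @return `write_canonical()`: the path, invisibly. `read_canonical()`: a
#'   `subject_recording`.
#' @export
write_canonical <- function(rec, path) {
  validate_recording(rec)
  obj <- list(layout_version = CANONICAL_LAYOUT_VERSION,
              subject_id = rec$subject_id,
              dataset_tag = rec$dataset_tag,
              sampling_rate = rec$sampling_rate,
              label_names = rec$label_names,
              channel_names = rec$channel_names,
              data = rec$data,
              labels = rec$labels)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_canonical
#' @export
read_canonical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$layout_version)) {
    stop("not a canonical recording container (no layout_version)", call. = FALSE)
  }
  if (obj$layout_version != CANONICAL_LAYOUT_VERSION) {
    stop("unknown canonical layout version: ", obj$layout_version, call. = FALSE)
  }
  for (field in c("data", "labels")) {
    if (is.null(obj[[field]])) {
      stop("canonical container is missing the '", field, "' field", call. = FALSE)
    }
  }
  subject_recording(obj$subject_id, obj$dataset_tag, obj$data,
                    obj$sampling_rate, obj$labels,
                    label_names = obj$label_names,
                    channel_names = obj$channel_names)
}

#' Export a recording in the DEAP pickle dialect
#'
#' Writes `rec` as a Python pickle with `data` and `labels` entries, the
#' per-subject layout distributed by DEAP. Useful for fixtures and for
#' interoperating with Python tooling.
#'
#' @param rec a [subject_recording()].
#' @param path output file path (`.dat`).
#' @return the path, invisibly.
#' @export
write_deap_pickle <- function(rec, path) {
  validate_recording(rec)
  tmp <- tempfile("deap_io_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  write_np_bin(rec$data, file.path(tmp, "data.bin"))
  write_np_bin(rec$labels, file.path(tmp, "labels.bin"))
  jsonlite::write_json(list(data_shape = dim(rec$data),
                            labels_shape = dim(rec$labels)),
                       file.path(tmp, "meta.json"), auto_unbox = FALSE)
  run_eeg_io("write_deap", tmp, path)
  invisible(path)
}

## ---- evaluation reports -----------------------------------------------------

#' Construct a per-subject evaluation report
#'
#' @param subject_id subject identifier.
#' @param confusion square integer matrix of test-set counts, rows = true
#'   class, columns = predicted class.
#' @param best_hyperparams named list of the selected hyperparameters
#'   (`units1`, `units2`, `dense_units`, `dropout`, `batch_size`), or `NULL`.
#' @param loss_trace numeric vector of the swarm's global-best validation loss
#'   after each iteration (non-increasing), or `NULL` when no search was run.
#' @param seed the master seed the run used.
#' @return an `eval_report` with fields `accuracy` (= trace / sum of
#'   `confusion`), `confusion`, `best_hyperparams`, `loss_trace`.
#' @export
eval_report <- function(subject_id, confusion, best_hyperparams = NULL,
                        loss_trace = NULL, seed = NA_integer_) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop("confusion matrix must be square", call. = FALSE)
  if (any(confusion < 0) || any(confusion != round(confusion))) {
    stop("confusion matrix must hold non-negative integer counts", call. = FALSE)
  }
  if (!is.null(loss_trace) && length(loss_trace) > 1L &&
      any(diff(loss_trace) > 1e-12)) {
    stop("loss_trace must be non-increasing (global best never worsens)", call. = FALSE)
  }
  structure(list(
    subject_id = as.character(subject_id),
    accuracy = sum(diag(confusion)) / sum(confusion),
    confusion = confusion,
    best_hyperparams = best_hyperparams,
    loss_trace = loss_trace,
    seed = seed
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> subject %s: accuracy %.4f on %d test segments\n",
              x$subject_id, x$accuracy, sum(x$confusion)))
  invisible(x)
}

#' Persist an evaluation report as JSON plus a CSV confusion matrix
#'
#' Writes `<path>` (JSON, deterministic field order: subject_id, accuracy,
#' best_hyperparams, loss_trace, confusion) and a companion
#' `<path minus .json>_confusion.csv`.
#'
#' @param report an [eval_report()].
#' @param path output JSON path.
#' @return the JSON path, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  out <- list(subject_id = report$subject_id,
              accuracy = report$accuracy,
              best_hyperparams = report$best_hyperparams,
              loss_trace = report$loss_trace,
              confusion = report$confusion,
              seed = report$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  csv <- sub("\\.json$", "", path)
  write.csv(report$confusion, paste0(csv, "_confusion.csv"), row.names = FALSE)
  invisible(path)
}
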