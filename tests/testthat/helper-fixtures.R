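# Shared fixtures: everything is generated in code at test time.

# tiny DEAP-geometry synthetic recording (full-length trials, few channels)
desk_recording <- function(seed = 1L, snr = 4) {
  generate_recording(synth_config("deap", desk_profile = TRUE, snr = snr,
                                  seed = seed))
}

# reference single-layer LSTM sequence built from lstm_step(), used as the
# independent route against the compiled layer
r_lstm_sequence <- function(cell, X) {
  # X: timesteps x input matrix for one example
  H <- nrow(cell$W_if)
  h <- numeric(H); c <- numeric(H)
  out <- matrix(0, nrow(X), H)
  for (t in seq_len(nrow(X))) {
    st <- lstm_step(cell, X[t, ], h, c)
    h <- st$h; c <- st$c
    out[t, ] <- h
  }
  out
}

# random per-gate cell parameters plus the equivalent gate-concatenated
# matrices used by the compiled layer (column blocks input|forget|cand|output)
random_cell <- function(input, hidden) {
  gm <- function() matrix(rnorm(hidden * input, sd = 0.5), hidden, input)
  rm_ <- function() matrix(rnorm(hidden * hidden, sd = 0.5), hidden, hidden)
  bv <- function() rnorm(hidden, sd = 0.5)
  cell <- lstm_cell_params(W_if = gm(), W_ii = gm(), W_io = gm(), W_ic = gm(),
                           W_hf = rm_(), W_hi = rm_(), W_ho = rm_(), W_hc = rm_(),
                           b_f = bv(), b_i = bv(), b_o = bv(), b_c = bv())
  W <- cbind(t(cell$W_ii), t(cell$W_if), t(cell$W_ic), t(cell$W_io))
  U <- cbind(t(cell$W_hi), t(cell$W_hf), t(cell$W_hc), t(cell$W_ho))
  b <- matrix(c(cell$b_i, cell$b_f, cell$b_c, cell$b_o), nrow = 1)
  list(cell = cell, W = W, U = U, b = b)
}

# write a SEED-style MATLAB session file with sentinel-valued trials:
# trial k, channel r, sample s (0-based) holds k*1000 + r + s*1e-4, so both
# channel selection and the temporal crop window are observable
make_seed_mat <- function(path, n_trials = 15L, n_channels = 40L,
                          n_samples = 12050L, prefix = "tst") {
  py <- Sys.which("python")
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import numpy as np",
    "from scipy.io import savemat",
    "d = {}",
    sprintf("ramp = np.arange(%d, dtype=float)[None, :] * 1e-4", n_samples),
    sprintf("chan = np.arange(1, %d + 1, dtype=float)[:, None]", n_channels),
    sprintf("for k in range(1, %d + 1):", n_trials),
    sprintf("    d['%s_eeg%%d' %% k] = chan + 1000.0 * k + ramp", prefix),
    sprintf("savemat(%s, d, do_compression=True)", deparse(path))
  ), script)
  status <- system2(py, script, stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status"))) stop(paste(status, collapse = "\n"))
  invisible(path)
}

# memoized desk-scale experiment runs shared by the acceptance blocks
desk_runs_env <- new.env(parent = emptyenv())
get_desk_runs <- function(seeds = 1:5) {
  key <- paste(seeds, collapse = ",")
  if (!is.null(desk_runs_env[[key]])) return(desk_runs_env[[key]])
  runs <- lapply(seeds, function(seed) {
    dp <- desk_profile(seed)
    fs <- build_feature_set(generate_recording(dp$synth))
    proposed <- run_subject(fs, "proposed", cfg = dp$train, space = dp$space,
                            pso = dp$pso)
    no_attention <- run_subject(fs, "no_attention", cfg = dp$train,
                                space = dp$space, pso = dp$pso)
    dp0 <- desk_profile(seed, snr = 0)
    control <- run_subject(generate_recording(dp0$synth), "fixed_params",
                           cfg = dp0$train)
    list(seed = seed, fs = fs, proposed = proposed,
         no_attention = no_attention, control = control)
  })
  desk_runs_env[[key]] <- runs
  runs
}
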