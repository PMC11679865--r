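#' Specify the attention-LSTM classifier architecture
#'
#' The classifier is: LSTM layer 1 (sequence output) -> batch normalization
#' -> dropout -> LSTM layer 2 (sequence output) -> batch normalization ->
#' dropout -> additive attention over the hidden-state sequence -> the
#' context vector concatenated with the final hidden state -> dense layer
#' with tanh -> dense softmax over classes. The `attention = FALSE` variant
#' drops the attention/context path and feeds the final hidden state alone to
#' the dense head (the "without attention" ablation).
#'
#' @param units1,units2 hidden units in the first and second LSTM layer
#'   (1-200).
#' @param dense_units units of the tanh dense layer (1-200).
#' @param dropout dropout rate in \[0.1, 0.9\] applied after each
#'   normalization layer during training.
#' @param num_classes 3 or 4 output classes.
#' @param timesteps,channels input geometry: each example is `timesteps`
#'   steps of `channels` features (time is the recurrence axis).
#' @param attention include the attention/context path (default `TRUE`).
#' @param attn_dim rows of the attention projection; defaults to `units2`.
#' @return a `model_spec`.
#' @export
model_spec <- function(units1, units2, dense_units, dropout, num_classes,
                       timesteps, channels, attention = TRUE,
                       attn_dim = units2) {
  stopifnot(units1 >= 1, units1 <= 200, units2 >= 1, units2 <= 200,
            dense_units >= 1, dense_units <= 200,
            dropout >= 0.1, dropout <= 0.9,
            num_classes >= 2, timesteps >= 1, channels >= 1, attn_dim >= 1)
  structure(list(units1 = as.integer(units1), units2 = as.integer(units2),
                 dense_units = as.integer(dense_units), dropout = dropout,
                 num_classes = as.integer(num_classes),
                 timesteps = as.integer(timesteps),
                 channels = as.integer(channels),
                 attention = isTRUE(attention),
                 attn_dim = as.integer(attn_dim)),
            class = "model_spec")
}

#' The fixed-hyperparameter baseline architecture
#'
#' Units (128, 64), dense 16, dropout 0.2, batch size 32 — the configuration
#' used by the fixed-parameters ablation.
#'
#' @return named list with `units1`, `units2`, `dense_units`, `dropout`,
#'   `batch_size`.
#' @export
fixed_baseline_hyperparams <- function() {
  list(units1 = 128L, units2 = 64L, dense_units = 16L, dropout = 0.2,
       batch_size = 32L)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Build (initialize) a classifier from a spec
#'
#' Glorot-uniform weights, zero biases except the forget-gate bias (set to 1,
#' the usual stabilization), batch-norm scale 1 / shift 0 with zero running
#' mean and unit running variance. Initialization draws come from R's RNG, so
#' `set.seed()` before calling fixes the model.
#'
#' @param spec a [model_spec()].
#' @return a `psolstm_model`: list with `spec` and `params` (named weight
#'   matrices; gate order input/forget/candidate/output, gate-concatenated).
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  H1 <- spec$units1; H2 <- spec$units2; Dn <- spec$dense_units
  Cc <- spec$channels; K <- spec$num_classes; A <- spec$attn_dim
  gate_bias <- function(H) {
    b <- matrix(0, 1, 4 * H)
    b[1, (H + 1):(2 * H)] <- 1  # forget gate
    b
  }
  params <- list(
    W1 = glorot(Cc, 4 * H1), U1 = glorot(H1, 4 * H1), b1 = gate_bias(H1),
    g1 = matrix(1, 1, H1), be1 = matrix(0, 1, H1),
    rm1 = matrix(0, 1, H1), rv1 = matrix(1, 1, H1),
    W2 = glorot(H1, 4 * H2), U2 = glorot(H2, 4 * H2), b2 = gate_bias(H2),
    g2 = matrix(1, 1, H2), be2 = matrix(0, 1, H2),
    rm2 = matrix(0, 1, H2), rv2 = matrix(1, 1, H2),
    Wd = glorot(if (spec$attention) 2 * H2 else H2, Dn),
    bd = matrix(0, 1, Dn),
    Wo = glorot(Dn, K), bo = matrix(0, 1, K))
  if (spec$attention) {
    params$Wa <- glorot(A, 2 * H2)
    params$va <- matrix(glorot(A, 1), A, 1)
  }
  structure(list(spec = spec, params = params), class = "psolstm_model")
}

#' Class probabilities for a batch of examples
#'
#' Evaluation-mode forward pass: dropout off, batch normalization using the
#' frozen running statistics. Deterministic: identical inputs give identical
#' outputs.
#'
#' @param model a trained or freshly built `psolstm_model`.
#' @param x array `examples x timesteps x channels`.
#' @param chunk examples per forward chunk (memory guard for big batches).
#' @return matrix `examples x num_classes`; rows sum to 1.
#' @export
predict_proba <- function(model, x, chunk = 512L) {
  stopifnot(inherits(model, "psolstm_model"))
  d <- dim(x)
  if (length(d) != 3L || d[2L] != model$spec$timesteps ||
      d[3L] != model$spec$channels) {
    stop_shape("input batch", c("*", model$spec$timesteps, model$spec$channels), d)
  }
  out <- matrix(0, d[1L], model$spec$num_classes)
  for (start in seq(1L, d[1L], by = chunk)) {
    sel <- start:min(start + chunk - 1L, d[1L])
    xb <- aperm(x[sel, , , drop = FALSE], c(1L, 3L, 2L))  # -> B x C x T
    out[sel, ] <- cpp_predict(model$params, xb, model$spec$attention)
  }
  out
}

#' @rdname predict_proba
#' @return `predict_class()`: integer class ids 0..K-1 (argmax; ties broken
#'   toward the lower id).
#' @export
predict_class <- function(model, x, chunk = 512L) {
  max.col(predict_proba(model, x, chunk), ties.method = "first") - 1L
}

## ---- pure-R reference equations (single step / single example) -------------

#' Per-gate LSTM cell parameters
#'
#' The single-step reference parameterization: separate input weights
#' (`hidden x input`), recurrent weights (`hidden x hidden`) and bias per
#' gate, with a distinct candidate gate (`W_ic`, `W_hc`, `b_c`).
#'
#' @param W_if,W_ii,W_io,W_ic input weights for the forget, input, output and
#'   candidate gates.
#' @param W_hf,W_hi,W_ho,W_hc recurrent weights.
#' @param b_f,b_i,b_o,b_c biases.
#' @return an `lstm_cell_params` list.
#' @export
lstm_cell_params <- function(W_if, W_ii, W_io, W_ic, W_hf, W_hi, W_ho, W_hc,
                             b_f, b_i, b_o, b_c) {
  p <- lapply(list(W_if = W_if, W_ii = W_ii, W_io = W_io, W_ic = W_ic,
                   W_hf = W_hf, W_hi = W_hi, W_ho = W_ho, W_hc = W_hc),
              as.matrix)
  p <- c(p, list(b_f = as.numeric(b_f), b_i = as.numeric(b_i),
                 b_o = as.numeric(b_o), b_c = as.numeric(b_c)))
  H <- nrow(p$W_if)
  stopifnot(all(vapply(p[1:8], nrow, 0L) == H),
            all(lengths(p[9:12]) == H))
  structure(p, class = "lstm_cell_params")
}

#' One LSTM cell step
#'
#' The standard cell update: forget/input/output gates through the sigmoid, a
#' distinct tanh candidate state, cell state `c_t = f * c_prev + i * cand`,
#' hidden state `h_t = o * tanh(c_t)`.
#'
#' @param params an [lstm_cell_params()].
#' @param x_t input vector at time t.
#' @param h_prev,c_prev previous hidden and cell state vectors.
#' @return list with `h`, `c`, and the gate activations `f`, `i`, `o`,
#'   `candidate` (each strictly inside (0,1) for the sigmoid gates).
#' @export
lstm_step <- function(params, x_t, h_prev, c_prev) {
  stopifnot(inherits(params, "lstm_cell_params"))
  if (length(x_t) != ncol(params$W_if)) {
    stop_shape("x_t", ncol(params$W_if), length(x_t))
  }
  f <- sigmoid(drop(params$W_if %*% x_t + params$W_hf %*% h_prev) + params$b_f)
  i <- sigmoid(drop(params$W_ii %*% x_t + params$W_hi %*% h_prev) + params$b_i)
  o <- sigmoid(drop(params$W_io %*% x_t + params$W_ho %*% h_prev) + params$b_o)
  cand <- tanh(drop(params$W_ic %*% x_t + params$W_hc %*% h_prev) + params$b_c)
  c_t <- f * c_prev + i * cand
  h_t <- o * tanh(c_t)
  list(h = h_t, c = c_t, f = f, i = i, o = o, candidate = cand)
}

#' Additive attention scores against the final hidden state
#'
#' `score_t = va' tanh(Wa [h_t; h_n])` where `h_n` is the final hidden state
#' of the sequence.
#'
#' @param H matrix `n x hidden` of hidden states in time order.
#' @param W_a projection matrix `attn_dim x (2 * hidden)`.
#' @param v_a scoring vector of length `attn_dim`.
#' @return numeric score vector of length `n`.
#' @export
attention_scores <- function(H, W_a, v_a) {
  H <- as.matrix(H)
  n <- nrow(H); hid <- ncol(H)
  if (ncol(W_a) != 2L * hid) stop_shape("W_a", c(length(v_a), 2 * hid), dim(W_a))
  hn <- H[n, ]
  vapply(seq_len(n), function(t) {
    sum(v_a * tanh(drop(W_a %*% c(H[t, ], hn))))
  }, 0)
}

#' Attention weights: softmax of the scores over time
#'
#' @param scores finite numeric score vector.
#' @return positive weights summing to 1.
#' @export
attention_weights <- function(scores) {
  stopifnot(all(is.finite(scores)))
  softmax(scores)
}

#' Context vector: attention-weighted sum of hidden states
#'
#' @param H matrix `n x hidden`.
#' @param a weight vector of length `n` (summing to 1).
#' @return numeric vector of length `hidden`.
#' @export
context_vector <- function(H, a) {
  H <- as.matrix(H)
  if (length(a) != nrow(H)) stop_shape("weights", nrow(H), length(a))
  drop(crossprod(H, a))
}
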